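# Counterfactual evaluation: scenario-to-base-case ratios, arena/SSMU
# aggregation, threshold-violation probabilities, magnitude classification,
# and catch-vs-abundance trade-off records.

#' Counterfactual ratio
#'
#' The ratio of a scenario outcome to its base-case outcome: 1.0 means the
#' management action had no effect; values above/below 1 are increases/
#' decreases. 0/0 is reported as 1.0 by convention (no change; a warning is
#' emitted); a positive numerator over a zero base is undefined and returned
#' as NA with a warning.
#'
#' @param scenario_mean scenario outcome(s).
#' @param base_mean base-case outcome(s), >= 0.
#' @return ratio(s), same length as the inputs.
#' @export
relative_change <- function(scenario_mean, base_mean) {
  stopifnot(length(scenario_mean) == length(base_mean))
  out <- scenario_mean / base_mean
  zz <- base_mean == 0 & scenario_mean == 0
  if (any(zz)) {
    out[zz] <- 1
    warning("0/0 counterfactual ratio reported as 1.0 (no change)",
            call. = FALSE)
  }
  undef <- base_mean == 0 & scenario_mean > 0
  if (any(undef)) {
    out[undef] <- NA_real_
    warning("undefined counterfactual ratio (zero base, positive scenario)",
            call. = FALSE)
  }
  out
}

#' Arena-scale aggregation
#'
#' Arena metrics are ratios of summed totals, not means of per-SSMU ratios:
#' `sum(scenario) / sum(base)`.
#'
#' @param scenario_values per-SSMU scenario totals.
#' @param base_values per-SSMU base-case totals.
#' @return a single arena-scale ratio.
#' @export
aggregate_arena <- function(scenario_values, base_values) {
  relative_change(sum(scenario_values), sum(base_values))
}

#' Threshold-violation probability
#'
#' The fraction of fishing trial-seasons (seasons with nonzero allocated
#' catch) in which krill density fell below the threshold, per SSMU. An SSMU
#' that is never fished has an undefined probability, reported as 0 with a
#' message.
#'
#' @param flags logical array (trials x seasons x SSMU), or a matrix
#'   (trial-seasons x SSMU), of violation flags.
#' @param fishing same shape: TRUE where catch was allocated. Defaults to
#'   all-TRUE (every trial-season counts).
#' @return violation probability per SSMU.
#' @export
violation_probability <- function(flags, fishing = NULL) {
  f <- if (length(dim(flags)) == 3)
    apply(flags, 3, sum) else colSums(flags)
  d <- if (is.null(fishing)) {
    rep(length(flags) / length(f), length(f))
  } else if (length(dim(fishing)) == 3) {
    apply(fishing, 3, sum)
  } else colSums(fishing)
  out <- ifelse(d > 0, f / d, 0)
  if (any(d == 0))
    message("SSMU(s) with no allocated catch: violation probability reported as 0")
  out
}

#' Classify the magnitude of a counterfactual change
#'
#' Maps `delta = ratio - 1` to the comparison scale: |delta| < 0.01 "none";
#' 0.01 <= |delta| <= 0.10 "small"; 0.10 < |delta| <= 0.50 "medium";
#' |delta| > 0.50 "large".
#'
#' @param delta signed change(s), ratio minus 1.
#' @return factor with levels none < small < medium < large.
#' @export
classify_magnitude <- function(delta) {
  a <- abs(delta)
  cls <- ifelse(a < 0.01, "none",
                ifelse(a <= 0.10, "small",
                       ifelse(a <= 0.50, "medium", "large")))
  cls[is.na(delta)] <- NA
  factor(cls, levels = c("none", "small", "medium", "large"), ordered = TRUE)
}

# Cumulative quantity through the end of `years` (steps 0 .. 2*years - 1).
cum_through_year <- function(step_matrix, years) {
  colSums(step_matrix[seq_len(2L * years), , drop = FALSE])
}

#' Evaluate a paired scenario / base-case comparison
#'
#' Computes counterfactual ratios at the evaluation years (default 30 and
#' 100): predator abundance per group (adults at the end of the evaluation
#' year) at SSMU and arena scale; cumulative catch per SSMU and arena-wide;
#' and threshold-violation probabilities through the evaluation year, per
#' SSMU plus two documented arena aggregations ("arena_any": probability that
#' at least one fished SSMU violates in a season; "arena_weighted": the
#' catch-weighted mean of the SSMU probabilities).
#'
#' @param comparison list with `scenario` and `base` ensemble summaries, as
#'   returned by [run_comparison()].
#' @param years evaluation time slices in years.
#' @return a data frame of class `relative_outcome` with columns `scale`
#'   ("arena"/"ssmu"), `ssmu`, `metric`, `time_slice`, `scenario_value`,
#'   `base_value`, `ratio`, `delta`, `magnitude_class`.
#' @export
evaluate_comparison <- function(comparison, years = c(30, 100)) {
  scen <- comparison$scenario
  base <- comparison$base
  stopifnot(inherits(scen, "ensemble_summary"),
            inherits(base, "ensemble_summary"))
  map <- scen$ssmu_map
  n <- length(map$ssmu_ids)
  years <- as.integer(years)
  stopifnot(all(years >= 1), all(years <= scen$spec$horizon_years))

  rows <- list()
  add <- function(scale, ssmu, metric, year, sv, bv) {
    r <- suppressWarnings(relative_change(sv, bv))
    rows[[length(rows) + 1L]] <<- data.frame(
      scale = scale, ssmu = ssmu, metric = metric, time_slice = year,
      scenario_value = sv, base_value = bv, ratio = r, delta = r - 1,
      stringsAsFactors = FALSE)
  }

  for (y in years) {
    idx <- 2L * y + 1L  # state at the end of year y
    # predator abundance, per group
    for (g in unique(scen$groups)) {
      sel <- which(scen$groups == g)
      sv_pop <- scen$mean_adults[idx, sel]
      bv_pop <- base$mean_adults[idx, sel]
      ssmus <- match(scen$resident[sel], map$ssmu_ids)
      add("ssmu", map$ssmu_ids[ssmus], paste0("abundance_", g), y,
          sv_pop, bv_pop)
      add("arena", "arena", paste0("abundance_", g), y,
          sum(sv_pop), sum(bv_pop))
    }
    # cumulative catch
    sv_c <- cum_through_year(scen$mean_catch, y)
    bv_c <- cum_through_year(base$mean_catch, y)
    add("ssmu", map$ssmu_ids, "catch", y, sv_c, bv_c)
    add("arena", "arena", "catch", y, sum(sv_c), sum(bv_c))
    # threshold-violation probabilities
    steps <- seq_len(2L * y)
    vp <- function(e) {
      v <- colSums(e$violation_count[steps, , drop = FALSE])
      f <- colSums(e$fishing_count[steps, , drop = FALSE])
      ifelse(f > 0, v / f, 0)
    }
    add("ssmu", map$ssmu_ids, "violation_prob", y, vp(scen), vp(base))
    ap <- function(e) {
      v <- sum(e$arena_violation_count[steps])
      f <- sum(e$arena_fishing_count[steps])
      if (f > 0) v / f else 0
    }
    add("arena", "arena", "violation_prob_arena_any", y, ap(scen), ap(base))
    wp <- function(e, w) {
      p <- vp(e)
      if (sum(w) > 0) sum(p * w) / sum(w) else 0
    }
    add("arena", "arena", "violation_prob_arena_weighted", y,
        wp(scen, bv_c), wp(base, bv_c))
  }
  out <- do.call(rbind, rows)
  out$magnitude_class <- classify_magnitude(out$delta)
  class(out) <- c("relative_outcome", class(out))
  attr(out, "strategy") <- scen$spec$strategy
  out
}

#' Catch-versus-abundance trade-off records
#'
#' One record per (SSMU, predator group, time slice): the counterfactual
#' catch ratio, the abundance ratio, and a quadrant label relative to the
#' (1, 1) no-change point, as plotted in catch/abundance trade-off scatter
#' figures.
#'
#' @param outcome a `relative_outcome` data frame from
#'   [evaluate_comparison()].
#' @param open_ssmus SSMU ids to include (default: all SSMU-scale entries).
#' @return data frame with columns `ssmu`, `group`, `time_slice`,
#'   `catch_ratio`, `abundance_ratio`, `strategy`, `quadrant`.
#' @export
tradeoff_records <- function(outcome, open_ssmus = NULL) {
  ss <- outcome[outcome$scale == "ssmu", ]
  if (is.null(open_ssmus)) open_ssmus <- unique(ss$ssmu)
  catch <- ss[ss$metric == "catch" & ss$ssmu %in% open_ssmus, ]
  ab <- ss[grepl("^abundance_", ss$metric), ]
  groups <- sort(unique(sub("^abundance_", "", ab$metric)))
  out <- list()
  for (g in groups) {
    a <- ab[ab$metric == paste0("abundance_", g), ]
    for (y in unique(catch$time_slice)) {
      cy <- catch[catch$time_slice == y, ]
      ay <- a[a$time_slice == y, ]
      m <- match(cy$ssmu, ay$ssmu)
      out[[length(out) + 1L]] <- data.frame(
        ssmu = cy$ssmu, group = g, time_slice = y,
        catch_ratio = cy$ratio, abundance_ratio = ay$ratio[m],
        strategy = attr(outcome, "strategy") %||% NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, out)
  rec$quadrant <- tradeoff_quadrant(rec$catch_ratio, rec$abundance_ratio)
  rec
}

tradeoff_quadrant <- function(catch_ratio, abundance_ratio) {
  q <- rep(NA_character_, length(catch_ratio))
  more_c <- catch_ratio > 1
  less_c <- catch_ratio < 1
  more_a <- abundance_ratio > 1
  less_a <- abundance_ratio < 1
  q[more_c & more_a] <- "more catch, more predators"
  q[more_c & less_a] <- "more catch, fewer predators"
  q[less_c & more_a] <- "less catch, more predators"
  q[less_c & less_a] <- "less catch, fewer predators"
  q[catch_ratio == 1 & abundance_ratio == 1] <- "no change"
  q[catch_ratio == 1 & more_a] <- "equal catch, more predators"
  q[catch_ratio == 1 & less_a] <- "equal catch, fewer predators"
  q[abundance_ratio == 1 & more_c] <- "more catch, equal predators"
  q[abundance_ratio == 1 & less_c] <- "less catch, equal predators"
  q
}
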