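# Management strategies: catch-limit allocation, the two feedback rules
# (krill-density and penguin-change based), the MPA closure, and the
# reassessment scheduler.

#' Fishery controls
#'
#' The overall catch-limit machinery in force at a point in time: the initial
#' arena krill biomass B0 and harvest rate gamma that set the overall annual
#' limit, the allocation fractions p' per SSMU and season (summing to 1 over
#' all open cells), per-SSMU closures, and the allocated catch limits Theta
#' in individuals per SSMU and season.
#'
#' @param B0 initial arena krill biomass (g).
#' @param gamma harvest rate in [0, 1].
#' @param fractions SSMU x season matrix of allocation fractions.
#' @param closed logical per SSMU; TRUE where fishing is prohibited.
#' @param mean_mass mean individual krill mass (g) per SSMU used to convert
#'   the biomass limit to individuals.
#' @return object of class `fishery_controls`.
#' @export
fishery_controls <- function(B0, gamma, fractions, closed, mean_mass) {
  fractions <- as.matrix(fractions)
  colnames(fractions) <- c("summer", "winter")
  if (any(fractions[closed, ] != 0))
    stopf("allocation fractions must be 0 on closed SSMUs")
  tot <- sum(fractions)
  if (any(!closed) && abs(tot - 1) > 1e-9)
    stopf("allocation fractions must sum to 1 (sum = %.12g)", tot)
  structure(
    list(B0 = B0, gamma = gamma, fractions = fractions,
         closed = as.logical(closed),
         catch_limits = allocate_catch_limits(B0, gamma, fractions, mean_mass)),
    class = "fishery_controls")
}

#' Allocate catch limits among SSMUs
#'
#' The catch limit allocated to SSMU i, in individuals, is
#' `Theta_i = B0 * gamma * p'_i / wbar_i`: the overall biomass limit
#' (initial arena krill biomass times the harvest rate) distributed by the
#' allocation fractions and converted to numbers with the mean individual
#' mass.
#'
#' @param B0 initial arena krill biomass (g).
#' @param gamma harvest rate.
#' @param fractions allocation fractions p' (vector per SSMU, or SSMU x
#'   season matrix).
#' @param mean_mass mean individual krill mass (g) per SSMU, > 0.
#' @return catch limits Theta (individuals), same shape as `fractions`.
#' @export
allocate_catch_limits <- function(B0, gamma, fractions, mean_mass) {
  if (any(!is.finite(mean_mass)) || any(mean_mass <= 0))
    stopf("mean_mass must be positive")
  if (sum(fractions) > 1 + 1e-9)
    stopf("allocation fractions sum above 1")
  if (is.matrix(fractions)) B0 * gamma * fractions / mean_mass
  else B0 * gamma * fractions / mean_mass
}

#' Krill-density feedback allocation
#'
#' Rescales sampled per-SSMU krill densities to the unit interval for use as
#' allocation fractions: `p'_i = d_i / sum(d)`. SSMUs with the highest krill
#' density receive the largest catch limits.
#'
#' @param densities krill densities (g m^-2) per SSMU, >= 0.
#' @return allocation fractions summing to 1, or `NULL` when all densities
#'   are zero (degenerate indicator: the caller keeps the previous fractions).
#' @export
fbm_krill_fractions <- function(densities) {
  stopifnot(all(densities >= 0))
  tot <- sum(densities)
  if (tot == 0) return(NULL)
  densities / tot
}

#' Penguin-change feedback allocation
#'
#' Computes the change in breeding-penguin abundance per SSMU over the
#' reassessment interval, `dP_i = P_now_i - P_prev_i`, remaps it to be
#' non-negative with `p_i = dP_i + alpha * |min(dP)|`, and rescales to
#' allocation fractions `p'_i = p_i / sum(p)`. With `alpha = 1` the SSMU(s)
#' with the greatest decline receive p = 0 and are reported closed until the
#' next reassessment; ties are all closed. Only SSMUs with resident penguin
#' populations enter the indicator.
#'
#' @param P_now penguin abundance per (penguin-resident) SSMU at the
#'   reassessment step.
#' @param P_prev abundance one reassessment interval earlier.
#' @param alpha sensitivity scalar; values that would produce a negative
#'   remapped p (alpha < 1 with a declining SSMU) are rejected.
#' @return list with `fractions` (summing to 1) and `closed` (integer indices
#'   into the supplied vectors), or `NULL` when the remap sums to zero
#'   (degenerate indicator).
#' @export
fbm_pengs_fractions <- function(P_now, P_prev, alpha = 1.0) {
  stopifnot(length(P_now) == length(P_prev),
            all(P_now >= 0), all(P_prev >= 0))
  dP <- P_now - P_prev
  m <- min(dP)
  pvec <- dP + alpha * abs(m)
  if (any(pvec < -1e-9 * max(1, abs(m))))
    stopf("alpha = %.3g produces negative remapped allocations (min dP = %.4g); alpha >= 1 is required when any SSMU declines", alpha, m)
  pvec <- pmax(pvec, 0)
  tot <- sum(pvec)
  if (tot == 0) return(NULL)
  tol <- 1e-12 * max(pvec)
  closed <- if (m < 0) which(pvec <= tol) else integer(0)
  list(fractions = pvec / tot, closed = closed)
}

#' MPA allocation fractions
#'
#' Sets the allocation fractions of SSMUs inside the MPA mask to zero and
#' redistributes the displaced share across open cells in proportion to their
#' baseline fractions (the recent spatial and seasonal catch distribution).
#' If every open cell has baseline 0, the displaced share is spread uniformly
#' over the open cells.
#'
#' @param base baseline allocation fractions (SSMU x season matrix, or a
#'   vector per SSMU), summing to 1.
#' @param mpa_mask logical per SSMU; TRUE inside the MPA.
#' @return fractions of the same shape as `base`, summing to 1, exactly 0 on
#'   masked SSMUs.
#' @export
mpa_fractions <- function(base, mpa_mask) {
  if (!any(mpa_mask)) return(base)  # empty mask: exact identity
  vec <- !is.matrix(base)
  b <- if (vec) matrix(base, ncol = 1) else base
  if (all(mpa_mask)) stopf("MPA mask closes every SSMU: no open area remains")
  out <- b
  out[mpa_mask, ] <- 0
  open_total <- sum(out)
  if (open_total > 0) out <- out / open_total
  else out[!mpa_mask, ] <- 1 / (sum(!mpa_mask) * ncol(out))
  if (vec) as.vector(out) else out
}

#' Reassessment schedule
#'
#' Summer time steps at which the feedback rules reassess the catch
#' distribution: after `interval, 2*interval, ...` elapsed years, strictly
#' within the horizon. With two seasons per year, consecutive reassessments
#' are `2 * interval` time steps apart, which is also the lookback of the
#' penguin-change indicator.
#'
#' @param interval_years reassessment interval (years, >= 1).
#' @param horizon_years projection horizon (years).
#' @return integer vector of summer time steps (possibly empty).
#' @export
reassessment_times <- function(interval_years, horizon_years) {
  stopifnot(interval_years >= 1)
  k <- seq_len(max(0, (horizon_years - 1) %/% interval_years))
  as.integer(2 * interval_years * k)
}

# Split per-SSMU annual fractions into seasons, retaining each SSMU's
# baseline summer/winter proportions (0.5/0.5 where the baseline row is 0).
split_seasonal <- function(annual, base) {
  rs <- rowSums(base)
  share <- ifelse(rs > 0, base[, 1] / rs, 0.5)
  cbind(summer = annual * share, winter = annual * (1 - share))
}

#' Apply a management strategy to the fishery controls
#'
#' Called once at t = 0 for "none" and "mpa", and at every reassessment step
#' for the feedback strategies. The feedback rules produce per-SSMU annual
#' fractions from the monitored indicator, read from the true simulated state
#' without observation error; within each SSMU the summer/winter split of the
#' baseline distribution is retained. Catch limits in individuals are
#' recomputed from the new fractions with the current (trended) mean krill
#' mass. On a degenerate indicator the previous fractions are kept and the
#' event is recorded.
#'
#' Under "fbm_pengs", SSMUs without resident penguin populations receive
#' fraction 0 (the indicator is undefined there), and the worst-declining
#' SSMU(s) are closed until the next reassessment.
#'
#' @param strategy one of "none", "fbm_krill", "fbm_pengs", "mpa".
#' @param controls current [fishery_controls()].
#' @param p the [krill_parameterization()].
#' @param spec the [scenario_spec()].
#' @param mean_mass current mean individual krill mass (g) per SSMU.
#' @param densities current krill densities (g m^-2); required for
#'   "fbm_krill".
#' @param penguins_now,penguins_prev penguin abundance per SSMU (full-arena
#'   vectors; non-resident SSMUs NA or 0) at the reassessment step and one
#'   interval earlier; required for "fbm_pengs".
#' @param time_step the current time step (recorded in the reassessment
#'   record).
#' @return updated `fishery_controls`, with a `record` attribute describing
#'   the reassessment (indicator values, new fractions, closures, degeneracy).
#' @export
apply_strategy <- function(strategy, controls, p, spec, mean_mass,
                           densities = NULL, penguins_now = NULL,
                           penguins_prev = NULL, time_step = 0L) {
  n <- n_ssmu(p)
  rec <- list(time_step = time_step, strategy = strategy,
              indicator_values = NULL, new_fractions = NULL,
              closed_ssmu = character(0), degenerate = FALSE)
  if (strategy == "none") {
    attr(controls, "record") <- rec
    return(controls)
  }
  if (strategy == "mpa") {
    mask <- p$ssmu_map$mpa_mask
    fr <- mpa_fractions(p$base_catch_fractions, mask)
    controls <- fishery_controls(controls$B0, controls$gamma, fr, mask,
                                 mean_mass)
    rec$new_fractions <- rowSums(fr)
    rec$closed_ssmu <- p$ssmu_map$ssmu_ids[mask]
    attr(controls, "record") <- rec
    return(controls)
  }
  if (strategy == "fbm_krill") {
    if (is.null(densities)) stopf("fbm_krill requires densities")
    rec$indicator_values <- densities
    annual <- fbm_krill_fractions(densities)
    if (is.null(annual)) {
      rec$degenerate <- TRUE
      attr(controls, "record") <- rec
      return(controls)
    }
    fr <- split_seasonal(annual, p$base_catch_fractions)
    controls <- fishery_controls(controls$B0, controls$gamma, fr,
                                 rep(FALSE, n), mean_mass)
    rec$new_fractions <- annual
    attr(controls, "record") <- rec
    return(controls)
  }
  if (strategy == "fbm_pengs") {
    if (is.null(penguins_now) || is.null(penguins_prev))
      stopf("fbm_pengs requires penguin abundances now and one interval back")
    resident <- penguin_resident_index(p)
    if (!length(resident)) stopf("fbm_pengs requires resident penguin populations")
    res <- fbm_pengs_fractions(penguins_now[resident],
                               penguins_prev[resident], spec$alpha)
    rec$indicator_values <- penguins_now - penguins_prev
    if (is.null(res)) {
      rec$degenerate <- TRUE
      attr(controls, "record") <- rec
      return(controls)
    }
    annual <- numeric(n)
    annual[resident] <- res$fractions
    closed <- rep(FALSE, n)
    closed[resident[res$closed]] <- TRUE
    fr <- split_seasonal(annual, p$base_catch_fractions)
    fr[closed, ] <- 0
    controls <- fishery_controls(controls$B0, controls$gamma, fr, closed,
                                 mean_mass)
    rec$new_fractions <- annual
    rec$closed_ssmu <- p$ssmu_map$ssmu_ids[closed]
    attr(controls, "record") <- rec
    return(controls)
  }
  stopf("unknown strategy '%s'", strategy)
}

# SSMU indices (arena order) holding a resident penguin population.
penguin_resident_index <- function(p) {
  ids <- vapply(p$predator_populations, function(pop)
    if (pop$group == "penguins") pop$resident_ssmu else NA_character_, "")
  sort(match(ids[!is.na(ids)], p$ssmu_map$ssmu_ids))
}

#' Initial fishery controls for a scenario
#'
#' Builds the controls in force at t = 0: B0 is the summed initial krill
#' biomass, the fractions are the baseline catch distribution (masked and
#' renormalized for the MPA strategy, which is fixed for the whole run), and
#' catch limits are allocated with the initial mean mass.
#'
#' @param p a [krill_parameterization()].
#' @param spec a [scenario_spec()].
#' @return a `fishery_controls` object.
#' @export
init_controls <- function(p, spec) {
  n <- n_ssmu(p)
  B0 <- sum(p$initial_krill_biomass)
  controls <- fishery_controls(B0, spec$gamma, p$base_catch_fractions,
                               rep(FALSE, n), p$initial_mean_mass)
  if (spec$strategy == "mpa")
    controls <- apply_strategy("mpa", controls, p, spec,
                               p$initial_mean_mass, time_step = 0L)
  controls
}
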