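#' Predator population
#'
#' One krill-dependent predator population: a group (penguins, seals, whales
#' or fish) resident in a single SSMU, foraging across SSMUs with a
#' season-specific distribution. Demography is a seasonal recursion: constant
#' adult survival, breeding each summer scaled by foraging success, and a
#' maturation delay of `recruit_lag` whole years.
#'
#' @param group one of "penguins", "seals", "whales", "fish".
#' @param resident_ssmu SSMU id the population is resident in.
#' @param initial_adults initial adult abundance (count).
#' @param per_capita_demand numeric length-2 (summer, winter): grams of krill
#'   demanded per adult per season.
#' @param foraging_dist matrix with one row per SSMU and columns
#'   `summer`, `winter`; each column non-negative and summing to 1.
#' @param adult_survival per-season adult survival fraction.
#' @param max_recruits_per_breeder recruits produced per adult at full
#'   foraging success (dimensionless).
#' @param recruit_lag whole years from birth to recruitment to the adult
#'   class (>= 1).
#' @return an object of class `predator_population`.
#' @export
predator_population <- function(group, resident_ssmu, initial_adults,
                                per_capita_demand, foraging_dist,
                                adult_survival, max_recruits_per_breeder,
                                recruit_lag) {
  foraging_dist <- as.matrix(foraging_dist)
  colnames(foraging_dist) <- c("summer", "winter")
  structure(
    list(group = group, resident_ssmu = as.character(resident_ssmu),
         initial_adults = as.numeric(initial_adults),
         per_capita_demand = as.numeric(per_capita_demand),
         foraging_dist = foraging_dist,
         adult_survival = as.numeric(adult_survival),
         max_recruits_per_breeder = as.numeric(max_recruits_per_breeder),
         recruit_lag = as.integer(recruit_lag)),
    class = "predator_population")
}

PREDATOR_GROUPS <- c("penguins", "seals", "whales", "fish")

#' Model parameterization
#'
#' Everything defining one ecosystem instance: SSMU geometry, initial krill
#' stocks and mean individual mass, the climate-driven mass trend, krill
#' demographic rates, movement matrices, the predator populations, the
#' breeder-response mode, and the baseline spatial/seasonal catch
#' distribution.
#'
#' Seasonal quantities are stored as matrices with one row per SSMU and
#' columns `summer`, `winter`. `base_catch_fractions` sums to 1 over all
#' SSMU-by-season cells. Movement matrices are row-stochastic with rows as
#' source SSMUs; `movement_mode = "none"` forces identity matrices.
#'
#' @param ssmu_map an [ssmu_map()].
#' @param initial_krill_biomass grams of krill per SSMU at the start.
#' @param initial_mean_mass mean individual krill mass (g) per SSMU.
#' @param mass_trend per-SSMU fractional change in mean mass per year
#'   (yr^-1; negative under warming).
#' @param krill_recruit_rate per-SSMU summer production fraction in [0, 1].
#' @param krill_recruit_sigma log-scale SD of the median-1 lognormal
#'   recruitment deviate (0 gives the deterministic model).
#' @param krill_survival matrix (SSMU x season) of per-season krill survival
#'   fractions.
#' @param movement_matrices list with elements `summer` and `winter`, each a
#'   row-stochastic SSMU x SSMU matrix.
#' @param movement_mode "none" or "drift".
#' @param predator_populations list of [predator_population()] objects.
#' @param breeder_response "linear" or "hyperstable".
#' @param hyperstable_halfsat half-saturation constant c > 0 used when
#'   `breeder_response = "hyperstable"`.
#' @param base_catch_fractions matrix (SSMU x season) of baseline catch
#'   allocation fractions summing to 1 overall.
#' @param id character identifier for the parameterization.
#' @return an object of class `krill_parameterization`.
#' @seealso [validate_parameterization()], [load_parameterization()]
#' @export
krill_parameterization <- function(ssmu_map, initial_krill_biomass,
                                   initial_mean_mass, mass_trend,
                                   krill_recruit_rate, krill_recruit_sigma,
                                   krill_survival, movement_matrices,
                                   movement_mode, predator_populations,
                                   breeder_response, hyperstable_halfsat,
                                   base_catch_fractions, id = "unnamed") {
  krill_survival <- as.matrix(krill_survival)
  base_catch_fractions <- as.matrix(base_catch_fractions)
  colnames(krill_survival) <- colnames(base_catch_fractions) <-
    c("summer", "winter")
  names(movement_matrices) <- c("summer", "winter")
  structure(
    list(ssmu_map = ssmu_map,
         initial_krill_biomass = as.numeric(initial_krill_biomass),
         initial_mean_mass = as.numeric(initial_mean_mass),
         mass_trend = as.numeric(mass_trend),
         krill_recruit_rate = as.numeric(krill_recruit_rate),
         krill_recruit_sigma = as.numeric(krill_recruit_sigma),
         krill_survival = krill_survival,
         movement_matrices = movement_matrices,
         movement_mode = movement_mode,
         predator_populations = predator_populations,
         breeder_response = breeder_response,
         hyperstable_halfsat = as.numeric(hyperstable_halfsat),
         base_catch_fractions = base_catch_fractions,
         id = as.character(id)),
    class = "krill_parameterization")
}

frac_ok <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)

check_parameterization <- function(p) {
  out <- check_ssmu_map(p$ssmu_map)
  n <- length(p$ssmu_map$ssmu_ids)
  chk_len <- function(x, nm) {
    if (length(x) != n) c(sprintf("%s must have one value per SSMU", nm))
    else character(0)
  }
  out <- c(out,
           chk_len(p$initial_krill_biomass, "initial_krill_biomass"),
           chk_len(p$initial_mean_mass, "initial_mean_mass"),
           chk_len(p$mass_trend, "mass_trend"),
           chk_len(p$krill_recruit_rate, "krill_recruit_rate"))
  if (any(!is.finite(p$initial_krill_biomass)) ||
      any(p$initial_krill_biomass < 0))
    out <- c(out, "initial_krill_biomass must be finite and >= 0")
  if (any(!is.finite(p$initial_mean_mass)) || any(p$initial_mean_mass <= 0))
    out <- c(out, "initial_mean_mass must be finite and > 0")
  if (any(!is.finite(p$mass_trend)))
    out <- c(out, "mass_trend must be finite")
  if (!frac_ok(p$krill_recruit_rate))
    out <- c(out, "krill_recruit_rate must lie in [0, 1]")
  if (!is.finite(p$krill_recruit_sigma) || p$krill_recruit_sigma < 0)
    out <- c(out, "krill_recruit_sigma must be finite and >= 0")
  if (!all(dim(p$krill_survival) == c(n, 2)) || !frac_ok(p$krill_survival))
    out <- c(out, "krill_survival must be an SSMU x 2 matrix of fractions in [0, 1]")
  if (!p$movement_mode %in% c("none", "drift"))
    out <- c(out, "movement_mode must be 'none' or 'drift'")
  for (s in c("summer", "winter")) {
    M <- p$movement_matrices[[s]]
    if (is.null(M) || !all(dim(M) == c(n, n))) {
      out <- c(out, sprintf("movement matrix '%s' must be %d x %d", s, n, n))
      next
    }
    rs <- rowSums(M)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      out <- c(out, sprintf(
        "movement matrix '%s' rows not summing to 1: %s (sums %s)", s,
        paste(bad, collapse = ", "),
        paste(format(rs[bad], digits = 6), collapse = ", ")))
    if (any(M < 0)) out <- c(out, sprintf("movement matrix '%s' has negative entries", s))
    if (p$movement_mode == "none" && !isTRUE(all.equal(M, diag(n), check.attributes = FALSE)))
      out <- c(out, sprintf("movement_mode 'none' requires identity movement matrix '%s'", s))
  }
  bc <- p$base_catch_fractions
  if (!all(dim(bc) == c(n, 2)) || any(!is.finite(bc)) || any(bc < 0))
    out <- c(out, "base_catch_fractions must be a non-negative SSMU x 2 matrix")
  else if (abs(sum(bc) - 1) > 1e-9)
    out <- c(out, sprintf("base_catch_fractions must sum to 1 over all cells (sum = %.12g)", sum(bc)))
  if (!p$breeder_response %in% c("linear", "hyperstable"))
    out <- c(out, "breeder_response must be 'linear' or 'hyperstable'")
  if (p$breeder_response == "hyperstable" &&
      (!is.finite(p$hyperstable_halfsat) || p$hyperstable_halfsat <= 0))
    out <- c(out, "hyperstable_halfsat must be > 0 under the hyperstable response")
  for (j in seq_along(p$predator_populations)) {
    pop <- p$predator_populations[[j]]
    tag <- sprintf("predator %d (%s in SSMU %s)", j, pop$group, pop$resident_ssmu)
    if (!pop$group %in% PREDATOR_GROUPS)
      out <- c(out, sprintf("%s: unknown group", tag))
    if (!pop$resident_ssmu %in% p$ssmu_map$ssmu_ids)
      out <- c(out, sprintf("%s: resident_ssmu not in ssmu_map", tag))
    if (!is.finite(pop$initial_adults) || pop$initial_adults < 0)
      out <- c(out, sprintf("%s: initial_adults must be >= 0", tag))
    if (length(pop$per_capita_demand) != 2 ||
        any(!is.finite(pop$per_capita_demand)) || any(pop$per_capita_demand < 0))
      out <- c(out, sprintf("%s: per_capita_demand must be length-2 and >= 0", tag))
    fd <- pop$foraging_dist
    if (!all(dim(fd) == c(n, 2)) || any(!is.finite(fd)) || any(fd < 0))
      out <- c(out, sprintf("%s: foraging_dist must be a non-negative SSMU x 2 matrix", tag))
    else if (any(abs(colSums(fd) - 1) > 1e-9))
      out <- c(out, sprintf("%s: foraging_dist columns must each sum to 1", tag))
    if (!frac_ok(pop$adult_survival) || length(pop$adult_survival) != 1)
      out <- c(out, sprintf("%s: adult_survival must be a fraction in [0, 1]", tag))
    if (!is.finite(pop$max_recruits_per_breeder) || pop$max_recruits_per_breeder < 0)
      out <- c(out, sprintf("%s: max_recruits_per_breeder must be >= 0", tag))
    if (is.na(pop$recruit_lag) || pop$recruit_lag < 1)
      out <- c(out, sprintf("%s: recruit_lag must be a whole number of years >= 1", tag))
  }
  out
}

#' Validate a parameterization
#'
#' Checks every structural invariant (positive areas, row-stochastic movement,
#' unit-sum catch and foraging fractions, rates within [0, 1], ...) and, on
#' failure, raises a single error listing all violations. Validation never
#' silently repairs a value.
#'
#' @param p a [krill_parameterization()].
#' @return `p`, invisibly, if valid.
#' @export
validate_parameterization <- function(p) {
  if (!inherits(p, "krill_parameterization"))
    stopf("not a krill_parameterization")
  problems <- check_parameterization(p)
  if (length(problems))
    stopf("invalid parameterization '%s':\n- %s", p$id,
          paste(problems, collapse = "\n- "))
  invisible(p)
}

#' @export
print.krill_parameterization <- function(x, ...) {
  grp <- table(vapply(x$predator_populations, `[[`, "", "group"))
  cat(sprintf(
    "krill_parameterization '%s': %d SSMUs, movement '%s', breeder response '%s'\n",
    x$id, length(x$ssmu_map$ssmu_ids), x$movement_mode, x$breeder_response))
  cat(sprintf("  arena krill biomass %.4g g; predators: %s\n",
              sum(x$initial_krill_biomass),
              paste(sprintf("%s (%d)", names(grp), grp), collapse = ", ")))
  invisible(x)
}
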