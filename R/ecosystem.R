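# Seasonal delay-difference update for krill and predators.
#
# Within-season operation order (chosen so krill biomass at the start of a
# step reflects recruitment, mortality and movement, and the density
# threshold is evaluated on pre-harvest biomass):
#   (1) climate trend on mean individual krill mass;
#   (2) summer-only stochastic recruitment;
#   (3) krill movement;
#   (4) density-threshold check and fishery suspension per SSMU;
#   (5) demand assembly (predators via foraging matrices, fishery via
#       allocated catch limits in individuals times current mean mass);
#   (6) proportional rationing of predator and fishery demand;
#   (7) krill survival applied to post-consumption biomass;
#   (8) predator demography.

# Floor on the mass-trend multiplier, keeping mean mass positive however
# strong the trend.
MASS_TREND_FLOOR <- 0.1

#' Climate-driven trend in mean individual krill mass
#'
#' Mean mass declines (or grows) linearly in years from its initial value:
#' `w(year) = mass0 * max(floor, 1 + trend * year)`, with a small positive
#' floor so mass never becomes non-positive. Warming scenarios use negative
#' trends (reduced gross growth potential of krill).
#'
#' @param mass0 initial mean individual mass (g) per SSMU.
#' @param trend fractional change per year (yr^-1) per SSMU.
#' @param year whole years elapsed since the start of the run.
#' @return trended mean mass (g) per SSMU.
#' @export
apply_mass_trend <- function(mass0, trend, year) {
  stopifnot(all(mass0 > 0))
  mass0 * pmax(MASS_TREND_FLOOR, 1 + trend * year)
}

#' Krill density
#'
#' @param K krill biomass (g) per SSMU.
#' @param A SSMU areas (m^2), strictly positive.
#' @return density in g m^-2 per SSMU.
#' @export
krill_density <- function(K, A) {
  if (any(!is.finite(A)) || any(A <= 0)) stopf("areas must be positive")
  K / A
}

#' Stochastic krill recruitment (summer)
#'
#' Recruitment biomass per SSMU is `R_i = rate_i * K_i * eps_i`, where
#' `eps_i` is a median-1 lognormal deviate (log-SD `sigma`) drawn
#' independently per SSMU per year. With `sigma = 0` the deviate is exactly 1
#' and no random numbers are consumed, so the deterministic limit is exact.
#'
#' @param K krill biomass (g) per SSMU.
#' @param rate per-SSMU production fraction in [0, 1].
#' @param sigma log-scale SD of the recruitment deviate.
#' @return recruitment biomass (g) per SSMU.
#' @export
recruit_krill <- function(K, rate, sigma) {
  eps <- if (sigma > 0) stats::rlnorm(length(K), 0, sigma) else rep(1, length(K))
  rate * K * eps
}

#' Redistribute krill biomass along a movement matrix
#'
#' Rows of `M` are source SSMUs, so the moved vector is `t(M) %*% K`. A
#' row-stochastic `M` conserves total biomass exactly.
#'
#' @param K krill biomass (g) per SSMU.
#' @param M row-stochastic SSMU x SSMU matrix.
#' @return moved biomass (g) per SSMU.
#' @export
move_krill <- function(K, M) {
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9) || any(M < 0))
    stopf("movement matrix is not row-stochastic")
  as.vector(crossprod(M, K))
}

#' Proportional rationing of predator and fishery demand
#'
#' Competition arises when available krill is insufficient to satisfy the
#' combined demand of predators and the fishery. Both consumers are rationed
#' symmetrically by the per-SSMU scaling
#' `lambda_i = min(1, available_i / (predator_demand_i + fishery_demand_i))`,
#' with `lambda_i = 1` when total demand is zero; realized consumption is
#' `lambda * demand` for every consumer.
#'
#' @param available krill biomass (g) available per SSMU.
#' @param predator_demand predator demand (g) per SSMU.
#' @param fishery_demand fishery demand (g) per SSMU.
#' @return list with `lambda`, `realized_predation`, `realized_catch`.
#' @export
resolve_competition <- function(available, predator_demand, fishery_demand) {
  stopifnot(all(available >= 0), all(predator_demand >= 0),
            all(fishery_demand >= 0))
  total <- predator_demand + fishery_demand
  lambda <- ifelse(total > 0, pmin(1, available / total), 1)
  list(lambda = lambda,
       realized_predation = lambda * predator_demand,
       realized_catch = lambda * fishery_demand)
}

#' Foraging success of a predator population
#'
#' The fraction of a population's seasonal demand that was satisfied:
#' the foraging-distribution-weighted mean of the per-SSMU rationing
#' coefficients, `x = sum_i f_i * lambda_i`, in [0, 1].
#'
#' @param foraging_dist non-negative weights per SSMU summing to 1.
#' @param lambda per-SSMU rationing coefficients in [0, 1].
#' @return scalar foraging success x in [0, 1].
#' @export
foraging_success <- function(foraging_dist, lambda) {
  sum(foraging_dist * lambda)
}

#' Effective breeder fraction
#'
#' Maps foraging success x to the fraction of adults that breed effectively.
#' `linear` is the identity; `hyperstable` is `x * (1 + c) / (x + c)`, which
#' keeps breeding output high until krill shortage is severe. Both satisfy
#' e(0) = 0, e(1) = 1, and the hyperstable curve dominates the linear one on
#' (0, 1).
#'
#' @param x foraging success in [0, 1] (vectorized).
#' @param mode "linear" or "hyperstable".
#' @param c half-saturation constant (> 0), hyperstable mode only.
#' @return effective breeder fraction(s) in [0, 1].
#' @export
effective_breeder_fraction <- function(x, mode = c("linear", "hyperstable"),
                                       c = NULL) {
  mode <- match.arg(mode)
  if (mode == "linear") return(x)
  if (is.null(c) || !is.finite(c) || c <= 0)
    stopf("hyperstable mode requires half-saturation c > 0")
  x * (1 + c) / (x + c)
}

# --- state -------------------------------------------------------------

#' Initial ecosystem state
#'
#' Builds the state at time step 0: initial krill biomass and mean mass per
#' SSMU, initial adult abundances, and pending-recruit queues (one slot per
#' year of `recruit_lag`) initialized at the stationary cohort size
#' `adults * max_recruits_per_breeder`, i.e. breeding at full foraging
#' success. A population whose survival and fecundity balance
#' (`survival^2 + max_recruits = 1`) therefore starts at demographic
#' equilibrium.
#'
#' @param p a [krill_parameterization()].
#' @return an object of class `ecosystem_state`.
#' @export
init_state <- function(p) {
  adults <- vapply(p$predator_populations, `[[`, 0, "initial_adults")
  pending <- lapply(p$predator_populations, function(pop)
    rep(pop$initial_adults * pop$max_recruits_per_breeder, pop$recruit_lag))
  structure(
    list(t = 0L,
         krill_biomass = p$initial_krill_biomass,
         mean_mass = p$initial_mean_mass,
         predator_adults = adults,
         pending_recruits = pending),
    class = "ecosystem_state")
}

# Per-trial cache of population-level matrices, so step_season avoids
# re-walking the predator list at every step.
build_pop_cache <- function(p) {
  pops <- p$predator_populations
  np <- length(pops)
  n <- n_ssmu(p)
  fmat <- list(
    summer = t(vapply(pops, function(x) x$foraging_dist[, 1], numeric(n))),
    winter = t(vapply(pops, function(x) x$foraging_dist[, 2], numeric(n))))
  if (np == 0) fmat <- list(summer = matrix(0, 0, n), winter = matrix(0, 0, n))
  list(n_pop = np,
       fmat = fmat,
       demand = matrix(vapply(pops, `[[`, numeric(2), "per_capita_demand"),
                       nrow = 2),  # 2 x n_pop (summer; winter)
       survival = vapply(pops, `[[`, 0, "adult_survival"),
       max_recruits = vapply(pops, `[[`, 0, "max_recruits_per_breeder"),
       group = vapply(pops, `[[`, "", "group"),
       resident = vapply(pops, `[[`, "", "resident_ssmu"))
}

#' Predator demographic update
#'
#' Seasonal recursion: `adults[t+1] = survival * adults[t] + maturing`, where
#' a cohort matures only in summer, `recruit_lag` years after it was bred.
#' Each summer a new cohort `adults * e(x_summer) * max_recruits_per_breeder`
#' enters the pending queue, with e() the effective breeder fraction.
#'
#' @param state an `ecosystem_state`.
#' @param x per-population foraging success this season.
#' @param p a [krill_parameterization()].
#' @param cache internal population cache (optional).
#' @return the state with `predator_adults` and `pending_recruits` advanced
#'   one season (the time counter is advanced by [step_season()]).
#' @export
update_predators <- function(state, x, p, cache = NULL) {
  if (is.null(cache)) cache <- build_pop_cache(p)
  adults <- state$predator_adults
  if (cache$n_pop == 0) return(state)
  if (is_summer(state$t)) {
    e <- effective_breeder_fraction(x, p$breeder_response,
                                    p$hyperstable_halfsat)
    newcohort <- adults * e * cache$max_recruits
    maturing <- numeric(cache$n_pop)
    for (j in seq_len(cache$n_pop)) {
      q <- state$pending_recruits[[j]]
      maturing[j] <- q[1]
      state$pending_recruits[[j]] <- c(q[-1], newcohort[j])
    }
    adults <- cache$survival * adults + maturing
  } else {
    adults <- cache$survival * adults
  }
  state$predator_adults <- pmax(adults, 0)
  state
}

#' Advance the ecosystem one season
#'
#' Applies the full within-season sequence documented above and returns the
#' updated state together with the season's outcome (realized catch and
#' predation per SSMU, per-population foraging success, rationing
#' coefficients, and threshold-violation flags). Deterministic given the
#' state, controls and RNG stream position; with `krill_recruit_sigma = 0`
#' no random numbers are consumed.
#'
#' A threshold violation is flagged in an SSMU when catch is allocated there
#' this season but pre-harvest krill density is below
#' `spec$density_threshold`; the fishery then suspends operations (its demand
#' is forgone, not redistributed).
#'
#' @param state an `ecosystem_state`.
#' @param p a [krill_parameterization()].
#' @param controls a [fishery_controls()] object.
#' @param spec a [scenario_spec()].
#' @param cache internal population cache (optional; built if missing).
#' @return list with elements `state` (advanced one step) and `outcome`.
#' @export
step_season <- function(state, p, controls, spec, cache = NULL) {
  if (is.null(cache)) cache <- build_pop_cache(p)
  t <- state$t
  s <- season_of(t) + 1L  # 1 = summer, 2 = winter
  n <- n_ssmu(p)
  areas <- p$ssmu_map$areas

  # (1) mass trend
  w <- if (spec$climate_trend)
    apply_mass_trend(p$initial_mean_mass, p$mass_trend, year_of(t))
  else p$initial_mean_mass

  # (2) summer recruitment
  K <- state$krill_biomass
  if (s == 1L)
    K <- K + recruit_krill(K, p$krill_recruit_rate, p$krill_recruit_sigma)

  # (3) movement
  K <- as.vector(crossprod(p$movement_matrices[[s]], K))

  # (4) threshold check and fishery suspension
  dens <- K / areas
  theta <- controls$catch_limits[, s]
  fishing <- theta > 0 & !controls$closed
  violations <- fishing & dens < spec$density_threshold
  fishery_demand <- ifelse(fishing & !violations, theta * w, 0)

  # (5) predator demand via foraging matrices
  fmat <- cache$fmat[[s]]
  percap <- state$predator_adults * cache$demand[s, ]
  predator_demand <- if (cache$n_pop > 0) as.vector(crossprod(fmat, percap))
  else numeric(n)

  # (6) proportional rationing
  ration <- resolve_competition(K, predator_demand, fishery_demand)
  x <- if (cache$n_pop > 0) as.vector(fmat %*% ration$lambda) else numeric(0)

  # (7) krill survival on post-consumption biomass
  K_next <- p$krill_survival[, s] *
    (K - ration$realized_catch - ration$realized_predation)
  K_next <- pmax(K_next, 0)  # guard against floating-point undershoot

  # (8) predator demography
  state <- update_predators(state, x, p, cache)
  state$krill_biomass <- K_next
  state$mean_mass <- w
  state$t <- t + 1L

  outcome <- list(t = t,
                  realized_catch = ration$realized_catch,
                  realized_predation = ration$realized_predation,
                  foraging_success = x,
                  lambda = ration$lambda,
                  violations = violations,
                  fishing = fishing,
                  density = dens)
  list(state = state, outcome = outcome)
}
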