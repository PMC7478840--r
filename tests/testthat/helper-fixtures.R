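# Fixtures built in code: a hand-sized toy arena and the default synthetic
# Antarctic-style setup (generated once per test run).

toy_penguins <- function(res, n, adults = 1000, demand = c(100, 50),
                         survival = 0.9, fecundity = NULL, lag = 2L) {
  local <- numeric(n)
  local[res] <- 1
  predator_population(
    group = "penguins", resident_ssmu = as.character(res),
    initial_adults = adults, per_capita_demand = demand,
    foraging_dist = cbind(summer = local, winter = local),
    adult_survival = survival,
    max_recruits_per_breeder = fecundity %||% ((1 - survival^2) / survival),
    recruit_lag = lag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_param <- function(n = 2, recruit_rate = 0.5, sigma = 0, survival = 0.8,
                      areas = rep(1e10, n), density = rep(20, n),
                      mass = rep(0.5, n), trend = rep(0, n),
                      movement_mode = "none", movement = NULL,
                      catch_fractions = NULL, predators = list(),
                      breeder = "linear", halfsat = 0.2, id = "toy") {
  if (is.null(movement)) movement <- diag(n)
  if (is.null(catch_fractions))
    catch_fractions <- matrix(1 / (2 * n), n, 2)
  krill_parameterization(
    ssmu_map = ssmu_map(as.character(seq_len(n)), areas,
                        rep("48.1", n)),
    initial_krill_biomass = density * areas,
    initial_mean_mass = mass,
    mass_trend = trend,
    krill_recruit_rate = rep(recruit_rate, length.out = n),
    krill_recruit_sigma = sigma,
    krill_survival = matrix(survival, n, 2),
    movement_matrices = list(summer = movement, winter = movement),
    movement_mode = movement_mode,
    predator_populations = predators,
    breeder_response = breeder,
    hyperstable_halfsat = halfsat,
    base_catch_fractions = catch_fractions,
    id = id)
}

# Small random-but-valid parameterizations for property tests.
random_small_param <- function(seed, n = NULL, sigma = 0) {
  opts <- generator_options(
    n_ssmus = n %||% (3 + seed %% 4), seed = seed,
    predator_occupancy = "random", krill_recruit_sigma = sigma)
  generate_parameterization(opts)
}

# Default Antarctic-style setup, shared across test files.
DEFAULT_P <- generate_parameterization(generator_options())
DEFAULT_P$ssmu_map$mpa_mask <- generate_mpa_mask(DEFAULT_P, coverage = 0.5)
DEFAULT_REFSET <- generate_reference_set(DEFAULT_P)

quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(strategy = "none", horizon_years = 100,
                   reassess_interval_years = 5, n_trials = 2, seed = 1)
  do.call(scenario_spec, utils::modifyList(defaults, args))
}
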