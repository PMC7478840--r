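#' Scenario specification
#'
#' Defines one management scenario: which strategy is in force, the projection
#' horizon, the reassessment interval of the feedback rules, the sensitivity
#' scalar of the penguin rule, the krill-density threshold below which the
#' fishery suspends operations in an SSMU, the harvest rate setting the
#' overall catch limit, whether the climate-driven krill-mass trend is active,
#' and the Monte-Carlo ensemble size and base seed.
#'
#' @param strategy one of "none", "fbm_krill", "fbm_pengs", "mpa".
#' @param horizon_years projection horizon in years (default 100; two
#'   seasonal time steps per year).
#' @param reassess_interval_years years between feedback reassessments
#'   (default 5).
#' @param alpha sensitivity scalar of the penguin-change remap (default 1.0;
#'   with 1.0 the worst-declining SSMU receives fraction 0 and is closed).
#' @param density_threshold krill density (g m^-2) below which the fishery
#'   suspends operations in an SSMU (default 15).
#' @param gamma harvest rate applied to initial arena krill biomass to set
#'   the overall annual catch limit (default 0.093, the fully developed
#'   fishery).
#' @param climate_trend logical; apply the per-SSMU linear trend in mean
#'   individual krill mass (default TRUE).
#' @param n_trials Monte-Carlo trials per parameterization (default 1001).
#' @param seed base RNG seed for the ensemble (default 1).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(strategy = "none", horizon_years = 100L,
                          reassess_interval_years = 5L, alpha = 1.0,
                          density_threshold = 15, gamma = 0.093,
                          climate_trend = TRUE, n_trials = 1001L, seed = 1L) {
  spec <- structure(
    list(strategy = strategy, horizon_years = as.integer(horizon_years),
         reassess_interval_years = as.integer(reassess_interval_years),
         alpha = as.numeric(alpha),
         density_threshold = as.numeric(density_threshold),
         gamma = as.numeric(gamma), climate_trend = isTRUE(climate_trend),
         n_trials = as.integer(n_trials), seed = as.integer(seed)),
    class = "scenario_spec")
  problems <- check_scenario_spec(spec)
  if (length(problems))
    stopf("invalid scenario_spec:\n- %s", paste(problems, collapse = "\n- "))
  spec
}

STRATEGIES <- c("none", "fbm_krill", "fbm_pengs", "mpa")

check_scenario_spec <- function(spec) {
  p <- character(0)
  if (!spec$strategy %in% STRATEGIES)
    p <- c(p, sprintf("unknown strategy '%s'", spec$strategy))
  if (is.na(spec$reassess_interval_years) || spec$reassess_interval_years < 1)
    p <- c(p, "reassess_interval_years must be >= 1")
  if (is.na(spec$horizon_years) ||
      spec$horizon_years < spec$reassess_interval_years)
    p <- c(p, "horizon_years must be >= reassess_interval_years")
  if (!is.finite(spec$gamma) || spec$gamma < 0 || spec$gamma > 1)
    p <- c(p, "gamma must lie in [0, 1]")
  if (!is.finite(spec$density_threshold) || spec$density_threshold < 0)
    p <- c(p, "density_threshold must be >= 0")
  if (!is.finite(spec$alpha)) p <- c(p, "alpha must be finite")
  if (is.na(spec$n_trials) || spec$n_trials < 1)
    p <- c(p, "n_trials must be >= 1")
  p
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario_spec: strategy '%s', %d yr, reassess every %d yr, alpha %.3g,\n  threshold %.3g g/m^2, gamma %.3g, climate trend %s, %d trials (seed %d)\n",
    x$strategy, x$horizon_years, x$reassess_interval_years, x$alpha,
    x$density_threshold, x$gamma, if (x$climate_trend) "on" else "off",
    x$n_trials, x$seed))
  invisible(x)
}
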