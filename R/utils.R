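# Time-step conventions: two seasons per year; step t = 2*(year-1) + s with
# s = 0 (summer), s = 1 (winter); the summer of year 1 is t = 0.

#' Season of a time step
#'
#' @param t integer time step(s), starting at 0.
#' @return 0 for summer, 1 for winter.
#' @export
season_of <- function(t) as.integer(t) %% 2L

#' Year index of a time step
#'
#' Counts whole years elapsed since the start of the run (year 0 for steps
#' 0 and 1, year 1 for steps 2 and 3, ...). Used by the krill mass trend.
#'
#' @param t integer time step(s).
#' @return integer year index.
#' @export
year_of <- function(t) as.integer(t) %/% 2L

is_summer <- function(t) season_of(t) == 0L

#' Deterministic per-trial seed
#'
#' Stable arithmetic hash mapping (base seed, parameterization index, trial
#' index) to a seed below 2^31, so ensembles are reproducible across machines
#' and invariant to trial execution order. All intermediate products stay
#' below 2^53 and are exact in double precision.
#'
#' @param base_seed integer base seed.
#' @param param_index 1-based parameterization index.
#' @param trial_index 1-based trial index.
#' @return a single integer seed in [1, 2147483646].
#' @export
trial_seed <- function(base_seed, param_index, trial_index) {
  s <- (abs(base_seed) %% 2147483647) * 97 +
    param_index * 1048573 + trial_index * 131
  s <- s %% 2147483647
  if (s == 0) s <- 1
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
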