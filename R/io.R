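# Parameterization and results I/O.
#
# A parameterization is stored as a directory holding one human-readable YAML
# document (scalars and schema version) plus delimited tables: a per-SSMU
# table, a predator table, per-season movement matrices and foraging
# matrices, and the baseline catch-fraction table. All fractions are stored
# as decimals, never percent; numbers are written with 17 significant digits
# so a load/save round trip is exact.

SCHEMA_VERSION <- "1.0"

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv_num <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("missing file '%s'", path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
}

write_matrix_tsv <- function(M, ids, path) {
  df <- as.data.frame(M)
  names(df) <- ids
  write_tsv_num(cbind(data.frame(row_id = rownames(M) %||% ids), df), path)
}

read_matrix_tsv <- function(path, ids) {
  df <- read_tsv(path)
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(M), as.character(ids)))
    stopf("'%s': column ids do not match the SSMU map", path)
  storage.mode(M) <- "double"
  dimnames(M) <- NULL
  M
}

#' Save a parameterization to a config directory
#'
#' Writes a validated parameterization as a directory of diffable text files:
#' `parameterization.yaml` (schema version, id, modes, scalars),
#' `ssmu_table.tsv` (per-SSMU geometry, stocks, rates, catch fractions),
#' `predators.tsv`, `foraging_summer.tsv` / `foraging_winter.tsv`,
#' and `movement_summer.tsv` / `movement_winter.tsv`. Refuses to write an
#' invalid parameterization. The output round-trips exactly through
#' [load_parameterization()], and saving a reloaded copy reproduces the files
#' byte for byte.
#'
#' @param p a [krill_parameterization()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_parameterization <- function(p, path) {
  validate_parameterization(p)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- p$ssmu_map
  header <- list(
    schema_version = SCHEMA_VERSION,
    id = p$id,
    movement_mode = p$movement_mode,
    breeder_response = p$breeder_response,
    hyperstable_halfsat = fmt_num(p$hyperstable_halfsat),
    krill_recruit_sigma = fmt_num(p$krill_recruit_sigma))
  writeLines(yaml::as.yaml(header), file.path(path, "parameterization.yaml"))
  write_tsv_num(data.frame(
    ssmu_id = m$ssmu_ids, subarea = m$subarea, area_m2 = m$areas,
    mpa = m$mpa_mask,
    initial_krill_biomass_g = p$initial_krill_biomass,
    initial_mean_mass_g = p$initial_mean_mass,
    mass_trend_per_yr = p$mass_trend,
    krill_recruit_rate = p$krill_recruit_rate,
    krill_survival_summer = p$krill_survival[, 1],
    krill_survival_winter = p$krill_survival[, 2],
    catch_fraction_summer = p$base_catch_fractions[, 1],
    catch_fraction_winter = p$base_catch_fractions[, 2]),
    file.path(path, "ssmu_table.tsv"))
  pops <- p$predator_populations
  write_tsv_num(data.frame(
    group = vapply(pops, `[[`, "", "group"),
    resident_ssmu = vapply(pops, `[[`, "", "resident_ssmu"),
    initial_adults = vapply(pops, `[[`, 0, "initial_adults"),
    demand_summer_g = vapply(pops, function(x) x$per_capita_demand[1], 0),
    demand_winter_g = vapply(pops, function(x) x$per_capita_demand[2], 0),
    adult_survival = vapply(pops, `[[`, 0, "adult_survival"),
    max_recruits_per_breeder = vapply(pops, `[[`, 0, "max_recruits_per_breeder"),
    recruit_lag_yr = vapply(pops, `[[`, 0L, "recruit_lag")),
    file.path(path, "predators.tsv"))
  for (s in c("summer", "winter")) {
    write_matrix_tsv(p$movement_matrices[[s]], m$ssmu_ids,
                     file.path(path, sprintf("movement_%s.tsv", s)))
    fmat <- t(vapply(pops, function(x)
      x$foraging_dist[, if (s == "summer") 1 else 2],
      numeric(length(m$ssmu_ids))))
    rownames(fmat) <- sprintf("pop%03d", seq_along(pops))
    write_matrix_tsv(fmat, m$ssmu_ids,
                     file.path(path, sprintf("foraging_%s.tsv", s)))
  }
  invisible(path)
}

#' Load a parameterization from a config directory
#'
#' Reads a directory written by [save_parameterization()], reconstructs the
#' parameterization, and validates every structural invariant; a parse
#' failure names the offending file or key, and invariant violations are all
#' reported in a single error.
#'
#' @param path config directory.
#' @return a validated [krill_parameterization()].
#' @export
load_parameterization <- function(path) {
  yml <- file.path(path, "parameterization.yaml")
  if (!file.exists(yml)) stopf("missing file '%s'", yml)
  header <- yaml::yaml.load_file(yml)
  for (key in c("schema_version", "id", "movement_mode", "breeder_response",
                "hyperstable_halfsat", "krill_recruit_sigma"))
    if (is.null(header[[key]]))
      stopf("'%s': missing required key '%s'", yml, key)
  if (header$schema_version != SCHEMA_VERSION)
    stopf("'%s': unsupported schema_version '%s' (expected '%s')",
          yml, header$schema_version, SCHEMA_VERSION)
  st <- read_tsv(file.path(path, "ssmu_table.tsv"))
  for (key in c("ssmu_id", "subarea", "area_m2", "mpa",
                "initial_krill_biomass_g", "initial_mean_mass_g",
                "mass_trend_per_yr", "krill_recruit_rate",
                "krill_survival_summer", "krill_survival_winter",
                "catch_fraction_summer", "catch_fraction_winter"))
    if (is.null(st[[key]]))
      stopf("ssmu_table.tsv: missing required column '%s'", key)
  map <- ssmu_map(st$ssmu_id, st$area_m2, st$subarea, as.logical(st$mpa))
  pt <- read_tsv(file.path(path, "predators.tsv"))
  ids <- map$ssmu_ids
  forag <- lapply(c("summer", "winter"), function(s)
    read_matrix_tsv(file.path(path, sprintf("foraging_%s.tsv", s)), ids))
  pops <- lapply(seq_len(nrow(pt)), function(j)
    predator_population(
      group = pt$group[j], resident_ssmu = pt$resident_ssmu[j],
      initial_adults = pt$initial_adults[j],
      per_capita_demand = c(pt$demand_summer_g[j], pt$demand_winter_g[j]),
      foraging_dist = cbind(summer = forag[[1]][j, ],
                            winter = forag[[2]][j, ]),
      adult_survival = pt$adult_survival[j],
      max_recruits_per_breeder = pt$max_recruits_per_breeder[j],
      recruit_lag = pt$recruit_lag_yr[j]))
  p <- krill_parameterization(
    ssmu_map = map,
    initial_krill_biomass = st$initial_krill_biomass_g,
    initial_mean_mass = st$initial_mean_mass_g,
    mass_trend = st$mass_trend_per_yr,
    krill_recruit_rate = st$krill_recruit_rate,
    krill_recruit_sigma = as.numeric(header$krill_recruit_sigma),
    krill_survival = cbind(st$krill_survival_summer,
                           st$krill_survival_winter),
    movement_matrices = lapply(
      stats::setNames(c("summer", "winter"), c("summer", "winter")),
      function(s) read_matrix_tsv(
        file.path(path, sprintf("movement_%s.tsv", s)), ids)),
    movement_mode = header$movement_mode,
    predator_populations = pops,
    breeder_response = header$breeder_response,
    hyperstable_halfsat = as.numeric(header$hyperstable_halfsat),
    base_catch_fractions = cbind(st$catch_fraction_summer,
                                 st$catch_fraction_winter),
    id = header$id)
  validate_parameterization(p)
  p
}

#' Write a results table
#'
#' Serializes an ensemble summary or a relative-outcome table as a delimited
#' text table with the header
#' `scenario, parameterization_id, ssmu, time_step, variable, value` (one row
#' per SSMU/time/variable; arena-scale rows use ssmu = "arena"). Refuses to
#' write an empty summary.
#'
#' @param x an `ensemble_summary` or `relative_outcome` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.relative_outcome <- function(x, path) {
  if (nrow(x) == 0) stopf("refusing to write an empty results table")
  strategy <- attr(x, "strategy") %||% "unknown"
  long <- rbind(
    data.frame(scenario = strategy, parameterization_id = "ensemble",
               ssmu = x$ssmu, time_step = 2L * x$time_slice,
               variable = paste0("ratio_", x$metric), value = x$ratio),
    data.frame(scenario = strategy, parameterization_id = "ensemble",
               ssmu = x$ssmu, time_step = 2L * x$time_slice,
               variable = paste0("delta_", x$metric), value = x$delta))
  write_tsv_num(long, path)
  invisible(path)
}

#' @export
write_results.ensemble_summary <- function(x, path) {
  if (is.null(x$mean_krill) || nrow(x$mean_krill) == 0 ||
      x$n_trials * x$n_parameterizations == 0)
    stopf("refusing to write an empty ensemble summary")
  ids <- x$ssmu_map$ssmu_ids
  steps <- seq_len(nrow(x$mean_catch)) - 1L
  long <- rbind(
    data.frame(scenario = x$spec$strategy, parameterization_id = "ensemble",
               ssmu = rep(ids, each = length(steps) + 1L),
               time_step = rep(c(steps, max(steps) + 1L), length(ids)),
               variable = "mean_krill_biomass_g",
               value = as.vector(x$mean_krill)),
    data.frame(scenario = x$spec$strategy, parameterization_id = "ensemble",
               ssmu = rep(ids, each = length(steps)),
               time_step = rep(steps, length(ids)),
               variable = "mean_catch_g", value = as.vector(x$mean_catch)))
  write_tsv_num(long, path)
  invisible(path)
}
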