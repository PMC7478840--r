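# Config round trips, validation, and results tables.

test_that("a saved parameterization reloads equal, and resaving is byte-identical", {
  p <- DEFAULT_REFSET[[4]]  # drift + hyperstable: non-trivial matrices
  d1 <- file.path(tempdir(), "cfg1")
  save_parameterization(p, d1)
  p2 <- load_parameterization(d1)
  expect_equal(p2, p)
  d2 <- file.path(tempdir(), "cfg2")
  save_parameterization(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the schema version is stamped and enforced", {
  d <- file.path(tempdir(), "cfg_schema")
  save_parameterization(DEFAULT_P, d)
  yml <- yaml::yaml.load_file(file.path(d, "parameterization.yaml"))
  expect_identical(yml$schema_version, "1.0")
  yml$schema_version <- "0.9"
  writeLines(yaml::as.yaml(yml), file.path(d, "parameterization.yaml"))
  expect_error(load_parameterization(d), "schema_version")
  unlink(d, recursive = TRUE)
})

test_that("validation reports every violation and never repairs silently", {
  p <- DEFAULT_P
  p$movement_matrices$summer[3, 3] <- 0.8  # row 3 now sums to 0.8
  expect_error(validate_parameterization(p), "rows not summing to 1: 3")
  p$base_catch_fractions[1, 1] <- p$base_catch_fractions[1, 1] + 0.5
  err <- tryCatch(validate_parameterization(p), error = conditionMessage)
  expect_match(err, "movement matrix")
  expect_match(err, "base_catch_fractions")

  d <- file.path(tempdir(), "cfg_bad")
  save_parameterization(DEFAULT_P, d)
  st <- read.table(file.path(d, "ssmu_table.tsv"), sep = "\t", header = TRUE)
  st$krill_recruit_rate[2] <- 1.7
  write.table(st, file.path(d, "ssmu_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_parameterization(d), "krill_recruit_rate")
  unlink(d, recursive = TRUE)
})

test_that("saving refuses non-finite inputs and loading names missing pieces", {
  p <- DEFAULT_P
  p$ssmu_map$areas[4] <- NaN
  expect_error(save_parameterization(p, file.path(tempdir(), "nope")),
               "areas")
  d <- file.path(tempdir(), "cfg_missing")
  save_parameterization(DEFAULT_P, d)
  file.remove(file.path(d, "movement_winter.tsv"))
  expect_error(load_parameterization(d), "movement_winter")
  unlink(d, recursive = TRUE)
})

test_that("the default synthetic config carries the published residency pattern", {
  d <- file.path(tempdir(), "cfg_default")
  save_parameterization(generate_parameterization(), d)
  p <- load_parameterization(d)
  res_of <- function(g) sort(as.integer(vapply(
    Filter(function(x) x$group == g, p$predator_populations),
    `[[`, "", "resident_ssmu")))
  expect_identical(res_of("penguins"), c(2:8, 10:12, 14:15))
  expect_identical(res_of("whales"), c(1L, 9L))
  expect_identical(res_of("fish"), 1:15)
  expect_identical(res_of("seals"), c(3L, 4L, 7L, 14L, 15L))
  unlink(d, recursive = TRUE)
})

test_that("results tables have the documented long shape", {
  spec <- quick_spec(horizon_years = 20, n_trials = 2)
  cmp <- run_comparison(DEFAULT_REFSET, "mpa", spec, n_trials = 2)
  ev <- suppressWarnings(evaluate_comparison(cmp, years = c(10, 20)))
  f <- tempfile(fileext = ".tsv")
  write_results(ev, f)
  tab <- read.table(f, sep = "\t", header = TRUE)
  expect_identical(names(tab), c("scenario", "parameterization_id", "ssmu",
                                 "time_step", "variable", "value"))
  # SSMU-scale: 15 SSMUs x 2 slices = 30 rows per variable
  catch_ratio <- tab[tab$variable == "ratio_catch" & tab$ssmu != "arena", ]
  expect_identical(nrow(catch_ratio), 30L)
  # arena scale: 1 row per (metric, slice)
  arena <- tab[tab$ssmu == "arena" & grepl("^ratio_", tab$variable), ]
  expect_identical(nrow(arena),
                   length(unique(arena$variable)) * 2L)
  # an ensemble summary also serializes
  f2 <- tempfile(fileext = ".tsv")
  write_results(cmp$base, f2)
  tab2 <- read.table(f2, sep = "\t", header = TRUE)
  expect_true(all(c("mean_krill_biomass_g", "mean_catch_g") %in%
                    tab2$variable))
  # an empty ensemble is an error, not an empty file
  empty <- cmp$base
  empty$n_trials <- 0L
  expect_error(write_results(empty, tempfile()), "empty")
  file.remove(f, f2)
})
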