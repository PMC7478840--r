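# Catch-limit allocation, the two feedback rules, the MPA redistribution,
# and the reassessment scheduler.

test_that("catch limits follow Theta = B0 * gamma * p' / wbar", {
  expect_equal(allocate_catch_limits(1000, 0.1, c(0.5, 0.5), c(0.5, 1.0)),
               c(100, 50), tolerance = 1e-12)
  expect_equal(allocate_catch_limits(1000, 0.1, c(0, 1), c(0.5, 1.0))[1], 0)
  # fully developed fishery: the whole limit in one SSMU
  B0 <- 3.7e12; w <- 0.46
  expect_equal(allocate_catch_limits(B0, 0.093, 1.0, w), 0.093 * B0 / w,
               tolerance = 1e-12)
  expect_error(allocate_catch_limits(1000, 0.1, c(0.5, 0.5), c(0.5, 0)),
               "positive")
  expect_error(allocate_catch_limits(1000, 0.1, c(0.9, 0.9), c(1, 1)),
               "sum")
})

test_that("krill-density fractions are normalized densities, order-preserving", {
  expect_equal(fbm_krill_fractions(c(10, 30, 60)), c(0.1, 0.3, 0.6),
               tolerance = 1e-12)
  expect_equal(fbm_krill_fractions(5), 1.0)
  expect_null(fbm_krill_fractions(c(0, 0, 0)))
  set.seed(2)
  for (i in 1:20) {
    d <- runif(8, 0, 50)
    fr <- fbm_krill_fractions(d)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_identical(order(fr), order(d))
  }
})

test_that("penguin-change fractions remap declines and close the worst SSMU", {
  res <- fbm_pengs_fractions(c(0, 150, 150), c(100, 100, 100), alpha = 1)
  expect_equal(res$fractions, c(0, 0.5, 0.5), tolerance = 1e-12)
  expect_equal(res$closed, 1L)

  # all-positive changes: |min| is still added, nothing is closed
  res2 <- fbm_pengs_fractions(c(110, 120, 130), c(100, 100, 100), alpha = 1)
  expect_equal(res2$fractions, c(2, 3, 4) / 9, tolerance = 1e-12)
  expect_length(res2$closed, 0)

  # equal declines everywhere: degenerate indicator
  expect_null(fbm_pengs_fractions(c(95, 95, 95), c(100, 100, 100), alpha = 1))

  # tied greatest declines are all closed
  res3 <- fbm_pengs_fractions(c(95, 95, 100), c(100, 100, 100), alpha = 1)
  expect_equal(res3$closed, c(1L, 2L))

  # alpha < 1 with a decline would produce a negative allocation: rejected
  expect_error(fbm_pengs_fractions(c(0, 150), c(100, 100), alpha = 0.5),
               "alpha")

  # order-preserving in the change
  set.seed(5)
  for (i in 1:20) {
    now <- runif(6, 0, 200); prev <- runif(6, 0, 200)
    res <- fbm_pengs_fractions(now, prev, alpha = 1)
    if (is.null(res)) next
    expect_identical(order(res$fractions), order(now - prev))
  }
})

test_that("MPA fractions zero the mask and renormalize the open cells", {
  expect_equal(mpa_fractions(c(0.2, 0.3, 0.5), c(FALSE, FALSE, TRUE)),
               c(0.4, 0.6, 0), tolerance = 1e-12)
  base <- c(0.2, 0.3, 0.5)
  expect_identical(mpa_fractions(base, rep(FALSE, 3)), base)  # exact no-op
  # every open cell has baseline 0: uniform fallback
  expect_equal(mpa_fractions(c(1, 0), c(TRUE, FALSE)), c(0, 1))
  expect_error(mpa_fractions(c(0.5, 0.5), c(TRUE, TRUE)), "open area")
  # seasonal matrix form sums to 1 with masked rows exactly 0
  m <- matrix(c(0.1, 0.2, 0.3, 0.05, 0.15, 0.2), 3, 2)
  out <- mpa_fractions(m, c(TRUE, FALSE, FALSE))
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_identical(out[1, ], c(0, 0))
})

test_that("reassessments fall on summer steps at whole-interval years", {
  expect_identical(reassessment_times(5, 20), c(10L, 20L, 30L))
  expect_identical(diff(reassessment_times(5, 50))[1], 10L)  # penguin lookback
  expect_identical(reassessment_times(5, 4), integer(0))
  expect_identical(reassessment_times(1, 3), c(2L, 4L))
})

test_that("apply_strategy keeps the allocation total at 1 under every rule", {
  p <- DEFAULT_P
  spec <- quick_spec(n_trials = 1)
  ctl <- init_controls(p, spec)
  n <- length(p$ssmu_map$ssmu_ids)

  none <- apply_strategy("none", ctl, p, spec, p$initial_mean_mass)
  expect_identical(none$fractions, ctl$fractions)

  set.seed(11)
  for (i in 1:40) {
    c1 <- apply_strategy("fbm_krill", ctl, p, spec, p$initial_mean_mass,
                         densities = runif(n, 0, 60))
    expect_equal(sum(c1$fractions), 1, tolerance = 1e-9)
    c2 <- apply_strategy("fbm_pengs", ctl, p, spec, p$initial_mean_mass,
                         penguins_now = runif(n, 0, 1e5),
                         penguins_prev = runif(n, 0, 1e5))
    expect_equal(sum(c2$fractions), 1, tolerance = 1e-9)
    expect_true(all(c2$fractions[c2$closed, ] == 0))
  }
  c3 <- apply_strategy("mpa", ctl, p, spec, p$initial_mean_mass)
  expect_equal(sum(c3$fractions), 1, tolerance = 1e-9)
  expect_true(all(c3$fractions[p$ssmu_map$mpa_mask, ] == 0))
})

test_that("degenerate indicators keep the previous allocation and are recorded", {
  p <- DEFAULT_P
  spec <- quick_spec(n_trials = 1)
  ctl <- init_controls(p, spec)
  n <- length(p$ssmu_map$ssmu_ids)
  out <- apply_strategy("fbm_krill", ctl, p, spec, p$initial_mean_mass,
                        densities = rep(0, n))
  expect_identical(out$fractions, ctl$fractions)
  expect_true(attr(out, "record")$degenerate)
  out2 <- apply_strategy("fbm_pengs", ctl, p, spec, p$initial_mean_mass,
                         penguins_now = rep(50, n), penguins_prev = rep(60, n))
  expect_identical(out2$fractions, ctl$fractions)
  expect_true(attr(out2, "record")$degenerate)
})

test_that("SSMUs without resident penguins get zero fraction under the penguin rule", {
  p <- DEFAULT_P
  spec <- quick_spec(n_trials = 1)
  ctl <- init_controls(p, spec)
  n <- length(p$ssmu_map$ssmu_ids)
  resident <- krillmse:::penguin_resident_index(p)
  out <- apply_strategy("fbm_pengs", ctl, p, spec, p$initial_mean_mass,
                        penguins_now = rep(100, n),
                        penguins_prev = c(rep(90, n - 1), 50))
  non_resident <- setdiff(seq_len(n), resident)
  expect_true(all(out$fractions[non_resident, ] == 0))
  expect_equal(sum(out$fractions), 1, tolerance = 1e-9)
})

test_that("a declining penguin SSMU is closed for the following interval", {
  p <- DEFAULT_REFSET[[1]]
  spec <- scenario_spec(strategy = "fbm_pengs", horizon_years = 40,
                        n_trials = 1, seed = 1)
  tr <- run_trial(p, spec, seed = 12)
  recs <- Filter(function(r) !r$degenerate && length(r$closed_ssmu) > 0,
                 tr$reassessments)
  expect_gt(length(recs), 0)
  for (r in recs) {
    resident <- krillmse:::penguin_resident_index(p)
    dP <- r$indicator_values[resident]
    worst <- p$ssmu_map$ssmu_ids[resident][dP == min(dP)]
    expect_true(all(worst %in% r$closed_ssmu))
    idx <- match(r$closed_ssmu, p$ssmu_map$ssmu_ids)
    steps <- (r$time_step + 1):min(r$time_step + 10, nrow(tr$catch))
    expect_true(all(tr$catch[steps, idx] == 0))
  }
})
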