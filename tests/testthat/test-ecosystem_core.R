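# The seasonal delay-difference update: mass trend, recruitment, movement,
# demand competition, breeder response, predator demography.

test_that("mass trend is linear in years with a positive floor", {
  expect_equal(apply_mass_trend(1.0, 0, 50), 1.0)
  expect_equal(apply_mass_trend(1.0, -0.002, 100), 0.8)
  # a trend strong enough to annihilate mass bottoms out at the floor
  floored <- apply_mass_trend(1.0, -0.02, 100)
  expect_gt(floored, 0)
  expect_equal(floored, apply_mass_trend(1.0, -1, 100))  # same floor
  # vectorized across SSMUs
  expect_equal(apply_mass_trend(c(1, 2), c(0, -0.001), 10), c(1, 2 * 0.99))
})

test_that("krill density is biomass over area, with the threshold boundary exact", {
  expect_equal(krill_density(2000, 100), 20)
  expect_equal(krill_density(0, 100), 0)
  expect_identical(krill_density(1.5e12, 1e11), 15)
  expect_error(krill_density(10, 0), "positive")
})

test_that("recruitment is proportional with a median-1 lognormal deviate", {
  expect_equal(recruit_krill(100, 0.5, 0), 50)
  expect_equal(recruit_krill(100, 0, 0.5), 0)
  # lognormal moment identity: E[R] = rate*K*exp(sigma^2/2)
  set.seed(99)
  draws <- replicate(1e5, recruit_krill(100, 0.5, 0.5))
  expect_equal(mean(draws), 50 * exp(0.5^2 / 2), tolerance = 0.01)
  # the deterministic limit consumes no random numbers
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(recruit_krill(100, 0.5, 0)); after <- runif(1)
  expect_identical(before, after)
})

test_that("movement redistributes along rows and conserves biomass", {
  expect_equal(move_krill(c(3, 4), diag(2)), c(3, 4))
  expect_equal(move_krill(c(100, 0), matrix(c(0.5, 0, 0.5, 1), 2, 2)),
               c(50, 50))
  expect_error(move_krill(c(1, 1), matrix(c(0.5, 0, 0.3, 1), 2, 2)),
               "row-stochastic")
  set.seed(4)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    M <- matrix(rgamma(n * n, 1), n, n)
    M <- M / rowSums(M)
    K <- runif(n, 0, 1e12)
    expect_equal(sum(move_krill(K, M)), sum(K), tolerance = 1e-9)
  }
})

test_that("demand competition rations predators and fishery proportionally", {
  r <- resolve_competition(100, 80, 40)
  expect_equal(r$lambda, 100 / 120, tolerance = 1e-12)
  expect_equal(r$realized_predation, 200 / 3, tolerance = 1e-12)
  expect_equal(r$realized_catch, 100 / 3, tolerance = 1e-12)
  r2 <- resolve_competition(100, 30, 40)
  expect_equal(r2$lambda, 1)
  expect_equal(r2$realized_catch, 40)
  r3 <- resolve_competition(100, 0, 0)
  expect_equal(r3$lambda, 1)
  expect_equal(r3$realized_predation + r3$realized_catch, 0)
})

test_that("foraging success is the distribution-weighted rationing", {
  expect_equal(foraging_success(c(0.3, 0.7), c(1, 1)), 1)
  expect_equal(foraging_success(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(foraging_success(c(0.2, 0.8), c(0.5, 0.25)), 0.3)
})

test_that("breeder response: linear identity, hyperstable dominates on (0,1)", {
  expect_equal(effective_breeder_fraction(0.5, "linear"), 0.5)
  expect_equal(effective_breeder_fraction(0.5, "hyperstable", c = 0.2), 6 / 7)
  expect_equal(effective_breeder_fraction(1, "hyperstable", c = 0.2), 1)
  expect_equal(effective_breeder_fraction(0, "hyperstable", c = 0.2), 0)
  x <- seq(0.01, 0.99, by = 0.01)
  hyper <- effective_breeder_fraction(x, "hyperstable", c = 0.3)
  expect_true(all(hyper >= x))          # dominates the linear response
  expect_true(all(diff(hyper) > 0))     # monotone increasing
  expect_error(effective_breeder_fraction(0.5, "hyperstable", c = 0),
               "c > 0")
})

test_that("predator demography follows the survival/maturation recursion", {
  # survival 1, no fecundity: constant population
  p <- toy_param(predators = list(
    toy_penguins(1, 2, adults = 100, survival = 1, fecundity = 0)))
  st <- init_state(p)
  for (k in 1:4) {
    st <- update_predators(st, x = 1, p)
    st$t <- st$t + 1L
  }
  expect_equal(st$predator_adults, 100)

  # survival 0.9, no recruitment: geometric decay, factor 0.81 in two steps
  p2 <- toy_param(predators = list(
    toy_penguins(1, 2, adults = 100, survival = 0.9, fecundity = 0)))
  st2 <- init_state(p2)
  for (k in 1:2) {
    st2 <- update_predators(st2, x = 1, p2)
    st2$t <- st2$t + 1L
  }
  expect_equal(st2$predator_adults, 81)

  # a lag-2yr cohort of 10 matures exactly 4 time steps after entering
  p3 <- toy_param(predators = list(
    toy_penguins(1, 2, adults = 100, survival = 1, fecundity = 0, lag = 2L)))
  st3 <- init_state(p3)
  st3$pending_recruits[[1]] <- c(0, 0)
  # inject the cohort as this summer's breeding output
  p3$predator_populations[[1]]$max_recruits_per_breeder <- 0.1
  adults_seen <- numeric(6)
  for (k in 1:6) {
    st3 <- update_predators(st3, x = 1, p3)
    st3$t <- st3$t + 1L
    adults_seen[k] <- st3$predator_adults
    p3$predator_populations[[1]]$max_recruits_per_breeder <- 0  # one cohort only
  }
  # created during step 0 (10 = 100 * 0.1), appears during step 4
  expect_equal(adults_seen[1:4], rep(100, 4))
  expect_equal(adults_seen[5:6], rep(110, 2))
})

test_that("single-SSMU deterministic trajectory matches a straight-line oracle", {
  s <- 0.8; r <- 0.4; sp <- 0.9; m <- (1 - sp^2) / sp; lag <- 2L
  q <- c(100, 50); A0 <- 1000; K0 <- 2e8
  pop <- toy_penguins(1, 1, adults = A0, demand = q, survival = sp, lag = lag)
  p <- toy_param(n = 1, recruit_rate = r, survival = s, areas = 1e7,
                 density = K0 / 1e7, mass = 0.5, predators = list(pop),
                 catch_fractions = matrix(0.5, 1, 2))
  spec <- quick_spec(gamma = 0, climate_trend = FALSE, n_trials = 1)
  tr <- run_trial(p, spec, seed = 1)

  # independent scalar recursion, same operation order
  K <- K0; A <- A0; queue <- rep(A0 * m, lag)
  Ks <- numeric(201); As <- numeric(201)
  Ks[1] <- K; As[1] <- A
  for (t in 0:199) {
    summer <- t %% 2 == 0
    if (summer) K <- K * (1 + r)
    D <- A * q[if (summer) 1 else 2]
    lam <- min(1, if (D > 0) K / D else Inf)
    x <- lam
    K <- s * (K - lam * D)
    if (summer) {
      mat <- queue[1]
      queue <- c(queue[-1], A * x * m)
      A <- sp * A + mat
    } else A <- sp * A
    Ks[t + 2] <- K; As[t + 2] <- A
  }
  expect_equal(tr$krill[, 1], Ks, tolerance = 1e-12)
  expect_equal(tr$adults[, 1], As, tolerance = 1e-12)
})

test_that("fishery suspends below the density threshold and flags the violation", {
  # SSMU 1 below 15 g/m^2 even after summer recruitment, SSMU 2 above
  p <- toy_param(density = c(8, 30))
  spec <- quick_spec(n_trials = 1)
  res <- step_season(init_state(p), p, init_controls(p, spec), spec)
  expect_true(res$outcome$violations[1])
  expect_false(res$outcome$violations[2])
  expect_equal(res$outcome$realized_catch[1], 0)
  expect_gt(res$outcome$realized_catch[2], 0)
  # with no allocated catch there is no violation to flag
  spec0 <- quick_spec(gamma = 0, n_trials = 1)
  res0 <- step_season(init_state(p), p, init_controls(p, spec0), spec0)
  expect_false(any(res0$outcome$violations))
  expect_false(any(res0$outcome$fishing))
})

test_that("deterministic limit is bit-reproducible regardless of RNG position", {
  p <- toy_param(sigma = 0, predators = list(toy_penguins(1, 2)))
  spec <- quick_spec(horizon_years = 10, n_trials = 1)
  st <- init_state(p); ctl <- init_controls(p, spec)
  set.seed(1); a <- step_season(st, p, ctl, spec)
  set.seed(99999); runif(3)
  b <- step_season(st, p, ctl, spec)
  expect_identical(a, b)
})

test_that("krill mass balance holds per step and consumption never exceeds availability", {
  for (seed in 1:6) {
    p <- random_small_param(seed, sigma = 0)
    if (seed %% 2 == 0) {  # exercise the drift members too
      p <- generate_reference_set(p)[[3 + seed %% 2]]
      p$krill_recruit_sigma <- 0
    }
    spec <- quick_spec(horizon_years = 6, n_trials = 1,
                       strategy = c("none", "fbm_krill")[1 + seed %% 2])
    st <- init_state(p); ctl <- init_controls(p, spec)
    for (t in 0:11) {
      K <- st$krill_biomass
      if (t %% 2 == 0) K <- K + p$krill_recruit_rate * K  # sigma = 0
      s <- t %% 2 + 1
      K_moved <- as.vector(crossprod(p$movement_matrices[[s]], K))
      res <- step_season(st, p, ctl, spec)
      o <- res$outcome
      consumed <- o$realized_catch + o$realized_predation
      expect_true(all(consumed <= K_moved * (1 + 1e-9)))
      expect_equal(res$state$krill_biomass,
                   p$krill_survival[, s] * (K_moved - consumed),
                   tolerance = 1e-9)
      expect_true(all(res$state$krill_biomass >= 0))
      expect_true(all(res$state$predator_adults >= 0))
      st <- res$state
    }
  }
})

test_that("increasing the harvest rate weakly decreases every predator at year 30", {
  pops <- list(toy_penguins(1, 2, adults = 1000, demand = c(4e6, 2e6)),
               toy_penguins(2, 2, adults = 500, demand = c(4e6, 2e6)))
  p <- toy_param(density = c(30, 20), predators = pops, recruit_rate = 0.6)
  at_y30 <- function(g) {
    spec <- quick_spec(horizon_years = 30, gamma = g, n_trials = 1,
                       climate_trend = FALSE)
    run_trial(p, spec, seed = 1)$adults[61, ]
  }
  prev <- at_y30(0)
  for (g in c(0.05, 0.093, 0.2, 0.4)) {
    cur <- at_y30(g)
    expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
})
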