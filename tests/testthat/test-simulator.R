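test_that("von Mises draws have the right concentration and centre", {
  set.seed(1)
  x <- rvonmises(1e5, mu = 0.5, kappa = 557)
  # large-kappa circular SD ~ 1/sqrt(kappa)
  R <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  circ_sd <- sqrt(-2 * log(R))
  expect_equal(circ_sd, 1 / sqrt(557), tolerance = 0.02)
  expect_equal(atan2(mean(sin(x)), mean(cos(x))), 0.5, tolerance = 3 * circ_sd / sqrt(1e5) * 5)
  # kappa -> very large collapses onto the mean
  y <- rvonmises(100, mu = -1.2, kappa = 1e9)
  expect_true(all(abs(angle_diff(y, -1.2)) < 1e-3))
  # kappa = 0 is uniform: mean resultant length near zero
  set.seed(2)
  u <- rvonmises(2e4, 0, 0)
  expect_lt(sqrt(mean(cos(u))^2 + mean(sin(u))^2), 0.02)
})

test_that("Rician speed draws match the closed-form mean and variance", {
  set.seed(3)
  v <- rrician(2e5, 4.81, 2.18)
  m_exact <- rician_mean_exact(4.81, 2.18)
  v_exact <- 2 * 2.18^2 + 4.81^2 - m_exact^2
  expect_equal(mean(v), m_exact, tolerance = 0.005)
  expect_equal(var(v), v_exact, tolerance = 0.02)
  expect_true(all(v >= 0))
})

test_that("per-step turns never exceed the lateral-acceleration limit", {
  cfg <- sim_config(duration = 40, detection = FALSE)
  sim <- simulate_pair(cfg, seed = 5)
  for (i in 1:2) {
    turns <- abs(angle_diff(sim$phi[-1, i], sim$phi[-nrow(sim$phi), i]))
    beta_dt <- (cfg$a_c / sim$v[-1, i]) * cfg$dt
    expect_true(all(turns <= beta_dt + 1e-9))
  }
  # a 180-degree desired turn at the Rician mean speed is clamped to
  # (a_c / v) dt ~ 0.163 rad
  expect_equal((4 * 9.81 / 4.81) * 0.02, 0.1632, tolerance = 1e-3)
})

test_that("with detection disabled the bats are independent correlated random walks", {
  cfg <- sim_config(duration = 60, detection = FALSE)
  sim <- simulate_pair(cfg, seed = 11)
  expect_false(any(sim$interacting))
  expect_equal(mean(sim$v), rician_mean_exact(4.81, 2.18), tolerance = 0.02)
  # heading increments of the two bats are uncorrelated
  d1 <- angle_diff(sim$phi[-1, 1], sim$phi[-nrow(sim$phi), 1])
  d2 <- angle_diff(sim$phi[-1, 2], sim$phi[-nrow(sim$phi), 2])
  expect_lt(abs(cor(d1, d2)), 0.05)
})

test_that("escape from interaction is geometric with the configured rate", {
  # always-detecting sonar keeps re-triggering the interacting state, so
  # dwell times between escapes are geometric with mean 1/escape_prob
  cfg <- sim_config(
    duration = 400, tau = 0, escape_prob = 0.05,
    sonar = sonar_params(B = -Inf)
  )
  sim <- simulate_pair(cfg, seed = 21)
  runs <- rle(sim$interacting[, 1])
  dwells <- runs$lengths[runs$values]
  expect_gt(length(dwells), 100)
  expect_equal(mean(dwells), 20, tolerance = 0.2)

  # escape_prob = 0: once interacting, never leaves
  cfg0 <- sim_config(duration = 10, tau = 0, escape_prob = 0, sonar = sonar_params(B = -Inf))
  sim0 <- simulate_pair(cfg0, seed = 4)
  on <- which(sim0$interacting[, 1])
  expect_true(length(on) > 0 && all(diff(on) == 1))

  # escape_prob = 1: never two consecutive interacting steps
  cfg1 <- sim_config(duration = 10, tau = 0, escape_prob = 1, sonar = sonar_params(B = -Inf))
  sim1 <- simulate_pair(cfg1, seed = 4)
  runs1 <- rle(sim1$interacting[, 1])
  expect_true(all(runs1$lengths[runs1$values] <= 1))
})

test_that("the reaction delay gates when call outcomes take effect", {
  cfg <- sim_config(duration = 5, tau = 0.4, escape_prob = 0, sonar = sonar_params(B = -Inf))
  sim <- simulate_pair(cfg, seed = 8)
  tau_steps <- cfg$tau_steps
  # no interaction can begin before the first call's effect time
  expect_false(any(sim$interacting[seq_len(tau_steps), ]))
  expect_true(any(sim$interacting[(tau_steps + 2):(tau_steps + 10), ]))
})

test_that("ensembles are deterministic and extendable per substream", {
  cfg <- sim_config(duration = 2)
  e1 <- simulate_ensemble(cfg, 3, seed = 99)
  e2 <- simulate_ensemble(cfg, 3, seed = 99)
  expect_identical(
    lapply(e1, function(s) s$pair$a$xy),
    lapply(e2, function(s) s$pair$a$xy)
  )
  # enlarging the ensemble leaves earlier pairs untouched
  e5 <- simulate_ensemble(cfg, 5, seed = 99)
  expect_identical(e1[[2]]$pair$b$xy, e5[[2]]$pair$b$xy)
})

test_that("close mutually facing bats detect each other and interact after tau", {
  # plant both bats near each other by shrinking the arena
  cfg <- sim_config(duration = 4, tau = 0.2, arena = 2, escape_prob = 0)
  sim <- simulate_pair(cfg, seed = 14)
  expect_true(any(sim$interacting))
  expect_true(any(sim$calls$det_bat1 | sim$calls$det_bat2, na.rm = TRUE))
})
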