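test_that("coupling profiles have the prescribed shapes", {
  t_ms <- seq(0, 3000)
  expect_equal(coupling_profile("off", t_ms), rep(0, length(t_ms)))

  step <- coupling_profile("step_tanh", t_ms, slope = 0.05,
                           inflections = 1000)
  expect_lt(step[t_ms == 900], 0.01)          # rises over ~200 ms
  expect_gt(step[t_ms == 1100], 0.99)
  expect_equal(step[t_ms == 1000], 0.5)       # tanh midpoint = half plateau
  expect_true(all(diff(step) >= 0))           # monotone
  expect_true(all(step >= 0 & step <= 1))

  two <- coupling_profile("two_step_tanh", t_ms, slope = 0.05,
                          inflections = c(1000, 2000))
  expect_equal(two[t_ms == 1500], 0.5, tolerance = 1e-6)  # first plateau
  expect_gt(two[t_ms == 2500], 0.99)                      # second higher
  expect_true(all(two >= 0 & two <= 1))
})

test_that("AR simulation matches its closed-form uncoupled variance", {
  cfg <- ar_config("unidirectional", gamma_xy = 0, n_reps = 60,
                   rep_length_ms = 1000)
  ens <- simulate_ar_pair(cfg, seed = 5)
  # stationary AR(1) variance 1/(1-a^2); a = 0.35 -> 1.140
  v <- var(as.vector(ens$values[1, , 100:1000]))
  n_eff <- 60 * 900 / 3            # generous correction for autocorrelation
  se <- sqrt(2 / n_eff) * 1.140
  expect_lt(abs(v - 1 / (1 - 0.35^2)), 3 * se)
})

test_that("AR scenarios carry the documented parameterization", {
  cfg <- ar_config("bidirectional")
  expect_equal(cfg$gamma_xy, 0.475)
  expect_equal(cfg$gamma_yx, -0.4)
  expect_equal(cfg$delta_xy, 10)
  expect_equal(cfg$delta_yx, 20)
  ens <- simulate_ar_pair(ar_config("unidirectional", n_reps = 3,
                                    rep_length_ms = 500), seed = 1)
  expect_equal(dim(ens$values), c(2L, 3L, 500L))
  expect_error(simulate_ar_pair(ar_config("unidirectional", a_x = 1.1)),
               "explosive")
})

test_that("simulators are bit-reproducible under a fixed seed", {
  a1 <- simulate_ar_pair(ar_config("two_step", n_reps = 4,
                                   rep_length_ms = 400), seed = 9)
  a2 <- simulate_ar_pair(ar_config("two_step", n_reps = 4,
                                   rep_length_ms = 400), seed = 9)
  expect_identical(a1$values, a2$values)

  l1 <- simulate_lorenz_pair(lorenz_config(n_reps = 2, rep_length_ms = 300),
                             seed = 9)
  l2 <- simulate_lorenz_pair(lorenz_config(n_reps = 2, rep_length_ms = 300),
                             seed = 9)
  expect_identical(l1$values, l2$values)
})

test_that("AR ensembles are stationary over repetitions before onset", {
  ens <- simulate_ar_pair(ar_config("unidirectional", n_reps = 40,
                                    rep_length_ms = 900), seed = 13)
  pre <- select_window(ens, analysis_window(100, 800))
  rep_report <- validate_ensemble(pre)
  expect_false(any(rep_report$per_channel$drift_flag))
})

test_that("uncoupled Lorenz trajectories stay bounded on the attractor", {
  ens <- simulate_lorenz_pair(lorenz_config(gamma = 0, n_reps = 3,
                                            rep_length_ms = 1500), seed = 3)
  expect_true(all(abs(ens$values) < 60))
  expect_true(all(apply(ens$values[1, , ], 1, sd) > 1))  # not collapsed
})

test_that("uncoupled Lorenz channels show no lagged dependence above
           chance", {
  ens <- simulate_lorenz_pair(lorenz_config(gamma = 0, n_reps = 8,
                                            rep_length_ms = 1500), seed = 7)
  v1 <- ens$values[1, , ]; v2 <- ens$values[2, , ]
  lags <- seq(20, 70, by = 5)
  cc <- vapply(lags, function(L)
    cor(as.vector(v1[, (500 - L):(1400 - L)]),
        as.vector(v2[, 500:1400])), numeric(1))
  # chance band from repetition-permuted pairings (dependence destroyed)
  set.seed(8)
  null_cc <- replicate(40, {
    pr <- make_surrogate(v2)
    L <- sample(lags, 1)
    cor(as.vector(v1[, (500 - L):(1400 - L)]), as.vector(pr[, 500:1400]))
  })
  expect_lt(max(abs(cc)), max(abs(null_cc)) + 3 * sd(null_cc))
})

test_that("coupled Lorenz pair peaks its lagged dependence near the true
           delay", {
  ens <- simulate_lorenz_pair(lorenz_config(n_reps = 12,
                                            coupling_window = c(500, 2500),
                                            rep_length_ms = 2500), seed = 5)
  v1 <- ens$values[1, , ]; v2 <- ens$values[2, , ]
  lags <- 20:70
  cc <- vapply(lags, function(L)
    cor(as.vector(v1[, (1000 - L):(2400 - L)]),
        as.vector(v2[, 1000:2400])), numeric(1))
  expect_lt(abs(lags[which.max(abs(cc))] - 45), 5)
})
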