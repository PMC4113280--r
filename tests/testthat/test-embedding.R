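test_that("delay embedding reproduces its defining coordinates", {
  ens <- ensemble_ts(matrix(0:4, 1, 5), 1000)
  ps <- delay_embed(ens, 1, embedding_params(2, 1), times = 2)
  expect_equal(ps$points, matrix(c(2, 1), 1, 2))

  # identity embedding at d = 1
  ps1 <- delay_embed(ens, 1, embedding_params(1, 1), times = 0:4)
  expect_equal(as.vector(ps1$points), 0:4)

  # ramp series: all coordinate gaps equal tau (closed form)
  ramp <- ensemble_ts(matrix(0:99, 1, 100), 1000)
  ps3 <- delay_embed(ramp, 1, embedding_params(3, 5), times = 10:99)
  expect_true(all(ps3$points[, 1] - ps3$points[, 2] == 5))
  expect_true(all(ps3$points[, 2] - ps3$points[, 3] == 5))

  expect_error(delay_embed(ramp, 1, embedding_params(3, 5), times = 9),
               "earliest legal reference time is t = 10")
})

test_that("embedding never mixes repetitions", {
  ens <- noise_ensemble(1, 4, 50, seed = 3)
  p <- embedding_params(3, 4)
  ps <- delay_embed(ens, 1, p, times = 8:49)
  m <- channel_matrix(ens, 1)
  for (i in sample(nrow(ps$points), 25)) {
    r <- ps$rep[i]; t <- ps$time[i]
    expect_equal(ps$points[i, ], m[r, t + 1 - (0:2) * 4])
  }
})

test_that("ragwitz selection matches an exhaustive R reference on a small
           instance", {
  ens <- gaussian_pair(a = 0.9, c = 0, n_rep = 8, n_samp = 120, seed = 6)
  cand <- expand.grid(tau = c(1, 2), dim = 1:3)
  m <- channel_matrix(ens, "Y")
  # reference: same criterion computed directly with the brute-force oracle
  ref_mse <- apply(cand, 1, function(g) {
    d <- g[["dim"]]; tau <- g[["tau"]]
    p <- embedding_params(d, tau)
    tt <- seq.int((d - 1) * tau, ncol(m) - 2)
    ps <- delay_embed(ens, "Y", p, tt)
    th <- max((d - 1) * tau + 1, act_samples(ens, "Y"))
    nn <- t(vapply(seq_len(nrow(ps$points)), function(i) {
      dd <- apply(abs(sweep(ps$points, 2, ps$points[i, ], "-")), 1, max)
      excl <- seq_along(dd) == i |
        (ps$rep == ps$rep[i] & abs(ps$time - ps$time[i]) <= th)
      order(ifelse(excl, Inf, dd))[1:4]
    }, integer(4)))
    nxt <- m[cbind(ps$rep, ps$time + 2)]
    mean((rowMeans(matrix(nxt[nn], nrow = nrow(nn))) - nxt)^2)
  })
  sel <- ragwitz_optimize(ens, "Y", dim_candidates = 1:3,
                          tau_candidates = c(1, 2), max_points = 1e6)
  got <- attr(sel, "errors")
  got <- got[order(got$dim, got$tau), ]
  cand <- cand[order(cand$dim, cand$tau), ]
  expect_equal(got$mse, ref_mse[order(cand$dim, cand$tau)], tolerance = 1e-10)
})

test_that("ragwitz prefers d = 1 for an AR(1) process with strong,
           nearly noise-free memory", {
  set.seed(8)
  R <- 40; Tn <- 400
  y <- matrix(0, R, Tn)
  y[, 1] <- rnorm(R)
  for (t in 2:Tn) y[, t] <- 0.9 * y[, t - 1] + 0.05 * rnorm(R)
  ens <- ensemble_ts(y, 1000)
  sel <- ragwitz_optimize(ens, 1, dim_candidates = c(1, 3),
                          tau_candidates = 1, max_points = 8000)
  expect_equal(sel$dim, 1L)
})

test_that("ragwitz resolves the phase ambiguity of a noiseless sinusoid", {
  P <- 20
  x <- sin(2 * pi * (0:399) / P)
  ens <- ensemble_ts(rbind(x, sin(2 * pi * (0:399) / P + 1)), 1000)
  sel <- ragwitz_optimize(ens, 1, dim_candidates = 1:2,
                          tau_candidates = P / 4, theiler_mode = "span",
                          max_points = 2000)
  expect_equal(sel$dim, 2L)
})

test_that("constant series warns and returns smallest candidates", {
  ens <- ensemble_ts(matrix(1, 2, 50), 1000)
  expect_warning(sel <- ragwitz_optimize(ens, 1, dim_candidates = 2:3,
                                         tau_candidates = c(2, 4)),
                 "constant")
  expect_equal(c(sel$dim, sel$tau), c(2L, 2L))
})

test_that("TE point sets satisfy the projection and alignment invariants", {
  ens <- noise_ensemble(2, 6, 80, seed = 10, labels = c("X", "Y"))
  px <- embedding_params(2, 3)
  py <- embedding_params(3, 2)
  w <- analysis_window(20, 60)
  ps <- build_te_pointsets(ens, "X", "Y", px, py, u = 5, window = w)
  n <- 6 * 40
  expect_equal(nrow(ps$J), n)
  expect_equal(ncol(ps$J), 1 + 3 + 2)
  # column blocks of J equal M1/M2/C row-for-row
  expect_identical(ps$J[, 1:4], ps$M1)
  expect_identical(ps$J[, -1], ps$M2)
  expect_identical(ps$J[, 2:4], ps$C)
  # first row spells out the definition: (y_t, y-state(t-1), x-state(t-u))
  xm <- channel_matrix(ens, "X"); ym <- channel_matrix(ens, "Y")
  t0 <- 20
  expect_equal(ps$J[1, ], unname(c(ym[1, t0 + 1],
                                   ym[1, t0 - (0:2) * 2],
                                   xm[1, t0 - 4 - (0:1) * 3])))
  # permuting repetitions permutes rows identically in all four clouds
  perm <- c(3, 1, 2, 6, 5, 4)
  ens_p <- ens
  ens_p$values <- ens$values[, perm, , drop = FALSE]
  ps_p <- build_te_pointsets(ens_p, "X", "Y", px, py, u = 5, window = w)
  rows <- as.vector(vapply(perm, function(r) which(ps$rep == r), integer(40)))
  expect_equal(ps_p$J, ps$J[rows, ])
  expect_equal(ps_p$C, ps$C[rows, ])
})

test_that("margin violations name the minimal legal window start", {
  ens <- noise_ensemble(2, 3, 50, seed = 12, labels = c("X", "Y"))
  px <- embedding_params(3, 4)   # x-state needs t - u >= 8
  py <- embedding_params(1, 1)
  expect_error(build_te_pointsets(ens, "X", "Y", px, py, u = 6,
                                  window = analysis_window(10, 20)),
               "minimal legal t_start is 14")
  expect_error(build_te_pointsets(ens, "X", "Y", py, py, u = 0,
                                  window = analysis_window(10, 20)),
               ">= 1")
  ps <- build_te_pointsets(ens, "X", "Y", px, py, u = 6,
                           window = analysis_window(14, 20))
  expect_equal(nrow(ps$J), 3 * 6)
})
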