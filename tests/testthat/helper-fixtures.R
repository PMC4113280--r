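# Fixtures are generated in code at test time; no data files.

# white-noise ensemble
noise_ensemble <- function(n_ch = 2, n_rep = 5, n_samp = 100, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  ensemble_ts(array(rnorm(n_ch * n_rep * n_samp), c(n_ch, n_rep, n_samp)),
              sampling_rate = 1000, channel_labels = labels)
}

# linear-Gaussian pair with known transfer: y_t = a*y_{t-1} + c*x_{t-u} + e,
# x white noise. Analytic TE (d = 1) is -0.5*log(1 - pc^2) with
# pc = c / sqrt(c^2 + 1) (partial correlation of y_t and x_{t-u} given
# y_{t-1}; x is independent of y's past).
gaussian_pair <- function(a = 0.5, c = 0.4, u = 1, n_rep = 50, n_samp = 250,
                          seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_rep * n_samp), n_rep, n_samp)
  y <- matrix(0, n_rep, n_samp)
  y[, 1] <- rnorm(n_rep)         # no exact duplicates at the series start
  for (t in seq(2, n_samp))
    y[, t] <- a * y[, t - 1] +
      (if (t > u) c * x[, t - u] else 0) + rnorm(n_rep)
  v <- array(0, c(2, n_rep, n_samp))
  v[1, , ] <- x
  v[2, , ] <- y
  ensemble_ts(v, 1000, c("X", "Y"))
}

gaussian_pair_te <- function(c = 0.4) {
  pc <- c / sqrt(c^2 + 1)
  -0.5 * log(1 - pc^2)
}

# brute-force R oracles for the max-norm searches (independent of src/)
oracle_knn <- function(X, k, rep = seq_len(nrow(X)), time = integer(nrow(X)),
                       theiler = 0) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    d <- apply(abs(sweep(X, 2, X[i, ], "-")), 1, max)
    excl <- seq_len(n) == i | (rep == rep[i] & abs(time - time[i]) <= theiler)
    sort(d[!excl])[k]
  }, numeric(1))
}

oracle_count <- function(X, radii, rep = seq_len(nrow(X)),
                         time = integer(nrow(X)), theiler = 0) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    d <- apply(abs(sweep(X, 2, X[i, ], "-")), 1, max)
    excl <- seq_len(n) == i | (rep == rep[i] & abs(time - time[i]) <= theiler)
    sum(d[!excl] < radii[i])
  }, integer(1))
}
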