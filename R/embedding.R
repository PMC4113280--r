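#' Delay-embedding parameters
#'
#' The state of a scalar process at (0-based) sample `t` is represented by
#' the Takens delay vector `(x_t, x_{t-tau}, ..., x_{t-(dim-1)tau})`.
#' `theiler` is the exclusion window for neighbour searches: candidate
#' neighbours from the *same* repetition within `theiler` samples of the
#' reference time are ignored, so that temporal autocorrelation cannot fake
#' close neighbours under mixed time/ensemble pooling. Cross-repetition
#' neighbours are never excluded.
#'
#' @param dim embedding dimension d (>= 1).
#' @param tau embedding delay in samples (>= 1).
#' @param theiler exclusion window in samples (>= 0).
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(dim, tau, theiler = 0) {
  if (dim < 1) stop("`dim` must be >= 1")
  if (tau < 1) stop("`tau` must be >= 1")
  if (theiler < 0) stop("`theiler` must be >= 0")
  structure(list(dim = as.integer(dim), tau = as.integer(tau),
                 theiler = as.integer(theiler)),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat("<embedding_params> d =", x$dim, ", tau =", x$tau,
      "samples, theiler =", x$theiler, "samples\n")
  invisible(x)
}

# span of the embedding window in samples: (d-1)*tau + 1 history samples
embedding_span <- function(params) (params$dim - 1L) * params$tau + 1L

#' Autocorrelation decay time of an ensemble channel
#'
#' First lag at which the autocorrelation function (averaged over
#' repetitions) drops below `1/e`; used as the time-scale unit for embedding
#' delay candidates and Theiler exclusion.
#'
#' @param data an [ensemble_ts()].
#' @param channel channel label or index.
#' @param max_lag largest lag considered (samples).
#' @return Integer lag in samples (>= 1).
#' @export
act_samples <- function(data, channel, max_lag = 100) {
  m <- channel_matrix(data, channel)
  max_lag <- min(max_lag, ncol(m) - 1L)
  a <- rowMeans(vapply(seq_len(nrow(m)), function(r) {
    acf(m[r, ], lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(max_lag + 1L)))
  below <- which(a < exp(-1)) - 1L     # lags are 0-based in acf output
  if (length(below) == 0) return(as.integer(max_lag))
  max(1L, below[1])
}

#' Delay-embed an ensemble channel
#'
#' Builds one state vector per (repetition, reference time). Coordinate
#' `j` (0-based) of the point at time `t` equals the series at `t - j*tau`
#' within the same repetition; embedding never crosses repetition
#' boundaries. Times are 0-based sample indices.
#'
#' @param data an [ensemble_ts()].
#' @param channel channel label or index.
#' @param params an [embedding_params()].
#' @param times integer vector of 0-based reference times; every `t` must
#'   satisfy `t >= (dim - 1) * tau`.
#' @return A `state_pointset`: list with `points` (matrix
#'   `[n_points, dim]`), and per-point `rep` / `time` origin tags.
#' @export
delay_embed <- function(data, channel, params, times) {
  stopifnot(inherits(data, "ensemble_ts"), inherits(params, "embedding_params"))
  m <- channel_matrix(data, channel)
  margin <- (params$dim - 1L) * params$tau
  if (any(times < margin))
    stop("insufficient history: earliest legal reference time is t = ", margin)
  if (any(times >= ncol(m)))
    stop("reference time beyond repetition length ", ncol(m))
  R <- nrow(m)
  Tn <- length(times)
  pts <- matrix(0, nrow = R * Tn, ncol = params$dim)
  for (j in seq_len(params$dim)) {
    cols <- times - (j - 1L) * params$tau + 1L    # 0-based -> R index
    block <- m[, cols, drop = FALSE]              # [R, Tn]
    pts[, j] <- as.vector(t(block))               # rep-major ordering
  }
  structure(list(points = pts,
                 rep = rep(seq_len(R), each = Tn),
                 time = rep(as.integer(times), times = R)),
            class = "state_pointset")
}

#' Select embedding parameters by the Ragwitz local-predictor criterion
#'
#' For every candidate `(d, tau)` the channel is embedded over all
#' repetitions, and each state's next sample is predicted as the mean of the
#' next samples of its `k_predict` nearest neighbours in the pooled ensemble
#' state space (max-norm; same-repetition neighbours inside the Theiler
#' window excluded). The pair minimising the mean squared one-step
#' prediction error is returned, with ties broken toward smaller `d`, then
#' smaller `tau`. Because the error is itself estimated from data, "tie" is
#' judged statistically: the smallest candidate whose error lies within one
#' standard error of the minimum is selected (a parsimony rule; excess
#' embedding dimensions waste data and dilute the state with uninformative
#' coordinates). This selection keeps a process's past state maximally
#' informative about its future, which avoids overestimating TE.
#'
#' @param data an [ensemble_ts()].
#' @param channel channel label or index.
#' @param dim_candidates integer vector of candidate dimensions.
#' @param tau_candidates candidate delays in samples, or `NULL` to use
#'   `{0.2, 0.4, ..., 1.0}` times the autocorrelation decay time, rounded to
#'   >= 1 sample.
#' @param k_predict number of neighbours for the local predictor.
#' @param theiler_mode `"act"`, `"span"` or a fixed number of samples;
#'   the default takes `max(embedding span, ACT)` per candidate.
#' @param times 0-based reference times to pool over, or `NULL` for all
#'   admissible times of the full repetition.
#' @param max_points cap on pooled points per candidate (evenly thinned
#'   beyond this), keeping the search affordable on long recordings.
#' @return An [embedding_params()] whose `theiler` field is set per
#'   `theiler_mode`; the error table is attached as attribute `"errors"`.
#' @export
ragwitz_optimize <- function(data, channel, dim_candidates = 1:8,
                             tau_candidates = NULL, k_predict = 4,
                             theiler_mode = "max", times = NULL,
                             max_points = 5000) {
  stopifnot(inherits(data, "ensemble_ts"))
  if (length(dim_candidates) == 0) stop("empty `dim_candidates`")
  m <- channel_matrix(data, channel)
  act <- act_samples(data, channel)
  if (is.null(tau_candidates))
    tau_candidates <- sort(unique(pmax(1L, as.integer(round(seq(0.2, 1, by = 0.2) * act)))))
  if (length(tau_candidates) == 0) stop("empty `tau_candidates`")

  if (sd(as.vector(m)) == 0) {
    warning("constant series: all prediction errors are zero, ",
            "returning smallest candidates")
    return(embedding_params(min(dim_candidates), min(tau_candidates),
                            theiler = act))
  }

  theiler_for <- function(p)
    switch(as.character(theiler_mode),
           act = act,
           span = embedding_span(p),
           max = max(embedding_span(p), act),
           as.integer(theiler_mode))

  grid <- expand.grid(tau = sort(tau_candidates), dim = sort(dim_candidates))
  grid <- grid[order(grid$dim, grid$tau), ]
  errs <- rep(NA_real_, nrow(grid))
  ses <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- embedding_params(grid$dim[i], grid$tau[i])
    margin <- (p$dim - 1L) * p$tau
    tt <- if (is.null(times)) seq.int(margin, ncol(m) - 2L) else
      times[times >= margin & times <= ncol(m) - 2L]
    if (length(tt) <= k_predict) next
    if (length(tt) * nrow(m) > max_points) {
      keep <- unique(as.integer(seq(1, length(tt),
                                    length.out = max(1, max_points %/% nrow(m)))))
      tt <- tt[keep]
    }
    ps <- delay_embed(data, channel, p, tt)
    th <- theiler_for(p)
    idx <- cpp_knn_idx(ps$points, as.integer(k_predict),
                       as.integer(ps$rep), as.integer(ps$time),
                       as.integer(th), TRUE)
    nxt <- m[cbind(ps$rep, ps$time + 2L)]      # value at t+1, R indexing
    pred <- rowMeans(matrix(nxt[idx], nrow = nrow(idx)))
    sq <- (pred - nxt)^2
    errs[i] <- mean(sq)
    ses[i] <- sd(sq) / sqrt(length(sq))
  }
  if (!any(is.finite(errs)))
    stop("no admissible (dim, tau) candidate for this repetition length")
  i_min <- which.min(errs)
  # one-SE parsimony rule: smallest (d, tau) statistically tied with the min
  i_best <- which(errs <= errs[i_min] + ses[i_min])[1]
  best <- embedding_params(grid$dim[i_best], grid$tau[i_best])
  out <- embedding_params(best$dim, best$tau, theiler = theiler_for(best))
  attr(out, "errors") <- cbind(grid, mse = errs)
  out
}

#' Build the four aligned point clouds of one TE estimation problem
#'
#' TE decomposes into four Shannon entropies over the joint space and its
#' marginals. For every reference time `t` inside the window and every
#' repetition, the rows are, in identical order across clouds:
#' `J  = (y_t, y-state at t-1, x-state at t-u)`,
#' `M1 = (y_t, y-state at t-1)`,
#' `M2 = (y-state at t-1, x-state at t-u)`,
#' `C  = (y-state at t-1)`.
#' The target's conditioning state ends at `t-1` (self-prediction-optimal
#' form); the source state is taken `u` samples back, `u >= 1`.
#'
#' @param data an [ensemble_ts()] holding both channels.
#' @param source,target channel labels or indices (source X, target Y).
#' @param params_x,params_y [embedding_params()] for source and target.
#' @param u assumed information-transfer delay in samples (>= 1).
#' @param window an [analysis_window()] of reference times.
#' @param k neighbour parameter carried into estimation.
#' @param stride keep every `stride`-th reference time inside the window
#'   (temporal thinning of the mixed time/ensemble pooling; 1 = every
#'   sample).
#' @return An object of class `te_pointsets` with matrices `J`, `M1`, `M2`,
#'   `C`, origin tags `rep`/`time`, and `meta`.
#' @export
build_te_pointsets <- function(data, source, target, params_x, params_y,
                               u, window, k = 4, stride = 1L) {
  stopifnot(inherits(data, "ensemble_ts"),
            inherits(params_x, "embedding_params"),
            inherits(params_y, "embedding_params"),
            inherits(window, "analysis_window"))
  u <- as.integer(u)
  if (u < 1) stop("`u` must be >= 1 sample")
  L <- n_samples(data)
  # margins: y-state at t-1 needs t-1 >= (d_y-1)*tau_y; x-state at t-u
  # needs t-u >= (d_x-1)*tau_x
  t_min <- max((params_y$dim - 1L) * params_y$tau + 1L,
               (params_x$dim - 1L) * params_x$tau + u)
  if (window$t_start < t_min)
    stop("window start ", window$t_start, " incompatible with embedding ",
         "margins and u = ", u, "; minimal legal t_start is ", t_min)
  if (window$t_end > L)
    stop("window end ", window$t_end, " beyond repetition length ", L)
  times <- seq.int(window$t_start, window$t_end - 1L, by = as.integer(stride))

  ym <- channel_matrix(data, target)
  y_now <- as.vector(t(ym[, times + 1L, drop = FALSE]))      # rep-major
  y_state <- delay_embed(data, target, params_y, times - 1L)
  x_state <- delay_embed(data, source, params_x, times - u)

  J <- unname(cbind(y_now, y_state$points, x_state$points))
  M1 <- unname(cbind(y_now, y_state$points))
  M2 <- unname(cbind(y_state$points, x_state$points))
  C <- unname(y_state$points)
  structure(list(J = J, M1 = M1, M2 = M2, C = C,
                 rep = y_state$rep,
                 time = rep(as.integer(times), times = n_repetitions(data)),
                 k = as.integer(k),
                 meta = list(u = u, window = window, params_x = params_x,
                             params_y = params_y)),
            class = "te_pointsets")
}

#' Restrict a TE point-set collection to its first rows
#'
#' Keeps the first `n` reference rows (repetition-major order) in all four
#' aligned clouds; used to study estimator robustness as a function of the
#' number of pooled ensemble points.
#'
#' @param psets a [build_te_pointsets()] result.
#' @param n number of rows to keep (`<=` available rows).
#' @return A `te_pointsets` object with `n` rows.
#' @export
head_pointsets <- function(psets, n) {
  stopifnot(inherits(psets, "te_pointsets"))
  if (n > nrow(psets$J)) stop("only ", nrow(psets$J), " rows available")
  idx <- seq_len(n)
  psets$J <- psets$J[idx, , drop = FALSE]
  psets$M1 <- psets$M1[idx, , drop = FALSE]
  psets$M2 <- psets$M2[idx, , drop = FALSE]
  psets$C <- psets$C[idx, , drop = FALSE]
  psets$rep <- psets$rep[idx]
  psets$time <- psets$time[idx]
  psets
}
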