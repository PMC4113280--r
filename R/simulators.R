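#' Time-varying coupling-strength profile
#'
#' Smooth coupling onsets are modelled with scaled hyperbolic tangents.
#' `"step_tanh"` rises from 0 to 1 around a single inflection point,
#' `0.5 * (1 + tanh(slope * (t - t0)))`; with the default slope of 0.05 per
#' ms the transition spans roughly 200 ms. `"two_step_tanh"` superposes two
#' such steps (half weight each), giving a first plateau at 0.5 after the
#' first inflection and a second, strictly higher plateau at 1 after the
#' second. Profiles are multiplied by the scenario's coupling strength.
#'
#' @param kind `"off"`, `"step_tanh"` or `"two_step_tanh"`.
#' @param t_grid times (ms) at which to evaluate the profile.
#' @param slope tanh slope per ms.
#' @param inflections inflection time(s) in ms (one for `step_tanh`, two
#'   for `two_step_tanh`).
#' @return Numeric vector of profile values in `[0, 1]`.
#' @export
coupling_profile <- function(kind = c("off", "step_tanh", "two_step_tanh"),
                             t_grid, slope = 0.05,
                             inflections = c(1000, 2000)) {
  kind <- match.arg(kind)
  switch(kind,
         off = rep(0, length(t_grid)),
         step_tanh = 0.5 * (1 + tanh(slope * (t_grid - inflections[1]))),
         two_step_tanh = 0.25 * (2 + tanh(slope * (t_grid - inflections[1])) +
                                   tanh(slope * (t_grid - inflections[2]))))
}

#' Configuration for a coupled AR(1) pair
#'
#' Two AR(1) processes with time-varying cross-coupling,
#' \deqn{x_t = a_x x_{t-1} + \gamma_{yx}(t) y_{t-\delta_{yx}} + \eta_t}
#' \deqn{y_t = a_y y_{t-1} + \gamma_{xy}(t) x_{t-\delta_{xy}} + \xi_t}
#' with unit-variance Gaussian innovations. The three standard scenarios
#' are: `"unidirectional"` (X to Y, onset ~1 s), `"two_step"` (X to Y with
#' increases at ~1 s and ~2 s) and `"bidirectional"` (X to Y at ~1 s plus
#' Y to X at ~2 s). Delays are in ms (= samples at 1000 Hz).
#'
#' @param scenario one of `"unidirectional"`, `"two_step"`,
#'   `"bidirectional"`.
#' @param ... overrides for any configuration field.
#' @return List of class `ar_config`.
#' @export
ar_config <- function(scenario = c("unidirectional", "two_step",
                                   "bidirectional"), ...) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    unidirectional = list(a_x = 0.35, a_y = -0.35,
                          gamma_xy = 0.75, gamma_yx = 0,
                          delta_xy = 10, delta_yx = 0,
                          profile_xy = "step_tanh", infl_xy = 1000,
                          profile_yx = "off", infl_yx = 2000),
    two_step = list(a_x = 0.35, a_y = -0.35,
                    gamma_xy = 0.75, gamma_yx = 0,
                    delta_xy = 10, delta_yx = 0,
                    profile_xy = "two_step_tanh", infl_xy = c(1000, 2000),
                    profile_yx = "off", infl_yx = 2000),
    bidirectional = list(a_x = 0.35, a_y = -0.35,
                         gamma_xy = 0.475, gamma_yx = -0.4,
                         delta_xy = 10, delta_yx = 20,
                         profile_xy = "step_tanh", infl_xy = 1000,
                         profile_yx = "step_tanh", infl_yx = 2000))
  cfg$slope <- 0.05
  cfg$n_reps <- 50
  cfg$rep_length_ms <- 3000
  cfg$sampling_rate <- 1000
  cfg$scenario <- scenario
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = "ar_config")
}

#' Simulate a coupled AR(1) pair with time-varying coupling
#'
#' Iterates the two AR(1) recursions of [ar_config()] with fresh
#' unit-variance Gaussian innovations per repetition. Marginal stability
#' requires `|a| < 1`; pre-history (samples before 0, including the delayed
#' cross terms at early times) is taken as 0, which matches the couplings
#' being effectively off at the start of a repetition.
#'
#' @param cfg an [ar_config()].
#' @param seed optional integer seed.
#' @return An [ensemble_ts()] with channels `"X"` and `"Y"`.
#' @export
simulate_ar_pair <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "ar_config"))
  if (abs(cfg$a_x) >= 1 || abs(cfg$a_y) >= 1)
    stop("explosive parameterization: need |a_x| < 1 and |a_y| < 1")
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sampling_rate
  Tn <- as.integer(round(cfg$rep_length_ms / 1000 * fs))
  R <- cfg$n_reps
  ms_per_sample <- 1000 / fs
  t_ms <- (seq_len(Tn) - 1) * ms_per_sample
  g_xy <- cfg$gamma_xy * coupling_profile(cfg$profile_xy, t_ms,
                                          cfg$slope, cfg$infl_xy)
  g_yx <- cfg$gamma_yx * coupling_profile(cfg$profile_yx, t_ms,
                                          cfg$slope, cfg$infl_yx)
  dxy <- as.integer(round(cfg$delta_xy / ms_per_sample))
  dyx <- as.integer(round(cfg$delta_yx / ms_per_sample))
  if (any(g_xy != 0) && dxy < 1) stop("delta_xy must be >= 1 sample")
  if (any(g_yx != 0) && dyx < 1) stop("delta_yx must be >= 1 sample")

  x <- matrix(0, R, Tn)
  y <- matrix(0, R, Tn)
  ex <- matrix(rnorm(R * Tn), R, Tn)
  ey <- matrix(rnorm(R * Tn), R, Tn)
  for (t in seq_len(Tn)) {
    xl <- if (t > 1) x[, t - 1] else 0
    yl <- if (t > 1) y[, t - 1] else 0
    xd <- if (dxy >= 1 && t > dxy) x[, t - dxy] else 0
    yd <- if (dyx >= 1 && t > dyx) y[, t - dyx] else 0
    x[, t] <- cfg$a_x * xl + g_yx[t] * yd + ex[, t]
    y[, t] <- cfg$a_y * yl + g_xy[t] * xd + ey[, t]
  }
  vals <- array(0, dim = c(2, R, Tn))
  vals[1, , ] <- x
  vals[2, , ] <- y
  ensemble_ts(vals, fs, c("X", "Y"))
}

#' Configuration for a delay-coupled Lorenz pair
#'
#' Two Lorenz systems in the classic chaotic regime (Prandtl number 10,
#' Rayleigh number 28, geometric scale 8/3), with a unidirectional delayed
#' diffusive drive from the source's V-coordinate onto the target's
#' V-equation, `+ gamma * (V1(t - delta) - V2(t))`, active only inside
#' `coupling_window` (ms within a repetition). The V-coordinates of both
#' systems are the observables. `tscale` maps Lorenz natural time units to
#' wall time (units per ms); delays and windows are stated in ms.
#'
#' @param ... overrides for any configuration field: `prandtl`, `rayleigh`,
#'   `scale`, `gamma`, `delta` (ms), `coupling_window` (`c(on, off)` ms;
#'   may start before 0 to have the drive active from the beginning),
#'   `n_reps`, `rep_length_ms`, `sampling_rate` (Hz), `tscale`,
#'   `burn_ms` (discarded lead-in per repetition), `h_ms` (integration
#'   step).
#' @return List of class `lorenz_config`.
#' @export
lorenz_config <- function(...) {
  cfg <- list(prandtl = 10, rayleigh = 28, scale = 8 / 3,
              gamma = 2, delta = 45, coupling_window = c(1000, 2000),
              n_reps = 150, rep_length_ms = 3000, sampling_rate = 1000,
              tscale = 0.03, burn_ms = 500, h_ms = 0.1)
  override <- list(...)
  cfg[names(override)] <- override
  if (cfg$gamma != 0 && cfg$delta <= 0) stop("delta must be > 0 when gamma != 0")
  structure(cfg, class = "lorenz_config")
}

#' Simulate a delay-coupled Lorenz pair
#'
#' Integrates the delay differential equations of [lorenz_config()] with a
#' fixed-step 4th-order Runge-Kutta scheme; the delayed source coordinate
#' is linearly interpolated from a per-repetition history buffer (the step
#' is a small fraction of the coupling delay). Each repetition starts from
#' independent random initial conditions followed by a burn-in before
#' recording, so repetitions are independent draws from the attractor.
#'
#' @param cfg a [lorenz_config()].
#' @param seed optional integer seed.
#' @return An [ensemble_ts()] with channels `"V1"` (source) and `"V2"`
#'   (target).
#' @export
simulate_lorenz_pair <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "lorenz_config"))
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$sampling_rate
  dt_sample <- 1000 / fs
  n_samples <- as.integer(round(cfg$rep_length_ms / dt_sample))
  if (cfg$h_ms > 0.1 * cfg$delta && cfg$gamma != 0)
    stop("integration step must be <= 0.1 * delta")
  out <- cpp_lorenz_pair(as.integer(cfg$n_reps), n_samples, dt_sample,
                         cfg$h_ms, cfg$prandtl, cfg$rayleigh, cfg$scale,
                         cfg$gamma, cfg$delta, cfg$coupling_window[1],
                         cfg$coupling_window[2], cfg$tscale, cfg$burn_ms)
  vals <- array(0, dim = c(2, cfg$n_reps, n_samples))
  vals[1, , ] <- out$V1
  vals[2, , ] <- out$V2
  ensemble_ts(vals, fs, c("V1", "V2"))
}
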