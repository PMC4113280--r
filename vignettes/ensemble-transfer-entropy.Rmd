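---
title: "Ensemble transfer entropy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble transfer entropy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transfer entropy (TE) measures directed information transfer from a source
process $X$ to a target process $Y$ as a conditional mutual information:
how much the source's past state tells us about the target's next value,
beyond what the target's own past already tells us. Estimating any
information-theoretic functional requires many realizations of the random
variables involved. The standard shortcut — pooling observations over time —
silently assumes stationarity, which experimental recordings (neural data
above all) routinely violate: stimulus-locked dynamics make the underlying
distributions change within a trial.

This package takes the ensemble route instead. Experiments are repeated;
each repetition (trial) is treated as an independent realization of the
same non-stationary process (cyclostationarity over repetitions). State
vectors from all repetitions at the *same within-trial time* are pooled
into one ensemble search space, so the estimated distributions are local in
time and TE becomes time-resolved. The cost is that surrogate statistics
must be recomputed for every surrogate data set — the computational burden
the batched neighbour-search backend is built for.

## Functional and estimator

With $y_t$ the target's next value, $\mathbf{y}_{t-1}$ the target's delay
state ending at $t-1$, and $\mathbf{x}_{t-u}$ the source's delay state taken
$u$ samples back, the estimated functional is

$$TE_{SPO}(X \to Y, t, u) =
  I\!\left(y_t ;\, \mathbf{x}_{t-u} \mid \mathbf{y}_{t-1}\right),$$

the self-prediction-optimal (SPO) form: the conditioning state ends at
$t-1$ regardless of $u$, so the target's own predictable structure is fully
removed. As a function of the assumed delay $u$, TE is maximal when $u$
equals the true information-transfer delay; `scan_delays()` exploits this
to reconstruct coupling delays as the argmax over a scan range.

The estimator decomposes the conditional mutual information into four
Shannon entropies over the joint space $J = (y_t, \mathbf{y}_{t-1},
\mathbf{x}_{t-u})$ and its marginals, and estimates them jointly with the
Kraskov–Stögbauer–Grassberger (KSG, type 1) nearest-neighbour technique:
$k$ is fixed only in $J$; each reference point's $k$-th neighbour distance
(max-norm) is projected into the marginal spaces as a strict counting
radius. Keeping one spatial scale across the four terms makes their biases
largely cancel:

$$\widehat{TE} = \psi(k) + \left\langle
  \psi(n_{\mathbf{y}} + 1) - \psi(n_{y\mathbf{y}} + 1)
  - \psi(n_{\mathbf{y}\mathbf{x}} + 1)\right\rangle .$$

The average runs over all reference rows: all repetitions, and all
reference times inside the analysis window (mixed time/ensemble pooling; a
one-sample window is the purely ensemble-based limit, and the window length
sets the temporal resolution of the analysis).

Estimates are reported in nats (natural logarithm). The analytic check
used throughout the tests: for jointly Gaussian variables the conditional
mutual information is $-\tfrac12\log(1-\rho^2_{\text{partial}})$, which the
estimator must reproduce within its sampling error.

## Parameters that matter

* **`k` (default 4)** — KSG neighbour count. Small $k$ keeps the
  estimator local (small bias, larger variance); 4 is the standard
  operating point for this estimator family and is used in every analysis
  here.
* **Embedding `dim`, `tau`** — per-channel Takens parameters, selected by
  `ragwitz_optimize()`: minimise the mean squared error of a local
  $k$-NN predictor of the next sample (neighbours pooled across
  repetitions). Defaults scan $d \in 1..8$ and $\tau \in \{0.2, 0.4, ...,
  1.0\}\times$ACT (autocorrelation decay time, rounded to $\ge 1$ sample).
  The aggregation of the local predictor is the neighbour *mean* — the
  smooth, standard choice.
  Because the criterion is itself estimated, selection uses a
  one-standard-error parsimony rule: the smallest $(d, \tau)$ whose error
  is within one standard error of the minimum. Excess dimensions waste
  data and — for the *source* — shift the reconstructed delay: if the
  source state spans $(d_x - 1)\tau_x$ samples beyond its most recent
  coordinate, every $u$ in $[\delta - (d_x-1)\tau_x,\ \delta]$ places the
  causal sample inside the state and TE is constant on that plateau, so
  the finite-sample argmax can land anywhere on it. The parsimony rule
  keeps embeddings minimal-sufficient and the scan peak sharp.
* **Theiler window** — same-repetition neighbours within
  $\max(\text{embedding span}, \text{ACT})$ samples of the reference time
  are excluded from all searches (mode switchable: `act`, `span`,
  `fixed:n`). Serially correlated points are not independent realizations;
  without the exclusion they masquerade as close neighbours under mixed
  pooling. Cross-repetition points are never excluded.
* **Analysis window** — half-open `[t_start, t_end)` in samples.
  Distinct from the *embedding window* (the history each reference point
  consumes): margins require
  $t \ge \max((d_y-1)\tau_y + 1,\ (d_x-1)\tau_x + u)$.
* **Assumed delay `u`** — source state taken at $t-u$; minimum 1 sample
  (u = 0 would condition on the source's present). Scanned over a range
  for delay reconstruction; ties in the argmax resolve to the smallest
  `u`.
* **Surrogates `N'` (default 500)** — trial-shuffling surrogates; the
  target's repetition axis is permuted by a uniformly drawn *derangement*
  (a fixed repetition would keep its original pairing and bias the null
  toward the observed value), leaving within-repetition time order intact.
  The p-value is the literal proportion of surrogate TE values $\ge$ the
  observed one; a conservative $(c+1)/(N'+1)$ variant is available.
  Correction across result rows defaults to Benjamini–Hochberg FDR
  (`bonferroni` available).

## The simulators and what they emulate

The two bundled generators reproduce the standard validation test-beds for
non-stationary directed-coupling analysis; all validation data in the
tests and the acceptance script come from them.

**AR(1) pair with tanh-modulated coupling** (`simulate_ar_pair()`):
$x_t = a_x x_{t-1} + \gamma_{yx}(t)\, y_{t-\delta_{yx}} + \eta_t$ and
$y_t = a_y y_{t-1} + \gamma_{xy}(t)\, x_{t-\delta_{xy}} + \xi_t$ with
unit-variance Gaussian innovations, $a_x = 0.35$, $a_y = -0.35$.
Couplings rise smoothly as scaled hyperbolic tangents (slope 0.05 per ms,
transition $\approx$ 200 ms) with inflection points at 1 s and/or 2 s.
Three scenarios: unidirectional ($\gamma_{xy} = 0.75$, $\delta_{xy} = 10$
ms, onset 1 s), two-step (same, plateaus at half and full strength after
1 s and 2 s; realized as the equal superposition of two tanh steps), and
bidirectional ($\gamma_{xy} = 0.475$ at 10 ms from 1 s;
$\gamma_{yx} = -0.4$ at 20 ms from 2 s). Defaults are 50 repetitions of
3000 samples at 1000 Hz.

**Delay-coupled Lorenz pair** (`simulate_lorenz_pair()`): two Lorenz
systems in the classic chaotic regime (Prandtl 10, Rayleigh 28, scale
8/3), the target's V-equation receiving a delayed diffusive drive
$\gamma\,(V_1(t-\delta) - V_2)$ with $\delta = 45$ ms, active only inside
a coupling window (default 1000–2000 ms of a 3000 ms repetition). The
V-coordinates are the observables. Integration is fixed-step RK4 with the
delayed coordinate linearly interpolated from a per-repetition history
buffer; the step (0.1 ms) is a small fraction of both the coupling delay
and the attractor time scale. Initial conditions are random per
repetition, followed by a 500 ms burn-in, so repetitions are independent
attractor draws.

Two generator constants are design choices of this package and are
configurable: the natural-time scale (`tscale = 0.03` units/ms, placing
the attractor's autocorrelation decay near 10 ms so that a 45 ms delay is
comfortably resolvable at 1000 Hz sampling), and the coupling strength
(`gamma = 2`). The choice of $\gamma$ was made by a simple lagged
cross-correlation scan — strong enough that the lagged dependence peaks
unmistakably at the simulated delay, weak enough that the two systems do
not synchronize (by $\gamma \approx 3$ the pair is fully synchronized and
the direction of transfer degenerates). Delay recovery is insensitive to
$\gamma$ across the usable range.

What the generators do *not* emulate: measurement noise, volume
conduction/linear mixing between channels, non-Gaussian innovations,
drifts across repetitions, or unequal repetition counts. Passing tests
therefore demonstrate estimator correctness under clean, repeatable
conditions — not robustness to the full messiness of recorded data.

## Numerical choices

* **Max-norm metric** everywhere; required for the KSG projection of the
  joint-space radius into marginal spaces to be exact.
* **Strict inequality** in range counts (type-1 convention); a radius of 0
  counts 0, and distance ties at the $k$-th neighbour are handled
  deterministically by the strict count.
* **Backends** — `oracle` is an exhaustive all-pairs scan; `tree` is a
  k-d tree (median split on the widest box side, max-norm pruning). They
  return identical results on every instance, which the tests assert; the
  batched interface guarantees per-chunk results independent of batch
  composition.
* **Duplicate points** make strict counting degenerate; they are broken by
  seeded uniform jitter at $10^{-8}$ of the data scale, applied
  consistently to the joint space and its marginals (`fail` mode
  available).
* **Degenerate inputs** — constant series in `ragwitz_optimize()` return
  the smallest candidates with a warning; windows violating embedding
  margins raise errors naming the minimal legal start; a repetition count
  of 1 makes the surrogate scheme (and ensemble pooling) undefined and is
  rejected.
* **0-based, half-open indexing** for all sample positions; the internal
  unit is samples, with milliseconds converted at the command-line
  boundary via the sampling rate.

## Design points that were genuinely open

* **Pooling for embedding optimisation** — over the full repetition (the
  default; both channels then use one embedding for all windows) or per
  analysis window (`times` argument). Full-repetition pooling is the
  stabler default for short windows.
* **Mixed pooling weighting** — with a window longer than one sample, the
  $\psi$-terms are averaged per reference row across the whole window
  (neighbour counts averaged over the epoch), not computed as separate
  per-time TE values that are then averaged.
* **Which surrogate test to run in a scan** — after delay scanning, only
  the argmax delay's TE is tested against surrogates (testing every
  scanned delay multiplies the dominant cost by the scan length; it can be
  enabled by running `estimate_te()` per delay with surrogate loops).
  Note the selection step means the tested value is a maximum over the
  scan; under the null this is mildly anticonservative, which matters when
  interpreting borderline p-values.
* **Corrections** — across result rows (pairs × windows) by FDR at the
  designated alpha; correcting additionally across scanned delays is not
  done, matching the single-test-per-window output.
* **Group-level thresholding** — `group_binomial()` flags a link when the
  binomial tail probability of its across-subject count under a
  per-subject null probability `p0` falls below alpha; `p0` defaults to
  the per-subject corrected alpha and is exposed, since different
  corrected levels imply different `p0`.

## Problem sizes used in the validation suite

The test suite and the acceptance script run the benchmark systems at the
sizes the analyses are designed for: AR scenarios at 50 repetitions × 3000
samples with 300-sample analysis windows (15 000 pooled points per
estimate, delay scans over 1–25 ms); the Lorenz benchmark at 50
repetitions with a 250-sample window inside the coupling interval (12 500
points, scans over 35–55 ms) and 100 surrogates for the null windows,
which are tested with the max-over-scan statistic on a coarse delay grid
and temporally thinned reference times so that the surrogate scans stay
affordable; the robustness benchmark uses 300 ms repetitions with subsets
of the first 500–10 000 embedded points (only the repetitions those
subsets reach are simulated). Calibration-style properties (p-value
uniformity, type-I error) use many small replicate analyses (hundreds of
runs at ~10³ points) rather than few large ones.

## Known limitations

* Bivariate only: no conditioning on further processes, so cascades and
  common drivers can produce spurious pairwise links; post-hoc graph
  pruning is out of scope.
* The volume-conduction output field is reserved and always 0; no
  instantaneous-mixing test is computed.
* Local (per-event) transfer entropy is not computed; estimates are
  averages over the ensemble.
* Delay reconstruction inherits the plateau ambiguity of over-embedded
  sources described above; with the parsimony rule this is rare but can
  still move the argmax one embedding-delay early on genuinely
  higher-order sources.
* Repetition counts must be equal across channels, and repetitions are
  assumed exchangeable; drifting ensembles (see `validate_ensemble()`)
  violate the method's core assumption.
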