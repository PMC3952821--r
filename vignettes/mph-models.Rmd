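---
title: "Mixed pair hidden Markov models for stimulus-response alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed pair hidden Markov models for stimulus-response alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mphmm)
```

## The model

Classical receptive-field estimators (spike-triggered averaging, reverse
correlation, spike-triggered covariance) assume a *fixed* stimulus-response
relationship: one filter, one nonlinearity, one constant latency.  Real
neurons violate this in two common ways: spike times jitter around their
stimulus-locked positions, and the stimulus-response mapping itself can
switch with hidden internal states.

`mphmm` treats response modelling as a *dynamic alignment* problem.  A
mixed pair hidden Markov model (MPH) is a generative model of the **pair**
(stimulus sequence $X = x_1..x_{T_x}$, binned spike response
$R = r_1..r_{T_r}$).  Hidden states come in three kinds:

* **M-states** emit a (stimulus, response) pair jointly,
  $e_s(x, r) = P(r \mid s)\, p(x \mid s, r)$, with one Gaussian (or
  Gaussian mixture) stimulus model per response symbol.  An M-state is a
  diagonal step in the alignment matrix: it *matches* response position $j$
  to stimulus position $i$.
* **X-states** emit only a stimulus vector (horizontal step).
* **R-states** emit only a response symbol (vertical step).

X and R steps change the running lag $j - i$ between the two sequences, so
a hidden path encodes both a segmentation into coding regimes (which
M-state was active) and a time-varying alignment (each spike's individual
latency).  Transition probabilities $a_{ss'}$, initial probabilities
$\rho_s$ and final probabilities $\tau_s$ complete the parameter set; we
adopt the pair-HMM convention that each transition row plus its final
probability sums to one, so the model is a proper distribution over finite
paths.  Dynamic programming runs over the banded alignment tensor
$(i, j, s)$ with $|i - j| \le W$; the band width $W$ caps the modelled lag
and gives $O((T_x + T_r)\, W N^2)$ complexity.

Three template architectures cover the use cases:

* `mph_mn(1, ...)` — the **M-MPH**: one M-state, no timing flexibility.
  With shared covariance $\Sigma$ its posterior spike probability is
  exactly $\sigma(w^\top x + c)$ with $w = \Sigma^{-1}(\mu_1 - \mu_0)$,
  i.e. a sigmoid LNP model whose filter is the reverse-correlation
  (covariance-corrected STA) solution; for white stimuli it *is* the STA.
  `mph_as_lnp()` exposes this bridge in closed form, and the package
  verifies the identity to machine precision.
* `mph_mxr(...)` — the **MXR-MPH**: M + X + R states for spike-time
  jitter.  Covariances are fixed (identity for white stimuli, or the
  shrinkage-regularized stimulus covariance for correlated stimuli), the
  no-spike means are fixed to the ensemble mean, and the R-state never
  emits spikes, so every spike must be matched to a stimulus.  The free
  parameters are the spike-conditioned mean (the RF) and the
  transition/initial/final probabilities.
* `mph_mn(n, ...)` — the **M^n-MPH**: n M-states for switching receptive
  fields; hidden paths stay on the diagonal and the model is a
  Markov-switching response model.

## Learning and inference

`mph_fit()` runs EM.  The E-step uses the generalized forward and backward
recursions (compiled, log-domain throughout) to obtain cell posteriors
$\gamma(i,j,s)$ and expected transition counts; the M-step re-estimates
transitions, initial/final probabilities, discrete emissions, and
responsibility-weighted Gaussian-mixture moments, pooling sufficient
statistics over all training pairs before normalizing and re-imposing the
constraint flags afterwards.  The training log-likelihood is non-decreasing
(monitored to 1e-8 in the tests).  Because EM only finds local optima, the
fitter supports seeded multi-restarts and returns the restart with the
highest training likelihood; the switching experiments use 3 restarts.

The re-estimation of $\tau$ mirrors that of $\rho$ (normalized terminal
occupancies); with sequences hundreds of bins long this parameter carries
negligible information, but the symmetric update keeps every row exactly
normalized.

Inference tools:

* `mph_viterbi()` — most likely hidden path (alignment + state sequence),
  with deterministic tie-breaking (lowest precursor index; M preferred over
  X over R at termination).
* `alignment_kernel()` — the posterior distribution of lags $j - i$ over
  matched spike cells: the model's estimate of the jitter/latency
  distribution.  Negative lags mean spikes precede their matched stimulus.
  The summand uses M-state posteriors at spike positions; an
  `include_r` flag adds R-state posteriors for model variants whose
  R-states can spike (in the MXR configuration they cannot, so the choice
  is immaterial there).
* `response_probabilities()` — $P(r_j = 1 \mid X)$ per bin.  The model is
  first rewritten (`rewrite_for_inference()`): each M-state splits into two
  X-states chained to two deterministic R-states, each stochastic R-state
  splits into never/always-spike branches, with response probabilities
  moved onto transitions.  The rewriting is likelihood-equivalent (checked
  to 1e-9 on random models), and with deterministic response emissions the
  per-bin spike probability is the posterior mass of spike-branch states,
  normalized per response position.  A subtlety: the stimulus-half of a
  split M-state transiently occupies one lag below the band; the package
  tracks per-state lag bounds so the rewritten model visits exactly the
  cells an original M step passes through, and no others — a plain global
  band of $W + 1$ would let ordinary X/R states escape the original band
  and inflate the likelihood.
* `encode_map()` — the extended Viterbi that jointly maximizes over hidden
  paths *and* response sequences for a given stimulus.
* `fit_cascade()` / `apply_cascade()` — the output nonlinearity of the
  cascaded MPH, estimated by dividing the histogram of posterior spike
  probabilities at actual spikes by the histogram of all posterior spike
  probabilities (25 equal-width bins by default; empty bins filled by
  linear interpolation).  On data generated by the model itself this
  mapping is the identity up to sampling noise, which the tests use as a
  calibration check.

Every DP quantity is validated against `enumerate_paths()`, a brute-force
enumeration oracle that lists all hidden paths of a small instance with
exact probabilities; response-side quantities are additionally validated
against exhaustive enumeration of all response sequences.

## Simulators, baselines, and the synthetic experiments

The package regenerates all of its test data:

* `white_noise_stimulus()` and `correlated_stimulus()` (AR(1) in time with
  a squared-exponential cross-channel kernel — a stand-in for natural
  stimuli such as song spectrograms, with every channel marginally standard
  normal).
* `lnp_simulate()` — Bernoulli spiking through a sigmoid
  $f(z) = 1/(1 + e^{-\text{slope}(z - \theta)})$ whose offset $\theta$ is
  calibrated by bisection to a target mean rate.
* `discretized_lognormal_kernel()` — zero-mean integer-lag jitter kernels
  that grow a heavy right tail as the variance increases, and
  `apply_jitter()` (iid per-spike shifts; spikes jittered off the edges are
  dropped; colliding spikes collapse to one because responses are binary).
* `switching_lnp_simulate()` — a first-order Markov chain over LNP models.
* Baselines: `sta_fit()`, `rc_fit()` (with `regularize_covariance()`:
  $(1-\lambda) C + \lambda\,(\mathrm{tr}\,C/d)\, I$, trace-preserving,
  $\lambda = 0.1$ by default), `stc_fit()` (orthonormal eigenvectors of the
  spike-triggered covariance difference), moment-based sigmoid predictors
  for STA/RC, and a two-filter Gaussian-Bayes quadratic predictor for STC.
* Metrics: `evaluate_cc()` (Pearson correlation of Gaussian-smoothed
  rates, default width 2 bins), `cc_upper_bound()` (mean pairwise CC of
  independently re-jittered ideal spike trains), `cosine_similarity()`
  (plain and shift-invariant), `tv_distance()`.

### Study conditions

The experiment drivers fix the following conditions; they are the
package's scaled-down versions of the reference designs and are also what
`scripts/acceptance.R` runs.

* **Jitter experiment** (`run_jitter_experiment`): 2x10^4 bins of
  white-noise stimulus, 2 channels x 10-bin causal window (d = 20), LNP
  rate 0.015 spikes/bin, sigmoid slope 4, band width W = 8, 40 sequences
  of 500 bins split 90/10 into training and validation, jitter variance
  grid {0.25, 1, 4} bins^2 (small / moderate / large).  The generating RF
  is a Gabor-like filter with temporal period about 3 bins and norm 2.
  The fine temporal structure is deliberate and matters twice over:
  bin-scale jitter only blurs receptive fields whose temporal detail is
  comparable to the jitter scale, and that same detail is what gives the
  aligner per-lag discrimination.  With a temporally smooth RF (period
  well above the jitter scale) the STA is essentially unaffected by jitter
  and the maximum-likelihood MPH legitimately collapses to a constant-lag
  solution — there is nothing to align.
* **Switching experiment** (`run_switching_experiment`): 10^4 bins, 21
  stimulus channels used frame-by-frame (d = 21), two filters of norm 2
  related by an in-plane rotation, per-model rate 0.044 spikes/bin, equal
  Markov stay/switch probabilities (0.5/0.5), M^2-MPH with 3 EM restarts.
  Filter recovery is scored by best-match mean cosine (absolute value for
  STC, whose filters have arbitrary sign); prediction by validation CC,
  with the cascaded MPH as the model's reference configuration since the
  fitted model's implicit sigmoid steepness is tied to its means and is
  typically shallower than the generating nonlinearity.
* **Cascade experiment** (`run_cascade_experiment`): calibration on 10^5
  bins sampled from a known single-M-state model, then a steep-sigmoid
  (slope 12) LNP on 3x10^4 bins to show the cascade does not hurt (and
  typically improves) validation CC.

Two measurement conventions deserve a note.  First, the filter-similarity
metric in the jitter experiment is the *shift-invariant* cosine: the
asymmetric log-normal kernel anchors the model's internal lag reference at
the kernel mode, which can shift the fitted RF and the alignment kernel by
compensating integer lags without changing any prediction.  Second, the
alignment kernel reported for a collection of sequences is the
spike-count-weighted average of per-sequence kernels.

### What the synthetic data do and do not emulate

The generators reproduce the structural features the model targets —
stimulus-locked spiking through a static nonlinearity, iid spike-time
jitter with realistic asymmetry, Markov switching between filters — under
exactly known ground truth.  They do not emulate refractoriness, bursting,
rate adaptation, correlated (slowly varying) latency drift, non-Gaussian
natural-stimulus statistics (the correlated Gaussian process matches
second-order structure only), or spike-sorting artifacts.  Passing the
experiment-level checks therefore demonstrates correct algorithmics and
the claimed qualitative advantages in the modelled regime, not performance
on any particular real preparation.

## Numerical choices

* All DP in the log domain with streaming log-sum-exp; log-likelihoods at
  $T_x = 10^4$, d = 40 are finite and negative (tested).
* EM stops when the relative log-likelihood change drops below 1e-6
  (default), capped at 200 iterations; the experiment drivers cap at 60
  because the constrained templates converge in tens of iterations (the
  shared-covariance M-MPH converges in one).
* Free covariances get an eigenvalue floor of 1e-6 times the mean diagonal
  after every M-step; mixture components with zero responsibility get
  weight zero with a warning.
* Initialization: free spike-conditioned means start at the
  spike-triggered mean plus small Gaussian noise; free response marginals
  at the empirical spike rate; transition matrices keep their template
  values on the first restart and are Dirichlet-jittered on later
  restarts.  All seeded.
* Embedding: $x_t$ concatenates all channels over the causal window
  $[t - \tau_w + 1 + \text{offset},\, t + \text{offset}]$, zero-padded at
  the edges.  Overlapping windows violate emission independence across
  time; like the estimators it generalizes, the model ignores this.
* Response alphabet defaults to binary (V = 2).  Larger alphabets are
  supported by the DP and EM but the inference rewriting (and hence
  `response_probabilities`) is implemented for the binary case.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
emb <- stimulus_embedding(window_length = 10, channels = 2)
stim <- white_noise_stimulus(2, 20000)
X <- embed_stimulus(stim, emb)

# LNP ground truth with jittered spikes
w <- mphmm:::make_rf(2, 10)
lnp <- lnp_simulate(lnp_spec(w, slope = 4, target_rate = 0.015), X)
pmf <- discretized_lognormal_kernel(4, support = -8:8)
spikes <- apply_jitter(lnp$spikes, pmf)

pairs <- split_pair(mph_pair(X, spikes), 500)
fit <- mph_fit(mph_mxr(emb, band_width = 8), pairs[1:36],
               mph_control(max_iters = 60))
summary(fit)
cosine_similarity(coef(fit)[, 1], w, shift_invariant = TRUE, channels = 2)
plot(pooled_alignment_kernel(fit$model, pairs[1:36]))
pred <- predict(fit, pairs[[37]])
evaluate_cc(pred$spike_prob, pairs[[37]]$response)
```

## Known limitations

* Only local likelihood optima are found; the antidote is restarts, and
  the switching experiments occasionally need them.
* The alignment economics are real: when the per-spike emission evidence
  for a lag (set by RF structure and nonlinearity steepness) is weak
  relative to the transition cost of lag changes, the maximum-likelihood
  solution is a constant-lag model.  This is a property of the model
  class, not of the implementation; the vignette section on study
  conditions describes the regime where alignment is identifiable.
* Memory is O((Tx + Tr) W N) per pair; there is no checkpointed
  linear-memory variant, so the package targets desk-scale data.
* Decoding (inferring the stimulus from spikes) is not implemented.
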