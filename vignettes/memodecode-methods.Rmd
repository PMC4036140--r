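---
title: "Models and methods in memodecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in memodecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`memodecode` models two complementary views of multi-neuron hippocampal
spike data from a two-lever delayed-non-match-to-sample (DNMS) task: a
*signal model* that predicts output-region (CA1) spike trains from
input-region (CA3) spike trains, and a *memory decoding model* that
classifies single-trial spatio-temporal spike patterns into the two
memory categories (left / right lever). This vignette explains the
models, their assumptions, the tunable parameters, and the design
decisions taken where the method leaves choices open. All empirical
statements here are the ones the package's test suite and
`scripts/acceptance.R` themselves compute.

## Data model

A session is a pair of tables: spikes (`trial_id, neuron_id, region,
spike_time_s`) and behavioral events (`trial_id, event_code,
event_time_s`; `LS`/`RS` for left/right sample presses, `LN`/`RN` for
the non-match presses). For every sample event the perievent window −2
to +2 s is discretized into 2 ms bins, giving one binary N × 2000
pattern per trial (half-open bins, 0-based; multiple spikes in a bin
clip to 1, which is rare at hippocampal rates and required by the
per-bin Bernoulli model). Windows are concatenated across trials for
signal-model estimation, with segment boundaries recorded so that no
convolution ever crosses a trial boundary — perievent windows are not
contiguous in real time.

Unit pre-screening is reduced to a configurable mean-rate band filter
(`prescreen_neurons()`, defaults 0.5–50 Hz); peri-event histogram
inspection is a plotting helper (`plot_perievent_histogram()`), not a
hard filter, because no numeric criterion for it is established.

## The probit Laguerre–Volterra signal model

Each output neuron is a threshold neuron: a synaptic potential `u`
driven by the inputs through second-order self-kernels (memory 2 s =
1000 bins), an after-potential `a` driven by the neuron's own past
spikes through a feedback kernel `h` (lags 1..1000), and unit-variance
Gaussian noise against a threshold. Only `(c0 − θ)/σ` is identified, so
the implementation fixes `σ = 1, θ = 0` and lets the bias absorb the
threshold; Gaussian noise makes the per-bin spike probability a probit:
`P = Φ(u + a)`. Second-order *cross* kernels and third-order kernels
are out of scope.

Kernels are expanded on discrete orthonormal Laguerre bases generated
by a first-order low-pass filter cascaded with all-pass sections. The
decay pole `α` and the basis counts `J` (feedforward) and `L`
(feedback) are free parameters of the method; the defaults are
`α = 0.99` (effective decay ≈ 100 bins = 200 ms, a reasonable synaptic
and after-potential timescale truncated at the 2 s memory) and
`J = L = 3`. These are configuration, not claims: `glvm_config()`
exposes them.

### Estimation

Coefficients are estimated by group-LASSO penalized probit likelihood:
the penalty is `λ Σ_n (‖c1^(n)‖₂ + ‖c2s^(n)‖₂)` — one group per
input's first-order block, one per input's second-order block — so an
uninformative input is removed as a whole. The bias and the feedback
block are unpenalized. The optimizer is an outer IRLS quadratic
approximation with exact probit curvature and an inner block coordinate
descent whose penalized block update solves the group subproblem
*exactly* (eigen-decomposition plus a one-dimensional root find), with
a line search on the true penalized objective guaranteeing monotone
descent. Along a warm-started penalty path the curvature metric is
reused between fits and refreshed whenever a damped step reveals it is
stale — a proximal quasi-Newton scheme. Convergence is declared at a
relative objective change below `tol` (1e−6 for final fits; 1e−5 inside
cross-validation, where the held-out score is insensitive to the last
digits).

`λ` is chosen by two-fold cross-validation with *contiguous* blocks of
trial segments (first half vs second half of the session), minimizing
held-out NLL per bin; ties break to the larger (sparser) penalty. The
default grid is 30 log-spaced points from the analytic `λ_max` (the
smallest penalty zeroing every group at the intercept+feedback-only
fit) down four decades.

Estimation uses teacher forcing — feedback features come from the
*observed* output spikes — which is the standard practice for
point-process GLMs with history terms; free-run Monte Carlo simulation
(feedback from the realization's own spikes, pre-drawn Gaussian
thresholds, per-realization independent state, history reset at each
segment bound) serves prosthesis-style prediction. Both modes are
exposed and the caller chooses.

### Support recovery and its limits

Cross-validation-minimum penalties are known to over-select: the CV
curve is flat near its minimum, and the penalty that just removes a
truly irrelevant input often lies above the CV minimum when that input
carries as much *information mass* (rate × session length) as the
relevant ones. The support-recovery experiment in the test battery
therefore uses the regime where selection is reliable and realistic: a
low-rate (1 Hz) irrelevant input alongside a 25 Hz relevant one, short
sessions (8 trials of 400 bins), and a 15-point, two-decade penalty
grid. Under those conditions the truly-zero input's groups are zeroed
at the CV penalty in ≈90% of seeded replicates. On the main benchmark
(equal-rate inputs, 200 trials) the CV-minimum penalty keeps small
nonzero estimates on the zero-kernel inputs — the expected behavior of
CV-minimum selection, documented rather than hidden.

## The B-spline logistic memory decoder

Patterns are projected neuron-by-neuron onto `J = m + d + 1` clamped
B-spline basis functions (degree `d = 3`, uniform interior knots on the
2000-bin grid, Cox–de Boor recursion with `0/0 := 0`). The degree-0
indicators use half-open intervals with the final interval closed — a
deliberate replacement of the textbook strict inequalities, needed so
the basis sums to exactly 1 at the knots and on the full grid. The
recursion denominator uses the standard spacing `η_{j+d} − η_j`.

The classifier is an L1-penalized logistic regression on the `J·N`
features (bias unpenalized), fit by outer IRLS with inner exact
coordinate soft-threshold updates and a monotone line search; a
perfect-separation stop ends iteration when the NLL underflows. The
penalty is chosen by stratified four-fold cross-validation maximizing
held-out accuracy (ties to the sparser penalty; grid of 30 log-spaced
points spanning three decades below the analytic `λ_max`). `J` is
selected in 5–100 by the same criterion (`select_J()`); `J = 20` is the
typical optimum on the 4 s window and is the pipeline default.

The weights map back to the time domain as the classification feature
matrix `F_n(τ) = Σ_j B_j(τ) w_n(j)`; decoding with `F` against the raw
pattern is algebraically identical (to ≤1e−8) to decoding with the
projected features, and the tests assert that identity. The exact
boundary `P = 0.5` maps to the *right* (0) class.

Headline accuracies are *out-of-sample* by nested cross-validation
(outer stratified 4-fold for evaluation; inner 4-fold for the penalty),
since a single-level CV accuracy at the selected penalty is optimistic.
The outer-fold decoders are retained so they can be applied, weights
untouched, to other versions of the same trials — this is how the
re-encoding property is measured.

## Goodness-of-fit

The time-rescaling KS test integrates the fitted conditional intensity
between successive spikes; under a correct model the transformed
intervals are uniform. At 2 ms bins the per-bin intensity mass is taken
as `−log(1 − p)` rather than `p` — the discrete correction matters once
`p` is non-negligible. Binned observations also make the naive rescaled
intervals discrete, which pushes even a correct model outside the tight
`1.36/√n` band once spike counts are large; the implementation instead
accumulates the full-bin masses strictly between spike bins (the
survival probability to a bin edge is exactly exponential in the
accumulated mass) and draws the position within the spiking bin from
the truncated exponential implied by that bin's mass, making the
rescaled interval exactly unit-exponential under the model. The 95%/99%
constants are the standard KS asymptotics.

## The synthetic session generator

No recordings are distributed with the method, so the generator is the
package's test bed. CA3 neurons fire as inhomogeneous Bernoulli
processes: baseline rate times Gaussian rate-gain bumps that depend on
the trial's side (amplitude, center, width per neuron per side). CA1 is
generated by free-running a known ground-truth MIMO model on the CA3
trains, so the estimation stage faces a well-specified truth. Left
labels are assigned as an exact count (`round(n_trials · p_left)`)
under the seed; spike times sit at bin centers so that perievent
re-extraction reproduces the generating matrices bit-for-bit; the whole
generator is byte-deterministic under a fixed seed.

Three pinned scenarios ship with the package. `easy` — 8 CA3 (6
modulated at gain ×3, sd 125 ms bumps staggered over the window,
alternating preferred sides), 4 CA1, 200 trials — is the benchmark for
kernel recovery and decoding. `null` removes all modulation, so
decoding must sit inside the binomial chance band. `hard` has weak
modulation (gain ×1.5 in 2 of 6 neurons) and 100 trials.

Ground-truth coefficient scales are a power calculation, decided once:
with CA3 at 10 Hz (0.02 spikes/bin) and ~400k estimation bins, the
per-coefficient Fisher information gives a standard error near 0.05, so
first-order coefficients drawn at sd 0.8 yield an expected normalized
kernel error near 0.1 — comfortably estimable, and far from trivial.
Second-order coefficients are smaller (sd 0.05), the feedback kernel is
refractory (−4·exp(−τ/10 bins) projected on the feedback basis), and
each output's bias is centred analytically (using the closed-form first
and second moments of Laguerre features under Bernoulli inputs) so
every output sits near the 10 Hz target rather than drifting with the
random kernel draw.

What the generator does *not* emulate: bursting and non-Poisson input
statistics, slow nonstationarity across a session, correlated noise
between neurons, electrode artifacts, and spike-sorting errors. Tests
passing on these synthetics show the estimators are correct and
well-calibrated under the model's own assumptions; they do not show the
model fits any particular real recording.

## Problem sizes used in the shipped experiments

The test battery and `scripts/acceptance.R` run the `easy` benchmark at
its full 200 trials (400k bins), the null scenario at 100 trials, the
support-recovery toy at 8 trials × 400 bins × 20 replicates, and the KS
calibration at 50 replicates of a 400k-bin intensity; free-run
prediction uses 10 realizations in the pipeline runs (the decoder is
evaluated on the single-realization path, the prosthesis-like output;
the thresholded mean path is also emitted but at ~5 Hz output rates it
is almost always empty, and decodes at chance — both are reported).

## Known limitations

* The group-LASSO CV-minimum does not consistently zero irrelevant
  inputs whose firing rates match the relevant ones (see above); a
  one-standard-error rule would trade a little likelihood for sparsity
  but is not the selection rule implemented.
* The second-order feature blocks are strongly correlated with the
  first-order blocks at low rates, which inflates first-order
  coefficient variance; kernel-recovery error is dominated by this, not
  by bias.
* Free-run simulation cost is linear in realizations × bins in plain R;
  the pipeline default of 50 realizations is affordable but not
  real-time.
* Only binary (left/right) decoding is implemented; multinomial or
  other classifiers are out of scope.
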