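---
title: "Models and methods for dyadic convergence and its EEG correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dyadic convergence and its EEG correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadconv)
```

## The task and its measures

Two participants (a *dyad*) simultaneously estimate the position of a point on
a line whose integer endpoints lie between 0 and 150, 40 to 50 units apart.
The same stimulus is presented three consecutive times (feedback repetitions
FB1-FB3); after each response both estimates are displayed, so participants
may converge — or not — without any instruction or reward to do so. The
trial-level quantities are:

* **discrepancy** `D`: absolute difference between the two members' estimates
  at the same repetition, shared by both members;
* **scaled discrepancy**: `D` min-max scaled with constants taken from the
  distribution of *first-feedback* discrepancies of the whole dataset, applied
  to all repetitions. A global scale keeps the covariate comparable across
  feedbacks; a per-dyad variant is available (`scaling = "per-dyad"`). Values
  above the FB1 maximum (possible at later repetitions) are clipped into
  [0, 1] to keep the covariate on the stated support;
* **adjustment** `A`: absolute change in a participant's own estimate between
  consecutive repetitions, stored with the repetition whose feedback was being
  processed, so that the epoch of feedback *k* is modelled with the adjustment
  *k* to *k + 1*;
* **accuracy**: absolute difference between the midpoint of the two FB3
  estimates and the true position, per trial. A "centered difference compared
  to the actual point" admits several readings (signed error, mean of
  individual errors); the midpoint error is used because it is symmetric in
  the two members and non-negative, as the gamma-family response requires.

Cleaning follows three rules: responses beyond the empirical 95th percentile
(type-7 linear interpolation, strict inequality) become `NA` for behavioral
models and are dropped for signal models; trials whose FB1 discrepancy is
exactly zero are removed from the discrepancy- and adjustment-by-feedback
signal models (they carry no convergence information); both filters report
their counts. Outliers are removed *after* discrepancy computation.

## The behavioral generator

The synthetic dyad is intentionally the simplest process that produces the
two phenomena the downstream models need: a convergence trend across
repetitions and a point mass of exact agreements that motivates a hurdle
likelihood.

The first estimate is the true position plus Gaussian *perceptual* noise
(`perceptual_noise_sd`, default 2 units). At each later repetition both
agents update simultaneously from the repetition-*k* values: with probability
`p_match` (default 0.1) an agent copies the partner's previous estimate
verbatim; otherwise it closes a fraction `lambda` (default 0.3) of the gap,
with *execution* noise `update_noise_sd`. Responses are rounded to integers
(keypad entry) and clamped to the displayed range; rounding is configurable
off for continuous tests, and clamping reflects a design decision that the
simulator produces no out-of-range typos.

The execution noise is deliberately smaller than the perceptual noise
(default one quarter). With a single shared noise scale the expected
discrepancy need not decrease at all: after one update the signed gap is
`(1 - 2 lambda)` times the previous gap plus a *fresh* difference of two
noise draws, so for small `lambda` the noise term dominates and expected
discrepancy can even grow. Separating the two noise sources is also the
behaviorally plausible reading — the first response expresses perceptual
uncertainty about the point, while later responses are deliberate adjustments
anchored on two displayed numbers. With this separation the expected
discrepancy is non-increasing across repetitions for any `lambda` in (0, 1),
which is the property the tests verify by Monte Carlo.

Exact agreement arises from three routes: one-sided copying while the
partner's own update rounds onto the copied value, symmetric half-gap closure
(`lambda = 0.5`) rounding both members onto the common midpoint, and
persistence of earlier agreement. The zero fraction at FB2 grows with
`p_match` over the realistic range (tested on {0, 0.2, 0.4}); at extreme
`p_match` mutual copying merely swaps the two estimates and the effect can
saturate, which is why the property is stated on that range.

## The EEG generator

Each behavior row (participant x trial x feedback) yields one epoch, −2 to
2 s around feedback onset, default channels Fz/Cz/Pz (extra channels receive
background noise only). The signal is a sum of:

* **1/f background**: spectrally shaped Gaussian noise with exponent 1 and
  standard deviation `noise_scale` (default 5 uV). No ocular or muscle
  components are modelled; `inject_artifacts()` plants rectangular +/-150 uV
  spikes to exercise the rejection rule instead.
* **deflections**: windowed raised-cosine kernels, a frontocentral one over
  275-350 ms (gain `frn_gain`, negative for a negativity, default −4 uV per
  unit scaled discrepancy; weights Fz 1, Cz 0.8, Pz 0.3) and a centroparietal
  one over 350-700 ms (`late_pos_gain`, default +5 uV; weights 0.3/0.8/1).
  Kernels are normalized to unit mean over their own window, so a gain of
  −4 uV shifts that window's mean-amplitude feature by exactly −4 uV per unit
  covariate — the gain is calibrated in feature units, and the window
  integral has a closed form used by the tests.
* **oscillatory bursts**: theta 6 Hz, alpha 10 Hz, beta 20 Hz, Hann-enveloped
  over 180-500 ms, with band *power* multiplied by `(1 + gain x covariate)` —
  theta follows the scaled adjustment (positive default), alpha and beta the
  scaled discrepancy (negative defaults), matching the directions the
  analysis is meant to recover.

What the generator does **not** emulate: volume conduction and realistic
topographies, ocular/muscle artifacts, reaction times, non-stationary
background spectra, or between-subject variability in component latency.
Passing recovery tests therefore demonstrates that the pipeline measures what
was planted at realistic signal-to-noise ratios — not that it would be robust
to every pathology of real recordings.

## Feature extraction

The continuous-record path offers a zero-phase Hamming-window FIR band-pass
(0.1-30 Hz defaults; linear phase with the group delay removed, so a single
pass is exactly zero-phase) and epoching with per-epoch, per-channel baseline
subtraction (−100..0 ms). Epochs exceeding +/-100 uV between −100 and
1000 ms on any analyzed channel are rejected, and rejection is monotone in
the threshold.

ERP features are arithmetic means over half-open windows [start, end):
225-275, 275-350, 350-500, 500-700 ms at Fz, Cz, Pz. Time-frequency power
uses 7-cycle complex Morlet wavelets (`sigma_t = n_cycles / (2 pi f)`,
L2-normalized) on a 1-30 Hz grid with 1 Hz spacing, implemented as FFT-based
linear convolution (a direct time-domain convolution serves as the test
oracle). The nominal wavelet support is +/-3 `sigma_t`; when that exceeds the
epoch, the wavelet is truncated symmetrically to the epoch length and
renormalized, provided the epoch covers at least +/-1 `sigma_t` (otherwise an
error) — taking a hard error at the nominal support would make the stated
1-30 Hz grid unusable on the stated 4 s epoch below 3 Hz. Edge samples within
half a wavelet length of either end are flagged, and all analysis windows lie
well inside the flagged margins for the bands analyzed (theta and above).
Power is divided by the mean over the −400..−100 ms baseline per epoch,
channel and frequency; band means use theta 4-8, alpha 8-12, beta 12-30 Hz
with shared edges assigned to the lower band (closed upper, open lower bound)
so no grid frequency is counted twice, and the early/late windows 180-230 and
230-500 ms.

## The multilevel models

All models share the structure "response ~ fixed effects + participants
nested in dyads", with treatment coding and the first feedback as reference:

| model | response | family | fixed | extra random terms |
|---|---|---|---|---|
| group-interaction | discrepancy | hurdle-gamma | feedback x group | — |
| feedback-simple | discrepancy | hurdle-gamma | feedback | feedback slopes by dyad and participant |
| accuracy | accuracy | hurdle-gamma | group | — |
| question | answer (1-5) | cumulative probit | group | — |
| feedback-signal | feature | Student-t / gamma(log) | feedback | per-cell slopes |
| discrepancy-fb | feature | Student-t / gamma(log) | feedback x scaled discrepancy | per-cell slopes |
| adjustment-fb | feature | Student-t / gamma(log) | feedback x scaled adjustment | per-cell slopes |

Signal models additionally carry one independent zero-mean effect per fixed
term per time-window x electrode cell ("uncorrelated slopes"), so each cell
has its own intercept and its own deviation of every slope; the reported
per-cell contrast is the fixed effect plus that cell's deviations. All random
effects — including the feedback-by-group slopes written with a single "|" —
are implemented as independent (uncorrelated) effects without covariance
estimation: no covariance estimates are reported anywhere downstream, the
correlated parameterization is substantially harder to identify at test
scale, and the uncorrelated form is the stated convention for the cell
slopes. The adjustment model uses epochs at FB1 and FB2, pairing the epoch
of feedback *k* with the adjustment *k* to *k + 1* (the alternative pairing
is a configuration away in the data preparation).

Families: the discrepancy and accuracy responses are non-negative with a
point mass at zero, hence **hurdle-gamma** — probability `pi` of an exact
zero (logit link, intercept only: the data motivate no predictors for the
hurdle) and a gamma density with log-linked mean for positive values, so the
fixed effects act multiplicatively on the positive part. ERP amplitudes are
heavy-tailed single-trial means, hence **Student-t** with estimated degrees
of freedom `nu = 1 + exp(l)` under a Gamma(2, 0.1) prior on `nu - 1`;
power ratios are strictly positive, hence **gamma with log link**, whose
coefficients read as multiplicative power changes. Questionnaire items use a
**cumulative probit** with ordered thresholds and no separate intercept (the
thresholds absorb it — keeping both would leave an exactly flat direction).

Priors: normal(0, 1) on fixed effects; group-level SDs under Gamma(1, 10)
for the simple feedback model (a tight, weakly informative choice with prior
mean 0.1) and half-Student-t(3, 0, 2.5) — the standard weakly informative
hierarchical family — for the interaction models, whose exact hierarchical
hyperparameters are otherwise unstated; log-normal priors on the gamma shape
and the Student-t scale (the latter centered at the log response SD);
normal(0, 1.5) on the hurdle logit.

## Posterior computation

`sample_posterior()` runs an adaptive Metropolis-within-Gibbs sampler on the
joint posterior defined by `log_density()` (all parameters on the
unconstrained scale, chains initialized at zero there):

* a joint random walk on the fixed effects with covariance adapted from the
  warmup history (several sub-steps per iteration, since correlated
  interaction columns are the slowest directions);
* vectorized single-site updates for every random-effect block — all groups
  of a block propose and accept independently in one likelihood pass over
  the block's active rows;
* conditional (prior-only) updates for group SDs, plus a joint *scale move*
  `(r, sd) -> (c r, c sd)` per block that removes the funnel coupling
  between effects and their SD;
* *translation moves* along exactly flat directions: for every fixed column
  that is group-constant on a block (the intercept for dyad and participant
  intercepts, the group indicator for between-group confounding), the
  coefficient and the group effects shift in opposition, leaving the
  likelihood untouched;
* scalar random walks for family parameters, with the hurdle probability
  update using only the zero/positive counts.

Proposal scales adapt during warmup only (Robbins-Monro towards standard
acceptance targets) and are frozen afterwards, so the post-warmup chain is a
valid fixed-kernel Markov chain. Convergence is checked with split R-hat at
the 1.01 threshold (`check_convergence()`, never silently accepted), and the
sampler's correctness is tested against conjugate closed forms, prior-only
sampling, label-permutation invariance and prior-sensitivity smoke tests.
The settings object carries `target_accept` and `max_tree_depth` for
interface compatibility with tree-based gradient samplers; they are recorded
but do not tune this sampler. Default test-scale settings are 4 chains x
1,500 iterations (500 warmup); `paper_settings()` gives 4 x 10,000 with
1,000 warmup.

## Contrasts, HDI and ROPE

Contrasts follow the sign-permuted reporting convention in which a negative
value is a reduction at the later feedback or at maximum covariate: FB2-FB1
is the FB2 coefficient, FB3-FB2 the coefficient difference, the group
contrast is Individual minus Cooperative at a given feedback, and the
covariate contrast is the linear predictor at covariate 1 minus covariate 0
(main effect plus any interaction active at that feedback), plus the cell's
random slopes for per-cell reporting.

Inference uses the 95% highest density interval — the shortest contiguous
interval containing `ceiling(0.95 n)` sorted draws, exact for unimodal
empirical distributions, no density smoothing — and a region of practical
equivalence of +/-0.05 SDy (behavioral and ERP) or +/-0.01 SDy
(time-frequency, whose scale is an order of magnitude smaller). SDy is the
sample SD of the response data entering the relevant cell (per-model SDy
minimum/maximum are reported alongside); a global-SD variant is available.
HDI endpoints are rounded to two decimals (behavioral/ERP) or three
(time-frequency) *before* the comparison; the ROPE is never rounded. The
decision is three-way: credible effect (rounded HDI disjoint from the ROPE),
practical equivalence (inside), undecided (overlap) — only credible effects
would be reported as findings.

## Problem sizes and numerical choices

The recovery studies use sizes chosen once for this package: the behavioral
convergence study simulates 20 dyads x 100 trials; the group-effect study 10
dyads per group x 40 trials over 20 seeded replicates; the planted-ERP study
5 dyads x 50 trials (1,500 epochs) at a 256 Hz synthesis rate; the null
calibration 200 datasets of 4 dyads x 12 trials with frozen estimates (a
true null). Degenerate inputs are handled explicitly: a constant FB1
discrepancy distribution scales to zero, zero response variance yields a
degenerate [0, 0] ROPE with a warning, zero baseline power is an error, and
ties at the outlier percentile are kept (strict inequality).

## Known limitations

The sampler trades the efficiency of gradient-based methods for transparency
and zero compiled dependencies; at full 10,000-iteration scale it is slower
per effective draw than NUTS, and split R-hat on the hardest interaction
models at test scale sits slightly above 1.01 on occasional random-effect
parameters even when the reported contrasts are stable. Hurdle predictors
beyond an intercept, covariance-structured random slopes, leave-one-out
family comparison, and adapters for vendor EEG formats are out of scope; the
external-preprocessing hook (`preprocess_external()`) is the extension point
for real recordings.
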