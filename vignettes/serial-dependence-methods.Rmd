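---
title: "Serial-dependence analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-dependence analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialbias)
library(dplyr)
```

## The problem

In continuous-report working-memory experiments, observers reproduce the
orientation of a cued grating. Reports are not unbiased: they are pulled
toward the target of the *previous trial* (an attractive between-trial
bias, often called serial dependence) and pushed away from the *other
grating on the same trial* (a repulsive within-trial bias). A parallel
question is whether the neural representation of the current stimulus —
as read out by a multivariate classifier from multichannel recordings —
is shifted toward or away from those same inducer orientations, and
whether a lingering (possibly sign-reversed) trace of the previous
stimulus can be detected at all.

`serialbias` implements the full analysis chain for both questions and a
synthetic-data generator with *known, injectable* bias parameters, so
that every estimator in the chain has a parameter-recovery test surface.

## Orientation circularity

Orientations live on a 180°-periodic circle. All circular computation is
done on the doubled-angle circle (angles × 2, period 360°), and signed
differences are mapped to (−90°, 90°]. Exact antipodes (±90°) are mapped
to +90° — one tie-break, stated once, used everywhere
(`circular_error()`).

## The behavioral model

### Response generation (synthetic data)

`simulate_responses()` draws each report from a three-component mixture:
target-centered with probability $p_T$, nontarget-centered ("swap") with
$p_S$, uniform guess with $p_G$. Target- and swap-centered responses
receive von Mises noise with shared concentration $\kappa$ on the doubled
circle. On target trials a systematic bias is added:

$$\text{bias} = \mathrm{DoG}(\Delta_{\text{btw}}; a_{\text{att}}, w_{\text{att}})
              - \mathrm{DoG}(\Delta_{\text{win}}; a_{\text{rep}}, w_{\text{rep}}),$$

where $\Delta_{\text{btw}}$ is the signed distance from the previous
trial's target to the current target, $\Delta_{\text{win}}$ the distance
from the same-trial nontarget, and

$$\mathrm{DoG}(\Delta; a, w) = a \frac{\Delta}{w}
  \exp\!\left(\tfrac12 - \frac{\Delta^2}{2w^2}\right),$$

normalized so its peak value is exactly $a$ degrees at $\Delta = w$. The
amplitude is therefore directly the maximum bias in degrees, which makes
parameter recovery interpretable. The DoG is a modeling choice for the
generator, not a claim about the true functional form of biases in real
data; the analysis operators it feeds never assume it.

Defaults are the study conditions the package emulates: 400 trials in
blocks of 50; a balanced four-condition design (report-first /
report-second × one / two items); $\kappa = 8$ (mean absolute error
≈ 11.9°), $p_T = 0.92$, $p_G = 0.047$, $p_S = 0.033$; attractive bias
1.5° peaking at 25°, repulsive bias 1° peaking at 20°. Where the
emulated study does not fix a value, these were chosen once as
field-typical magnitudes and are not revisited.

### Bias curves and the summed bias

`bias_curve()` bins the signed distance between inducer and target into
64 equally sized, *overlapping* bins, each holding 25% of trials (the
nearest trials to each bin center, with circular wrap-around so every bin
averages the same number of trials). Bin centers are offset by half a
step so that none sits at 0° or ±90°, making mirror pairs fold exactly.
After sign-flipping the error in negative-center bins, mirrored pairs are
averaged into 32 folded bins on (0°, 90°), and the *summed bias* — the
sum of the folded means — is the single-number attraction (+) /
repulsion (−) index.

Two numerical consequences are worth stating explicitly:

* With uniformly distributed distances, a bin holding 25% of trials
  spans roughly ±22.5°. Each folded bin mean therefore estimates the
  *window-averaged* bias profile, not its raw value at the bin center.
  For a DoG with $a = 3°, w = 25°$ the difference peaks near 0.7–0.85°.
  The recovery tests use the analytic window-averaged DoG as the oracle.
* "25% of trials" is rounded to the nearest integer for odd counts, and
  ties in nearest-distance membership are broken by trial order, so
  binning is deterministic.

For between-trial analyses the first trial of each block (no previous
target) is dropped before binning. Binning is always on the *target*
orientation distance, never the response, to avoid confounding serial
bias with the oblique bias.

### Mixture fitting

`fit_mixture()` maximizes the three-component likelihood by EM on the
doubled circle. $\kappa$ is updated by inverting the Bessel ratio
$A(\kappa) = I_1(\kappa)/I_0(\kappa)$ with a root finder (no closed-form
approximation, preserving monotone likelihood ascent). Initialization is
method-of-moments for $\kappa$ and $(0.8, 0.1, 0.1)$ for the weights —
deterministic, no random restarts. Two guards:

* $\kappa$ is floored at 0.5: below that a von Mises is statistically
  indistinguishable from the uniform guess component and the mixture is
  unidentifiable. The floor restores identifiability (pure-guessing data
  then correctly drive $p_G \to 1$) and is inert for any concentrated
  data.
* $\kappa$ is capped at 1000 to keep the Bessel ratio numerically stable
  for noiseless data.

Trials without a nontarget drop the swap component with renormalized
priors. Non-convergence after `max_iter` returns the best fit with
`converged = FALSE` rather than an error.

## The neural model

### Synthetic epochs

`simulate_epochs()` builds trials × channels × time arrays: a fixed pair
of orthonormal channel patterns weighted by $\cos 2\theta, \sin 2\theta$
of the encoded orientation, a piecewise-linear rise/fall envelope
(default 100 → 350 → 750 ms, covering the standard 250–600 ms analysis
window), i.i.d. Gaussian sensor noise, and two injectable history
effects:

* `repulse_shift`: the encoded orientation is shifted *away* from an
  inducer by a fixed number of degrees whenever the absolute inducer
  distance falls inside `shift_range` (default 10–50°);
* `linger_amp`: a previous-target pattern added with signed amplitude —
  negative values emulate a sign-reversed lingering trace.

The generator emulates what the decoding chain needs (orientation-tuned
sensor patterns with known geometry) and deliberately nothing else: no
1/f noise, no evoked-response shape beyond the linear envelope, no
artifacts, no realistic forward model. Passing recovery tests therefore
demonstrates that the *estimators* are unbiased and correctly signed
under known ground truth — not that real recordings satisfy the
generator's assumptions. Sensor positions are laid out deterministically
on a hemisphere (Fibonacci lattice) so position-based neighborhoods are
well defined.

### Decoding

`build_features()` concatenates all channels over a trailing
`window_len`-sample window (the value at time $t$ summarizes
$(t - L + 1) \dots t$; window anchoring is a package choice — only full
windows are emitted). Magnetometer-type channels are scaled ×20 onto the
gradiometer range before concatenation; no baseline correction is
applied, so slow signals from preceding stimuli survive.

`decode_cv()` then, independently per time point and per stratified
cross-validation fold: fits PCA on the *training fold only* (fold purity
is a deliberate tightening — fitting the projection on all trials would
leak test information), keeps the smallest number of components reaching
90% of training variance, fits an LDA into the 9-dimensional
discriminant space (10 classes − 1), projects the held-out fold, and
computes Euclidean distances to the training class means. Class evidence
is the negated, class-mean-centered distance — monotone in any
reasonable likelihood mapping and linear, which keeps the cosine score
well behaved; a softmax likelihood mapping is available as an option.
The within-class covariance is shrunk toward its diagonal with an
automatic analytic intensity (Ledoit–Wolf-style); with a few hundred
trials and up to a few hundred components some regularization is
necessary, and the analytic level avoids a tuning parameter. Stratified
folds deal remainders round-robin in seeded random order, so fold
assignment is reproducible.

Orientation classes are right-open 18° bins over [0°, 180°).
`align_evidence()` re-indexes the class axis per trial so offset 0 is the
bin containing the alignment orientation (a pure permutation); with 10
classes the offsets are −72° … 72°, 90°. `cosine_evidence()` averages
evidence × cos(2·offset) into one signed score per trial and time point.

### Asymmetry and neural bias

Following the standard asymmetry-score procedure, per-trial asymmetry is
mean evidence in the clockwise offset bins (−72° to −18°) minus the
counterclockwise bins (18° to 72°); the 0° and 90° offsets belong to
neither set (taken literally from the conventional bin lists). Trials
are selected by inducer distance — within-trial 10° < |Δ| < 50°, both
ends open; between-trial 0 < |Δ| ≤ 60° — and split by inducer side.
The CW/CCW labels are fixed *jointly* with the bin sets: an inducer is
CW when its signed offset from the presented orientation is negative,
the same side as the CW evidence bins. The neural bias score is the
CW-group asymmetry minus the CCW-group asymmetry; the package verifies
by injected-shift simulation (rather than by assumption) that an
attractive shift yields a positive score and a repulsive shift a
negative one. Scalar summaries average 250–600 ms post-onset by default,
where the generator's envelope (and, in the emulated study design,
decodable orientation information) is sustained.

`cross_decode_evidence()` aligns the same evidence tensor to the
*previous* trial's target: negative window means indicate a
sign-reversed lingering trace, and across simulated subjects with
varying trace strength the cross-decoding score co-varies with the
neural bias score — the mechanism-level correlation the analysis is
designed to expose.

## Inference

`signflip_null()` implements the trialwise sign-flip shuffle null: each
iteration flips the sign of every trial's inducer distance
independently, recomputes the statistic per subject, and averages across
subjects. The null is z-scored; the headline p-value is the two-tailed
normal tail of the observed z (as is conventional for this procedure),
with the empirical $(b+1)/(m+1)$ tail count also reported — the latter
can never be exactly zero.

`cluster_permutation_1d()` is the standard one-sample cluster-based
permutation test: pointwise t against zero, cluster-forming threshold at
two-tailed $p < 0.05$ by default (the threshold is exposed, since
conventions differ), cluster mass = summed t, null = maximum |mass|
under per-subject sign flips. Sign flips are per-trial for the shuffle
null but per-subject for the cluster test, matching how each statistic
is formed. Zero-variance points are excluded with a warning rather than
producing infinite t values.

Default iteration counts are 10,000; the calibration experiments in the
test suite use 400–500 iterations per run (p-value resolution ≈ 0.002,
ample for checking a 0.05 level) so that 500-experiment type-I-rate
checks complete quickly.

## Problem sizes used in tests

All tests and the acceptance script generate their data at run time at
desk scale, chosen as the package's own test conditions: behavioral
recovery at 4,000 trials; decoding sanity at 400 trials × 32 channels;
neural-bias and cross-decoding simulations at 250 trials × 16 channels,
50 Hz sampling, 0.9 s epochs, 4-sample feature windows, 5-fold CV;
20-simulation means for shift ordering; 100 runs for null coverage; 500
experiments for type-I calibration. The 306-channel × 30-sample feature
geometry is exercised structurally (dimensions), not simulated end to
end.

## Known limitations

* The generator's noise is white in time and space; estimator variances
  on real recordings (autocorrelated, spatially structured noise) will
  differ, though the null-calibration properties of the permutation
  tests do not depend on the noise model.
* The mixture model shares one $\kappa$ across target and swap
  components and fits one set of weights per call; fit per condition,
  as is standard.
* `read_epochs()`/`write_epochs()` use a plain-text container intended
  for desk-scale data; importing epochs from acquisition formats should
  go through `as_ori_epochs()` on an exported array.
* The searchlight reports time-averaged cosine evidence per channel; it
  does not attempt source reconstruction or anatomical claims.

## A minimal end-to-end run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  seed = 1, n_trials = 200, condition_mix = c(0.5, 0, 0.5, 0),
  neural = neural_params(n_channels = 16, sfreq = 50, t_start = -0.1,
                         t_end = 0.7, signal_onset = 0.05,
                         signal_peak = 0.3, signal_offset = 0.65,
                         snr = 2, repulse_shift = 10, seed = 1),
  window_len = 4, n_folds = 5, n_iter = 2000
)
res <- run_pipeline(cfg, dir = "run01")
res$null          # sign-flip inference on the neural bias score
autoplot(res$curve)
autoplot(res$asym)
```
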