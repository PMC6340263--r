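---
title: "Decoding saccade timing and direction from peri-saccadic V1 LFPs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding saccade timing and direction from peri-saccadic V1 LFPs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisacc)
```

## The scientific question

Primary visual cortex receives signals about eye movements that are not
driven by the retinal image. When local field potentials (LFPs) are
aligned on the end of a saccade (the onset of the new fixation, `t = 0`),
they show a stereotyped deflection — a small dip near fixation onset, a
peak around 30–40 ms, and a second dip around 60–70 ms — whose detailed
shape depends on the direction of the saccade. This package quantifies
the information in that signal with three linked analyses:

1. **Saccade vs. fixation classification.** Can a 100 ms epoch of LFP be
   classified as containing a saccade rather than steady fixation?
2. **Fixation-onset timing.** How precisely does the LFP time the start
   of the new fixation?
3. **Direction decoding.** Can the LFP tell which way the eyes moved?

All three run on trial sets with synchronized eye traces, per-trial
saccade events, and multi-channel LFPs at 1 kHz. Because the macaque
recordings this emulates are not publicly deposited, the package ships a
synthetic-session generator with the statistical structure the analyses
assume, plus a signal-free null mode; every analysis is validated against
that generator's ground truth.

## The classification machinery

Epochs are described by a window center $\tau$ (ms, relative to fixation
onset) and an even length $L$ (default 100): the window covers samples
$\tau - L/2, \dots, \tau + L/2 - 1$, so $\tau = 0$ is the peri-saccadic
interval $[-50, 49]$, $\tau = -250$ the pre-saccadic fixation
$[-300, -201]$, and $\tau = 250$ the post-saccadic fixation $[200, 299]$.
Each channel is normalized by the mean and population SD of its LFP
pooled over *all* trials — deliberately including test trials, matching
the emulated protocol; this mild leakage is documented here and a
train-only variant can be had by fitting `fit_norm_stats()` on a subset.

A linear soft-margin SVM (`train_linear_svm()`, solved by libsvm via
e1071) separates positive (saccade) from negative (fixation) epochs using
the $L$ raw 1 ms samples as unweighted features. Performance is assessed
criterion-free: each trial's **s-value** is its signed distance
$s = (w \cdot x + b)/\lVert w \rVert$ to the hyperplane of a classifier
trained with that trial wholly held out (leave-one-out; a trial's saccade
*and* fixation epochs leave together). Sweeping a threshold across the
two s-value distributions traces the ROC; the AUC equals the probability
that a random saccade epoch outscores a random fixation epoch, ties
counting one half. Percent correct is reported both at the hyperplane
(threshold 0) and at the accuracy-maximizing threshold under equal error
costs. Two controls separate shape from amplitude information: scoring
epochs by their mean alone (`amplitude_auc()`), and classifying epochs
after removing each epoch's mean (`shape_only()`).

Channels are pooled by summing each trial's s-values across channels and
building one ROC from the pooled scores; a concatenated-histogram variant
sits behind `pool_channels(method = "concat")`. Summation is the default
because it is the only reading that yields one score per trial for a
trial-level ROC. The "optimal combination" ranks channels by
single-channel AUC and takes the prefix with the highest pooled AUC.

## Timing by a train/test window sweep

A family of classifiers is trained at centers $\tau_{train}$ on the grid
$\{-50, \dots, 49\}$ (for 100 ms windows), always against the
post-saccadic fixation window. Each held-out trial is then scanned with
test windows and votes for the $\tau_{test}$ with the largest s-value.
The test range obeys two rules: it is symmetric about $\tau_{train}$ and
spans the whole training grid for every $\tau_{train}$ — i.e. centers
$\{\tau_{train} - 100, \dots, \tau_{train} + 99\}$, 200 windows. The
symmetry is what makes the vote unbiased under pure noise: a trained
pattern can be "found" equally far on either side, so the expected vote
equals $\tau_{train}$ (verified by simulation in the test suite). The RMS
of votes around $\tau_{train}$ summarizes timing precision.

Two numerical details are pinned down here because the procedure leaves
them open. Argmax ties are broken toward the center nearest
$\tau_{train}$, then toward the earlier center — the choice that adds no
directional bias in expectation. And under pure noise the votes are
*approximately* uniform over the test range (analytic RMS
`uniform_vote_rms(100)` = 57.74 ms): because s-curves from overlapping
windows are correlated, the empirical argmax shows a mild excess at the
range edges, so null-calibration checks compare the observed RMS to the
uniform null within Monte-Carlo error rather than asserting exact
uniformity. Trials whose test range would leave the recorded span are
skipped, not clipped — clipping would reintroduce the edge bias the
symmetric range removes.

For shorter windows ($L$ = 50, 20, 10 ms) the training grid generalizes
to all centers whose windows lie inside the analyzed $[-100, 99]$ ms
span: `seq(-100 + L/2, 99 - L/2)`. This reproduces both stated anchor
cases: the 100 ms grid $\{-50..49\}$ and a leftmost 10 ms window centered
at $-95$ ms starting at $-100$ ms.

## Direction decoding

Direction analyses use the $\tau = 25$ window ($[-25, 74]$ ms), where
saccade/fixation classification is reliably high. One-vs-rest
classifiers give a per-direction AUC per channel. The 12-way decoder
builds all 66 pairwise classifiers per cross-validation fold (30-fold,
stratified by direction — leave-one-out would multiply the 66 fits by the
trial count) and predicts by pairwise-vote majority; ties go to the
larger sum of winning-margin s-values. Per-direction estimates average
the predicted angles with the **circular mean** (vector sum), since
arithmetic averaging is ill-defined across the 0°/360° wrap; a direction
whose votes cancel exactly raises an undefined-mean error rather than
returning an arbitrary angle. Angular errors are wrapped to
$(-180°, 180°]$ and summarized by mean absolute, RMS, SD, min and max:
"average error" is mean *absolute* error, because signed errors would
average toward zero and could not match a reported minimum well above it.

Whether LFP *shape* genuinely varies with direction is tested by
permutation: the within-direction statistic is the mean Pearson
correlation over all trial pairs; for a pair of directions the observed
value is the average of the two within-direction statistics, and the null
reassigns the pooled trials to two groups of the *original* sizes (the
exchangeable null that matches the observed statistic), 10,000 times by
default. The p-value is upper-tail with add-one smoothing,
$p = (1 + \#\{null \ge obs\})/(n_{perm} + 1)$, and Bonferroni correction
runs over the 66 pairs within one channel, which keeps per-channel
significance flags well-defined. Pairwise correlations of fixed trials
do not change under reassignment, so the pooled correlation matrix is
computed once and permutations merely re-average its entries — this is
what makes 10,000 permutations per pair cheap. Mean-waveform uncertainty
is shown with a percentile bootstrap over trials (default 2000
replicates) plus per-sample SD bands.

## The synthetic session generator

`synth_config()` encodes the emulated task: 12 directions in 30°
increments, outside-in 7° saccades landing at the display center, 42
trials per direction, multi-channel LFPs at 1 kHz on a trial span of
$[-400, 400]$ ms around fixation onset.

**Eye traces.** The speed pulse is a raised cosine — analytic, unimodal,
integrable in closed form — so displacement is exactly the configured
amplitude. This family ties amplitude $A$, duration $D$ and peak speed
together (peak $= 2A/D$), and the three reported values (7°, ~30 ms,
300–350 deg/s) are mutually inconsistent for it: amplitude and duration
are taken as primary (both are stated experimental facts), giving a peak
of 467 deg/s; setting `saccade_duration = NA` instead derives
$D = 2A/\mathrm{peak} \approx 43$ ms from the configured peak. Fixational
noise is white position noise (SD 0.01°, an eye-tracker-scale value).
Eye traces are generated at 1 kHz aligned to the LFP samples; the
analyses operate at 1 ms resolution, so nothing downstream needs a faster
eye clock.

**Templates.** Each channel's saccade-locked deflection is a sum of
three Gaussian lobes (dip at ~8 ms, peak at 35 ms, dip at 65 ms),
amplitude-modulated by a von Mises function of the angle between saccade
direction and a lobe-specific preferred direction (lobe offsets 0°, 120°,
240° around the channel's preferred direction), with a small
direction-dependent latency shift and a smooth taper to zero outside the
$[-40, 120]$ ms support. This is the minimal family that reproduces the
dip/peak/dip morphology, smooth similarity between neighboring directions
with large variation across the full circle, and channel-to-channel
diversity. An amplitude floor keeps anti-preferred directions from
vanishing; with the default floor some channels still carry little
information about directions opposite their preference — which is
realistic, and why direction tests that demand high AUC in *every*
direction on a *single* channel use a strongly tuned configuration
(`tuning_kappa = 1.5`, `tuning_floor = 0`, `latency_mod = 8`).

**Noise and SNR.** Background noise is spectrally shaped Gaussian
$1/f^\alpha$ noise ($\alpha = 1$ by default; the realized spectral slope
is verified by fit in the tests), unit RMS per channel. Templates are
scaled so the direction-averaged RMS over the support equals `snr` times
the noise RMS, with per-channel log-normal gain spread (SD 0.25 in log
space) emulating electrode variability. Single-trial SNR in the emulated
recordings was never quantified, so the default `snr = 5` is chosen to
put the pipeline in its high-recovery regime rather than to match
macaque data; control analyses use `snr = 1.5` and the null mode uses
`snr = 0` (no template inserted at all). True fixation onsets are
jittered trial-to-trial by a truncated Gaussian (SD 3 ms, capped at
±10 ms, rounded to the 1 ms grid).

**What the generator does not emulate.** Real LFPs contain microsaccades,
blinks, corrective saccades, line noise, non-stationary gain, and
cross-channel correlated noise; none are modeled (trials with corrective
saccades were discarded in the emulated protocol, so the generator simply
never produces them). Passing recovery tests on this generator therefore
demonstrates that the *pipeline* is correct and calibrated — not that
macaque V1 LFPs carry the reported information; that evidence lives in
the original recordings.

## Saccade detection

Eye speed is the norm of per-component central differences (one-sided at
the ends), smoothed by a 5-sample moving average. The threshold is the
fixation-baseline mean speed plus 3 SDs; saccade onset and end are the
threshold crossings of the suprathreshold run containing the speed
maximum (identical to the plain first-crossing rule on a clean unimodal
pulse, but immune to isolated noise crossings). The smoothing width and
baseline interval are module defaults, not facts about the emulated
experiment, which cited only the velocity-based criterion. At default
noise levels, detection recovers true saccade ends with RMS error well
under 1 ms; the acceptance suite requires 2 ms.

## Numerical and protocol choices

- **Soft-margin cost.** The emulated analysis reported only its solver,
  not its regularization; the default is `cost = 1` on normalized
  features, exposed everywhere. Oracle tests use large cost to force
  hard margins with closed-form solutions.
- **Degenerate classes.** Identical positive and negative sets yield a
  zero-weight optimum; s-values are defined as 0 (every point on the
  hyperplane) so downstream AUC is exactly 0.5.
- **Population SD** (divide by $n$) for channel normalization; sample SD
  for the velocity baseline. Both used consistently and tested.
- **Leave-one-out fold integrity.** Scoring pools LOO s-values across
  folds; with unpaired classes this is known to be slightly pessimistic
  at small $n$, but with the paired design used here (a trial's saccade
  and fixation epochs leave together) the null AUC is centered on 0.5 —
  the null-calibration test runs 100 signal-free replicate channels of
  16 trials and checks the mean AUC within three standard errors.
- **Problem sizes.** The bundled analyses and acceptance script run one
  session of 12 × 42 × 8 (directions × trials × channels) — the trial
  count of the smaller emulated data sets, with a channel count between
  the 16- and 96-electrode arrays — plus 100 single-channel null
  replicates; the test suite uses smaller sessions per check. These sizes
  make every quantity reproducible on a laptop in minutes while keeping
  all estimates comfortably inside their tolerance bands.
- **Container format.** Sessions persist as a versioned single-file RDS
  bundle with logical groups (lfp/eye/events/meta) and an events CSV
  sidecar; R has no HDF5 binding in this package's dependency set, and a
  native serialization keeps the round trip bit-exact. Time is stored as
  integer milliseconds relative to fixation onset.

## Known limitations

- The generator's direction tuning is smooth and unimodal per lobe; real
  channels show multimodal and more idiosyncratic tuning.
- The SVM hyperplanes are not claimed to replicate any particular
  solver's output beyond the QP optimum; solver tolerance differences
  appear in the third decimal of s-values.
- The 100-feature/1 ms-sample design fixes the feature clock at 1 kHz;
  other LFP sampling rates require re-deriving the window grids.
- Normalization leaks train/test by design fidelity (see above); for
  deployment-style estimates, fit normalization on training trials only.
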