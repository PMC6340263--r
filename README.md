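# perisacc

Saccadic eye movements sweep the retina three times a second, yet
perception stays stable — in part because visual cortex is told what the
eyes are doing. `perisacc` quantifies that extraretinal signal: it asks
how much information about the *occurrence*, *timing*, and *direction*
of saccades is carried by peri-saccadic local field potentials (LFPs) in
primary visual cortex, using trial sets of multi-channel 1 kHz LFPs
aligned on fixation onset (t = 0 = saccade end). Because the macaque
recordings this analysis was designed around are not publicly deposited,
the package includes a synthetic session generator with the statistical
structure the analyses assume — direction-tuned saccade-locked LFP
templates in 1/f background noise, realistic outside-in 7° saccade eye
traces — and a signal-free null mode, so every result is validated
against known ground truth.

The machinery, in the field's standard terms:

- **Epochs** are windows of length *L* (default 100 ms) centered at τ on
  the fixation-aligned axis; τ = 0 covers −50..+49 ms, τ = ±250 are the
  fixation controls.
- **Classification** uses a linear soft-margin SVM on the *L* raw 1 ms
  samples. Performance is criterion-free: each trial's **s-value** is its
  signed distance s = (w·x + b)/‖w‖ to a hyperplane trained with that
  trial held out (leave-one-out); sweeping a threshold over the s-value
  distributions gives the ROC, and AUC = P(s_saccade > s_fixation), ties
  ½. Controls: percent correct (hyperplane vs. optimal criterion), a
  mean-amplitude baseline, and shape-only (epoch-mean-removed)
  classification.
- **Timing**: classifiers trained at τ_train ∈ {−50..49} vote, per
  held-out trial, for the τ_test ∈ {τ_train−100..τ_train+99} with the
  largest s-value; the symmetric test range makes votes unbiased under
  noise, and the RMS of votes around τ_train measures how precisely the
  LFP times fixation onset.
- **Direction**: one-vs-rest AUCs per channel, a 12-way decoder from all
  66 pairwise SVMs (30-fold CV, pairwise-vote majority), circular-mean
  direction estimates with wrapped angular error statistics, a
  permutation test on within-direction LFP waveform correlations
  (Bonferroni over the 66 direction pairs), and channel pooling by
  summed s-values with sequential-addition optimization.

## Worked example

```r
library(perisacc)

cfg <- synth_config(trials_per_direction = 8, n_channels = 3, seed = 7)
gen <- gen_trialset(cfg)
trials <- normalize_trialset(gen$trials)

# detect saccades from eye speed (3-SD velocity criterion)
events <- detect_events(trials)
sqrt(mean((events$end_ms - gen$truth$events$end_ms)^2))
#> [1] 0.3535534

# saccade vs fixation, one channel, one direction, leave-one-out
ids <- events$trial_id[events$direction_deg == 0]
pos <- epoch_matrix(trials, 1, window_spec(25), events, ids)   # -25..74 ms
neg <- epoch_matrix(trials, 1, window_spec(250), events, ids)  # 200..299 ms
sv <- loo_svalues(pos, neg)
roc_auc(sv$s[sv$true_class == "pos"], sv$s[sv$true_class == "neg"])
#> <roc_curve> AUC = 1 (8 pos, 8 neg)

# where in time does the trained pattern best match each trial?
sw <- tau_sweep(trials, 1, direction = 0, tau_train = 25, events = events)
attr(sw, "summary")
#>    tau_train mean_vote   sd_vote rms
#> 25        25     25.75 0.7071068   1
```

The AUC of 1 says saccade and fixation epochs are perfectly separable on
this high-SNR synthetic channel; the sweep summary says the best-matching
test window sits within a millisecond of the 25 ms training center — the
LFP times fixation onset to ~1 ms here. On signal-free data (`snr = 0`)
the same pipeline returns AUCs centered on 0.5 and timing votes spread
over the whole test range.

The full session-scale analyses live in `analysis/01_simulate.R` through
`analysis/04_direction_decoding.R`; each is a thin driver over the
package functions that prints what it found and writes tidy CSVs under
`results/`.

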