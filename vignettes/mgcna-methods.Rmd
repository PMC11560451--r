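---
title: "Seizure detection with multi-branch graph convolution and separable attention: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure detection with multi-branch graph convolution and separable attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what is modeled,
which knobs matter, what the synthetic data does and does not emulate, and
where the design was genuinely open and a choice had to be made.

## The problem and the model

Scalp EEG during an epileptic seizure shows two coupled phenomena: a rhythmic
oscillation (roughly 3–12 Hz in pediatric recordings) and a rise in
synchrony between brain regions. A detector that sees each channel in
isolation can exploit the first but not the second. `mgcna` therefore models
a 3-second, 22-channel segment as signals on a graph whose nodes are the
bipolar derivations of the longitudinal montage, and classifies graph
features rather than raw traces.

Three adjacency structures are used side by side, because none alone is
adequate:

* **Spatial distance.** Abnormal discharges spread to neighboring cortex, so
  physically close derivations are correlated. Midpoints of the two 10–20
  electrodes of each derivation give 2-D coordinates; pairwise Euclidean
  distances are normalized by their maximum (so the sparsity threshold lives
  on `[0, 1]`), and edge weights follow a Gaussian kernel
  `exp(-d^2 / (2 delta^2))` with `delta` the standard deviation of the
  pairwise distances. Pairs farther than `R1` are cut. This graph is fixed
  per montage.
* **Functional connectivity.** Pearson correlation between the channels'
  extracted feature vectors, mapped affinely from `[-1, 1]` to `[0, 1]` and
  thresholded at `R2`. It changes segment by segment and is the view designed
  to pick up ictal synchrony.
* **Adaptive.** A trainable matrix, standardized, affinely mapped and
  rectified before use. Neither anatomy nor correlation fully determines the
  functional coupling relevant for classification; this branch lets the
  optimizer discover the remainder. It is a registered parameter receiving
  gradients like any weight.

Each view drives its own two-layer GCN with the symmetric-normalized
propagation rule; self-loops are added exactly once, inside the normalizer
(`A + I`), never in the adjacency builders, whose diagonals stay zero. The
three branch outputs are fused by separable multi-head attention — a single
softmax-normalized context vector per head instead of a pairwise score
matrix, so cost grows linearly with the `22 x 64` positions — and a small
convolutional head produces two sigmoid units.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `window_s`, `fs` | 3 s, 256 Hz | segment length and sampling rate; 768 samples |
| band-pass | 0.5–70 Hz, order 5 | noise reduction; applied zero-phase (below) |
| `k_depthwise` | 2 | two halvings, features of length 192 per channel |
| `R1` | 0.4 | distance-graph sparsity on the normalized scale |
| `R2` | 0.25 | connectivity threshold on `(rho+1)/2` |
| `gcn_layers`, `gcn_dim` | 2, 64 | shallow GCN; deeper stacks oversmooth |
| `n_heads`, `head_dim` | 3, 1 | heads over a 3-branch axis (see open points) |
| `dropout` | 0.5 | before the output linear layer, training only |
| `classifier_channels` | 16, 32 | head widths |
| `lr`, `weight_decay` | 3e-4, 1e-3 | Adam with decoupled weight decay |
| `batch_size`, `epochs` | 64, 100 (patience 10) | unspecified upstream; set here |
| rebalancing | 5:1, then per-epoch balance | class imbalance control |

## What the synthetic generator emulates — and what it does not

`generate_recording()` produces interictal background as per-channel
1/f-power ("pink-ish") noise mixed with a shared component, so the expected
pairwise correlation equals `background_corr` and the band-pass has visible
effect (white noise would make the filter nearly invisible in-band). Inside
annotated seizure intervals the mixing weight rises to `ictal_sync` and a
common sinusoid at `ictal_freq_hz` is added — random phase per seizure, ±10%
slow frequency modulation so the class boundary is not a single frequency
bin, quarter-second onset/offset ramps, and per-channel gain highest on the
focal channels. The amplitude scales with `ictal_gain - 1`, so
`ictal_gain = 1` with `ictal_sync = background_corr` is an exact null: ictal
and interictal stretches become statistically indistinguishable, which the
tests use as a negative control. `generate_cohort()` perturbs frequency,
gain and focus per patient to give leave-one-subject-out splits something
real to generalize over.

Deliberately absent: eye-blink/EMG artifacts, electrode pops, sleep-stage
nonstationarity, spike-wave morphology, and any calibrated microvolt scale.
Passing tests on this data demonstrates that the implementation learns and
generalizes when the class signal is the designed synchrony/rhythm contrast;
it says nothing about clinical performance on real recordings, where class
overlap, artifacts and inter-patient variability dominate.

Default study conditions (used by the heavier tests and the acceptance
script): one patient, 20 minutes, six 40-second seizures, `ictal_gain = 3`,
`ictal_sync = 0.8`, background correlation 0.15, focal channels 1–6 (left
temporal/parasagittal chains). Problem sizes in the test suite — 5-fold
training for 12 epochs at batch 32 across three seeds, and an 8-epoch
ablation grid — were chosen as the smallest runs that converge reliably on
these conditions.

## Numerical and design choices

* **Filtering.** The named fifth-order Butterworth band-pass is applied
  forward-backward (zero phase, magnitude squared) — standard EEG practice,
  since phase distortion would shift seizure onsets. The filter is realized
  as analytically derived second-order sections (prototype poles, band
  transform, bilinear map, per-section gain at the band center) rather than a
  direct-form order-10 polynomial: with a 0.5 Hz edge at 256 Hz the
  direct form is ill-conditioned enough to break linearity at the 1e-7
  level, while the cascade holds it to ~1e-14.
* **Window labeling.** A window is ictal only when wholly inside a seizure
  interval (half-open `[onset, offset)`); windows straddling a boundary are
  discarded to avoid label noise. Overlap (50%) applies only to ictal
  windows — its purpose is to multiply the scarce class — interictal windows
  do not overlap.
* **Validation sets.** The protocols define test folds; early stopping needs
  a validation set. Patient-specific mode uses the cyclically next fold as
  validation (keeping the five test folds an exact partition);
  leave-one-subject-out holds out one seeded training patient.
* **5:1 discard** happens before fold construction (a `ratio` argument can
  disable it), so all folds draw from the same rebalanced pool.
* **Distance kernel.** `2 delta^2` in the Gaussian denominator (heat-kernel
  convention); a flag drops the factor 2. Distances are normalized to
  `[0, 1]` before thresholding so the documented `R1` grid 0.2–0.7 is
  meaningful. The montage intentionally contains the coincident pair
  `T7-P7`/`P7-T7`, whose distance 0 yields weight 1.
* **Pearson normalization** is `(rho + 1) / 2`; `|rho|` is available behind a
  flag. The connectivity graph is recomputed per segment (matching the
  per-sample correlation description; a per-fold average would be cheaper
  but stationary).
* **Adaptive constraint.** The raw matrix is standardized over all entries
  with the population standard deviation plus `1e-5`, then a learnable
  scalar affine (identity at initialization), then ReLU. Initialization is
  i.i.d. uniform `(0, 1/n)`, unsymmetric — no symmetry is imposed.
* **Gradients.** All backward passes are analytic. The gradient of the loss
  with respect to the raw adaptive matrix flows through the full
  `D^-1/2 (A+I) D^-1/2` normalizer, including the degree terms; central
  finite differences confirm agreement to ~1e-8 relative. The per-segment
  Pearson adjacency, by contrast, is treated as a constant during
  backpropagation (no gradient through the correlation coefficient): only
  the adaptive matrix is described as trainable, and differentiating through
  per-segment correlation would couple every weight to the graph topology
  for marginal benefit.
* **Attention semantics.** The softmax runs over the flattened `n * P`
  positions per head; the fused update is
  `ReLU(V) ⊙ Σ_positions softmax(Q) ⊙ K`, then head concatenation, 3×3
  convolution + BN + ReLU, residual addition and BN. With the convolution
  weights zeroed the module reduces exactly to BN of its input — a property
  the tests pin down.
* **Loss.** Binary cross-entropy on the ictal sigmoid unit (clamped at
  1e-7), with the l2 penalty realized as decoupled weight decay
  (`weight_decay = 1e-3`) to avoid double regularization; an explicit
  `tau * ||Omega||_2` mode exists for exactness. A `two_unit` mode sums the
  cross-entropy of both units; it is not the default. Ties in the final
  argmax break to interictal — the safe default for a screening tool is to
  not raise an alarm on no evidence.
* **Batch norm** uses batch statistics in training and running statistics
  (momentum 0.1, eps 1e-5) in evaluation, everywhere including the adaptive
  constraint.
* **Determinism.** One master seed fans out to named substreams (simulation,
  rebalancing, folds, per-fold initialization, per-epoch resampling and
  dropout), so identical seeds reproduce histories exactly on a
  single-threaded CPU BLAS.

## Open points resolved

* The attention head bookkeeping upstream ties `d = m/h` on a branch axis of
  size 3, which is dimensionally inconsistent for general `h`; here `h` and
  `d` are independent configuration fields with defaults `h = 3`, `d = 1`.
* GCN depth and width are never specified upstream; `m = 2`, `P = 64` follow
  common shallow-GCN practice and are configurable.
* Classifier channel counts (16, 32) and batch size (64) are likewise
  package choices, recorded in `model_config()`/`train_config()` defaults.

## Known limitations

* Training only on the positive-class unit leaves the second output unit at
  its initialization; early in training the decision threshold is therefore
  effectively `p1 > ~0.5` until the ictal unit saturates. AUC is unaffected
  (it uses `p1` only); the `two_unit` loss mode removes the asymmetry.
* The EDF layer writes classic EDF (16-bit, one-second records, common
  sampling rate) with seizure intervals in a plain-text sidecar, not EDF+
  annotation channels.
* Evaluation is segment-level only — no event-level onset latency or false
  alarms per hour.
* No artifact rejection, montage conversion or resampling: recordings are
  expected in the canonical 22-channel bipolar montage at a single rate.
* CPU-only by design; the compute core is dense BLAS plus compiled per-tap
  convolutions, adequate for the scales tested here but not for
  corpus-scale training.
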