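---
title: "amypet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{amypet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cortical aggregation of amyloid-beta plaques is among the earliest
measurable events in Alzheimer's disease (AD), visible on amyloid-PET years
before clinical symptoms. `amypet` implements a deliberately classical
two-stage pipeline for binary classification of 2D amyloid-PET brain
slices: a compact image-preparation phase that reduces each slice to a
short, normalized feature vector, followed by a from-scratch, three-layer
back-propagation neural network (BPNN) evaluated with a single stratified
hold-out split. The supported diagnostic classes are normal control (NC),
significant memory concern (SMC), early and late mild cognitive impairment
(EMCI, LMCI) and AD; classification is always binary, NC versus one disease
group.

Clinical amyloid-PET datasets are access-controlled, so the package also
ships a synthetic phantom generator that reproduces the one statistical
feature the pipeline actually consumes — elevated cortical-rim uptake that
grows with disease stage — allowing the entire pipeline, including its
acceptance tests, to run self-contained.

## Image preparation

Three deterministic steps map a grayscale slice to the network input:

1. **Autocrop.** The minimal bounding box of all pixels with intensity
   above `crop_threshold * max(img)` is kept. The default threshold 0
   removes exactly the all-black frame; a small positive fraction tolerates
   low-level export noise in the frame. Cropping is idempotent and never
   modifies interior pixels.
2. **Bilinear resize** to a square `target_size` grid (default 200). We use
   the corner-aligned sampling convention — output pixel $(i,j)$ (0-based)
   samples the source at $\big(i\frac{H-1}{T-1},\, j\frac{W-1}{T-1}\big)$ —
   implemented separably; tests compare it against an independently coded
   per-pixel bilinear formula. Outputs are convex combinations of inputs,
   so the intensity range can only shrink.
3. **APPN (Average Pixel Per Node).** The grid is partitioned into
   non-overlapping `segment_size × segment_size` blocks (default 10); each
   feature is the arithmetic mean gray value of one block divided by a
   normalization ceiling. With the defaults this yields
   $(200/10)^2 = 400$ features in $[0,1]$.

Two conventions are under-determined by the method description and fixed
here explicitly:

* **Feature order** is row-major (top-left block first, then across each
  block row). Any fixed order is equivalent at network initialization, but
  the order must be deterministic for reproducibility, so it is documented
  and probed by a test.
* **Normalization ceiling.** Features are divided by the image's *nominal*
  intensity maximum when the format declares one (255 for 8-bit rasters),
  and otherwise by the *dataset-wide* maximum over such images
  (`prepare_manifest()`). Per-image max-normalization would silently equate
  every image's brightest structure and erase the between-image uptake
  differences that carry the diagnostic signal.

## The network

A fully connected 400–45–2 network with bias weights, logistic-sigmoid
activations, and online (per-pattern) gradient descent with momentum:

$$\delta_k = (t_k - o_k)\,\sigma'(z_k), \qquad
  \Delta w(t) = \eta\, \delta\, a + \alpha\, \Delta w(t-1),$$

with learning rate $\eta = 0.00079$ and momentum $\alpha = 0.90$ by
default. Targets are one-hot $\{1,0\}$ over the two output neurons and the
decision rule is argmax (ties to the lower index). Training stops when the
epoch-end RMS error

$$\mathrm{RMS} = \sqrt{\tfrac{1}{PK}\sum_{p=1}^{P}\sum_{k=1}^{K}
  (t_{pk} - o_{pk})^2}$$

computed with frozen weights reaches `min_rms` (default 0.003), or at
`max_epochs` (default 50,000), a safety valve against settings that
converge late or never.

Choices made where the classical recipe leaves freedom:

* **Update mode** is online with a seeded per-epoch shuffle. Classic-era C
  implementations of BPNN are online, and per-step momentum buffers match
  that reading.
* **Weight initialization** is uniform on $[-0.5, 0.5]$. With 400 inputs in
  $[0,1]$ this keeps initial hidden pre-activations in the responsive part
  of the sigmoid.
* **ReLU** is available for the hidden layer only; the output layer is
  always sigmoid because ReLU is unbounded above and cannot represent the
  $(0,1)$ targets.
* **Epoch counts are not comparable across RMS definitions.** The stopping
  statistic above is one of several in circulation (others divide by $P$
  only, or use half squared error). Under this definition and the default
  parameters, converging to 0.003 on separable 60-pattern phantom data
  takes on the order of $10^5$ epochs (the tail decays roughly like
  $\mathrm{epoch}^{-1/2}$ as the sigmoids saturate), a few minutes in the
  compiled training loop. Epoch counts are therefore logged, never
  asserted.

The inner training loop is compiled (RcppArmadillo) and works on transposed
weight copies with no per-step allocation; a readable single-step reference
implementation is exported as `backprop_step()`, and the suite asserts the
fast loop equals sequential reference steps bit-for-bit. Gradient
correctness is checked against a central-difference oracle at relative
tolerance $10^{-6}$ on 50 random small networks.

## Evaluation protocol

`make_split()` draws, per class, `round(0.30 · n)` images into the training
set (seeded, stratified); the remaining 70% are never seen during training.
Each binary experiment trains an independent network from a fresh seed.
From the held-out predictions, with the disease group as positive class:

$$\text{sensitivity} = 100\,\tfrac{TP}{TP+FN},\quad
  \text{specificity} = 100\,\tfrac{TN}{TN+FP},\quad
  \text{accuracy} = 100\,\tfrac{TP+TN}{TP+TN+FP+FN},$$

rounded half away from zero to one decimal, matching the convention of the
published results tables this pipeline reproduces. When a published
confusion matrix is fed through `compute_metrics()`, the returned values
must agree with the published metrics exactly; the one internal
inconsistency in the source tables (an NC/AD sensitivity printed as 92.4
while its own counts give 64/70 = 91.4) is resolved in favor of the counts,
and the discrepancy is documented rather than reproduced.

## The phantom generator

`generate_phantom()` draws an ellipse (semi-axes 0.30 and 0.36 of the
256-pixel frame, jittered ±3% in position and scale) on a black frame. The
interior is a bright core at intensity 1.0 — white matter shows high
nonspecific binding on amyloid PET — and the outer 20% of the ellipse is a
cortical rim at 0.35 for NC. Disease raises the rim by a class-specific
fraction of the core–rim contrast: SMC 0.05, EMCI 0.12, LMCI 0.30, AD 0.60
by default, a monotone gradient mirroring the clinical ordering. The image
is then smoothed with a Gaussian of 8 px FWHM (emulating the uniform 8 mm
resolution filter applied to clinical PET at roughly 1 mm/px) and Gaussian
noise (SD 0.08) is added *after* smoothing — scanner noise lives on the
reconstructed, filtered image — and clipped at zero. Datasets are written
as 8-bit PNGs on a fixed shared intensity scale (ceiling 1.5 × core) so
between-image contrast survives quantization.

What the phantom does **not** emulate: anatomy (gyri, ventricles,
asymmetry), attenuation/scatter/reconstruction physics, scanner
harmonization differences, and biological label noise — in real cohorts a
sizeable fraction of non-AD subjects are amyloid-positive and some NC
subjects are too, which is precisely why published prodromal-stage
accuracies are modest. A green synthetic test therefore establishes that
the pipeline recovers a graded rim-contrast signal of known size; it does
not certify clinical accuracy. Absolute uptake units are arbitrary: only
relative contrast is calibrated.

## Numerical and testing choices

* All randomness flows through R's RNG; every public operation that draws
  random numbers takes an explicit seed and restores the caller's RNG
  state. The C++ loop consumes the same stream (Fisher–Yates with
  `unif_rand`), so training histories are bit-reproducible.
* Degenerate inputs fail loudly with classed conditions: all-background
  images (nothing to crop), non-divisible APPN sides, shape mismatches,
  undefined metrics (no positives or no negatives).
* The simulation-scale acceptance tests state their sizes in-line: the
  convergence test uses 30 phantoms/class at noise 0.05 and runs to the RMS
  threshold (~10^5 epochs, minutes); the effect-size-ordering test uses 50
  phantoms/class over 10 seeds with training capped at 1,500 epochs per
  run, because held-out accuracy plateaus orders of magnitude before the
  RMS tail ends. Caps were fixed from the convergence analysis above, not
  tuned against outcomes.
* Minimal TIFF (baseline, uncompressed) and NIfTI-1 readers are included
  because no reader for those formats is available in the supported
  dependency set; both are validated against independent Python readers in
  the test suite. For volumes, the first array axis is the slice axis and
  the default slice is the middle one — which plane of a subject's volume
  to analyze is a user decision the method itself does not prescribe.

## Known limitations

* Binary experiments only (NC versus one group); no 5-way classification,
  cross-validation, or ROC analysis.
* The hold-out protocol has a single split; reported metrics inherit its
  variance. Seeds make this reproducible, not smaller.
* Hidden-layer ReLU is provided but the reference configuration is
  sigmoid; no tangent-sigmoid or hard-threshold activations.
* The phantom's simplicity means synthetic accuracies should not be read
  as forecasts of clinical performance (see above).
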