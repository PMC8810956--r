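---
title: "Detecting local tumor progression on post-ablation CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting local tumor progression on post-ablation CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After radiofrequency or microwave ablation of hepatocellular carcinoma,
follow-up contrast CT is read for *local tumor progression* (LTP): a new
enhancing nodule at the margin of the treated, devascularised ablation
zone. On arterial-phase images the ablation zone is hypodense relative to
liver parenchyma while LTP nodules enhance; the perceptual task is finding
a small bright blob next to a dark cavity, among bright distractors such as
hepatic vessels and arterioportal shunts. `ltpdetect` implements a
patch-based screening pipeline for this task: multi-window channel
composition, rule-based 3D patch sampling around annotated lesion centres,
a small 3D convolutional classifier, validation-set operating-point
selection, and bounding-box region proposals rendered on axial slices. A
synthetic phantom generator stands in for patient data so that every stage
is exercised end to end by the test suite.

## Multi-window three-channel representation

CT voxels are Hounsfield units spanning roughly 12 bits; the classifier
consumes 8-bit channels. Each channel is the standard radiology display
transform applied with a different window:

out = clamp(round(255 · (HU − WL + WW/2) / WW), 0, 255)

with the liver window (WL 60 / WW 400) on the red channel, the ablation
window (WL 80 / WW 60) on green and the tumor window (WL 120 / WW 40) on
blue. The narrow tumor window saturates enhancing nodules; the ablation
window preserves the treated-zone contrast; the wide liver window keeps
anatomical context. All three channels are re-windowings of one
arterial-phase volume, so "registration" is identity alignment — no
resampling occurs and the composed volume inherits the source geometry
exactly. The rounding rule (round-half-up) is isolated in one function and
pinned by tests, because floor vs round changes single gray levels at
window edges.

## Coordinate conventions

Volumes use 0-based voxel indices ordered (x, y, z) = (column, row,
slice). World coordinates are RAS millimetres (the 3D Slicer convention in
which lesion fiducials are recorded); DICOM geometry, which is LPS, is
sign-converted at load. Annotations arrive either as FCSV fiducials (RAS or
LPS, converted on read) or as plain CSV tables of voxel indices (the
phantom's native format). Non-axial acquisitions are rejected rather than
resampled — the patch geometry is defined on axial slices.

## Patch sampling rules

Patches are 32 × 32 pixels in-plane by 8 axial slices, three channels. For
an annotated lesion centre p = (x, y, z):

* **Positives** — 20 patches per lesion whose in-plane centres are uniform
  integer jitters of p with |Δx|, |Δy| ≤ 12, so p always stays at least 4
  voxels inside the footprint; all 20 share the 8-slice stack centred on
  p's z (slices z−4 … z+3; the low-biased centre is the package's
  convention for the even stack depth). Lesions closer than 4 slices to the
  axial boundary are refused by name — padding would fabricate HU values.
* **Negatives in lesion-bearing cases** — 40 per case, centres uniform over
  all fully in-bounds positions but strictly outside a Euclidean sphere of
  radius 15 voxels around every lesion centre. The radius is interpreted in
  voxel units and kept in `sampling_config` so a millimetre-based variant
  is a one-line change. Note the sphere constrains patch *centres*: a
  negative centred 16–20 voxels from a lesion may still clip the lesion's
  rim inside its footprint. These deliberately ambiguous negatives are part
  of the sampling rule, and they are what bounds achievable per-patch
  discrimination.
* **Negatives in control cases** — 40 random fully in-bounds patches per
  case, restricted to the body (centre voxel above −500 HU) so air-only
  patches are not drawn. Whole-volume rather than liver-restricted sampling
  is intentional: negative candidates should span the full spectrum of
  distractors.

With the reference cohort layout (49 lesions split 36/5/8 across
train/validation/test; 34 lesion-bearing cases split 21/5/8; 40 controls
split 27/5/8) this yields exactly 980 positive patches (720/100/160),
1,360 lesion-case negatives and 1,600 control negatives, with an
800-patch test split (160 positive / 640 negative). The split is always at
case (patient) level; the test suite asserts that no case feeds two
splits.

## Augmentation

Axial-plane augmentation of training positives composes flip, integer
shift (≤ 4 px), shear (≤ 10°), isotropic zoom (0.9–1.1) and rotation
(≤ 15°), each applied with probability ½, identically to every slice and
channel, with nearest-neighbour resampling. Two choices matter and are
deliberate:

* **Edge replication, not zero fill.** Zero-filled corners after rotation
  gave augmented positives a trivially recognisable black-wedge signature;
  the network learned the artefact instead of the lesion and validation
  performance degraded. Out-of-footprint source coordinates are clamped to
  the border instead.
* **Online augmentation.** Positives are re-augmented with fresh random
  transforms at the start of every epoch rather than once up front, so the
  network never sees the same positive twice. With only hundreds of
  distinct positives this markedly reduces overfitting.

## The classifier

The network is a small 3D CNN: three same-padded 3 × 3 × 3 convolution
stages of 16, 32 and 64 feature maps, 2 × 2 × 2 max pooling after the
first two stages (the printed stage sizes 16@8×32×32 → 32@4×16×16 →
64@2×8×8 force exactly two pools), then fully connected layers of 512 and
128 rectified-linear units and a single sigmoid output. The flattened
vector entering the first fully connected layer has 64·2·8·8 = 8,192
units. `infer_stage_shapes()` propagates these sizes analytically and
`forward_stage_shapes()` verifies them against real tensors — the two are
compared in the acceptance suite.

No deep-learning framework is involved: the convolution and pooling
kernels are im2col + GEMM routines written for this package
(Rcpp/RcppArmadillo), with gradients verified against central finite
differences in development. Internally a sample is the flattened R array
(x, y, z, channel); inputs are scaled to [0, 1].

Training is minibatch Adam on binary cross-entropy — the natural loss for
a sigmoid output — with the following defaults, all overridable through
`train_config()` and logged with every run: learning rate 1e-3 decayed by
0.92 per epoch, batch 32, decoupled weight decay 1e-4, early stopping on
validation AUC (patience in epochs; the best-validation state is
returned). Class imbalance is handled by the sampling ratio (40 negatives
per case against 20 positives per lesion), not by loss weighting. Training
and validation patches must come from disjoint cases; the trainer enforces
this.

## Operating point, metrics and proposals

The decision threshold is chosen on the validation split as the cut
maximising (sensitivity + specificity)/2 over all distinct predicted
probabilities, with ties broken toward higher specificity and then the
larger threshold; when a gap separates the winning cut from the next lower
score the gap midpoint is returned (any value in the gap yields identical
predictions). A probability equal to the threshold is a positive call.

Test-split performance is reported as sensitivity, specificity, PPV and
accuracy at that threshold, ROC AUC, and step-wise (non-interpolated)
average precision. AUC and the ROC curve come from pROC (the AUC is the
Mann–Whitney statistic; the test suite checks it against exhaustive pair
counting); proportion intervals are exact Clopper–Pearson; the AUC
interval is DeLong's. A metric with a zero denominator is flagged
undefined rather than silently NaN.

Above-threshold patches become `ProposalRecord`s: the patch centre, its
probability, the axial slice number, a 32 × 32 in-plane box centred on the
patch centre, and the z-range of its slice stack. Proposals are sorted by
descending probability and are not merged — no non-maximum suppression is
applied, matching the deployment description; overlapping boxes remain
visible. `render_prediction_map()` draws the boxes in red on every slice
of each proposal's stack and returns slice numbers and probabilities as an
annotation table alongside the rasters (also written to CSV/PNG); text is
not burned into pixels, which keeps rendering free of any graphics-device
dependency. `grid_candidates()` adds an annotation-free screening mode — a
regular grid of fully in-bounds patch centres — as a clearly labelled
extension, since candidate extraction around known coordinates is circular
at screening time.

## The phantom: what it emulates and what it does not

Each phantom case is a liver-like block (100 HU, arterial-phase
parenchyma) containing a hypodense spherical ablation zone (45 HU, radius
10 mm), optional enhancing lesions (120 HU — the centre of the tumor
window — diameter 6 mm) placed uniformly on the ablation sphere's surface
with ±2 mm radial jitter (the ablative-margin location that defines LTP),
and bright straight cylindrical vessels (150 HU, radius 1.5 mm) as
distractors, since vessels are the canonical false-positive source.
Gaussian HU noise (σ = 10) is added after structure placement; structures
are painted liver → ablation → vessels → lesions so a lesion centre voxel
always carries exactly the lesion HU before noise. The default grid is
96 × 96 × 24 voxels at 0.7 × 0.7 × 3.0 mm — the thick-slice axial regime
of clinical follow-up CT, shrunk in-plane to the neighbourhood of one
ablation site so cohorts generate in seconds.

Deliberately absent: anatomical context (ribs, kidneys, aorta),
contrast-phase kinetics, scanner noise spectra and texture, lesion shape
irregularity, and respiratory/positioning variation. Passing the phantom
bars therefore demonstrates that the pipeline's plumbing, sampling rules,
optimisation and bookkeeping are correct and that the model can learn the
intended contrast-and-context cue — it says nothing about clinical
performance on patient data. HU statistics for real LTP lesions and
ablation zones are not published in a usable form; the phantom values were
chosen once to respect the window-setting geometry (ablation < liver <
lesion ≤ vessel, lesion centred in the tumor window) and have not been
adjusted since.

## Study scale and runtime

The end-to-end experiment (`run_phantom_experiment()`) defaults to the
reference cohort layout above — 74 cases, 3,940 patches, 2,640 of them for
training — with an 8-epoch training budget, which completes in roughly ten
minutes on a single CPU core. The held-out bars asserted by the acceptance
suite (test AUC ≥ 0.95, lesion hit rate ≥ 0.9) are property bars for this
synthetic setting, not clinical claims. At a quarter of that training-set
size the same model plateaus around AUC 0.93 — the ambiguous exclusion-rim
negatives and vessel distractors dominate the error budget when training
cases are few — which is why the full reference scale is the default.

## Numerical choices and degenerate inputs

* Windowing rounds half-up; tests pin the exact gray levels at window
  edges and centres.
* `ras_to_voxel` rounds to the nearest voxel and rejects points more than
  half a voxel outside the grid, naming the offending axis.
* Threshold selection warns and returns the common value when all
  validation probabilities are identical.
* Patch extraction never pads: boundary lesions are an error naming the
  case.
* The exclusion-sphere sampler aborts with a clear message when the
  geometry cannot host the requested number of negatives.
* Seeds: every stochastic stage (phantom, cohort assignment, sampling,
  augmentation, initialisation, shuffling) takes an explicit seed; a master
  seed derives per-stage seeds, and repeated runs are bitwise identical.

## Known limitations

Per-patch evaluation only (no FROC per lesion); single arterial phase; no
washout confirmation — the pipeline proposes candidates for a radiologist,
it does not diagnose. The DICOM reader supports uncompressed little-endian
single-frame CT series only. The patch archive format is RDS + CSV, which
is R-native; interoperable HDF5 export would require an HDF5 binding.
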