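# ltpdetect

Detection of **local tumor progression (LTP)** on arterial-phase CT after
thermal ablation of hepatocellular carcinoma, as a patch-based 3D deep
learning pipeline — with a synthetic CT phantom generator so the whole
system runs, trains and is tested without any patient data.

After radiofrequency or microwave ablation, follow-up CT is screened for a
new enhancing nodule at the margin of the hypodense ablation zone. This
package implements that screening task end to end:

1. **ct_io** — DICOM series / NIfTI volume readers with unambiguous
   RAS-mm ↔ 0-based-voxel geometry, 3D Slicer FCSV fiducial parsing.
2. **windowing** — the radiology display transform
   `out = clamp(round(255·(HU − WL + WW/2)/WW), 0, 255)` applied with the
   liver (60/400), ablation (80/60) and tumor (120/40) windows to form a
   co-registered 3-channel 8-bit volume.
3. **patch_sampler** — 32×32×8 three-channel patches: 20 jittered
   positives per annotated lesion, 40 negatives per case with centres
   strictly outside a 15-voxel exclusion sphere around each lesion
   (lesion-bearing cases) or uniform in-body (controls); axial-plane
   augmentation (flip/shift/shear/zoom/rotation).
4. **model** — a 3D CNN written from first principles (Rcpp/RcppArmadillo
   im2col + GEMM kernels): three same-padded 3×3×3 conv stages of
   16/32/64 maps (16@8×32×32 → 32@4×16×16 → 64@2×8×8, two 2×2×2 max
   pools), FC 512 → FC 128 → sigmoid; Adam on binary cross-entropy with
   early stopping on validation AUC.
5. **evaluate** — confusion metrics at an operating threshold chosen on
   the validation split by maximising (sensitivity+specificity)/2, ROC
   AUC (Mann–Whitney, via pROC) with DeLong CI, Clopper–Pearson CIs,
   step-wise average precision, exportable ROC/PR curves.
6. **region_proposal** — above-threshold patches become bounding-box
   proposals (centre, probability, slice number, 32×32 box, slice-stack
   range), rendered as red rectangles on axial slices; plus a grid-based
   whole-volume screening mode.
7. **phantom** — synthetic post-ablation cases: liver block (100 HU),
   spherical ablation zone (45 HU), enhancing margin lesions (120 HU, on
   the ablation rim ±2 mm), bright tubular vessels (150 HU) as
   false-positive distractors, Gaussian HU noise; with exact ground-truth
   lesion centres, written as NIfTI + FCSV/CSV.

## Worked example

The full phantom experiment — generate a 74-case cohort (34 LTP cases
with 49 lesions, 40 controls; case-level splits 21/5/8 and 27/5/8, lesion
split 36/5/8), window, sample 3,940 patches, train, pick the threshold,
evaluate, propose — runs in about ten minutes on one CPU core:

```r
library(ltpdetect)
ex <- run_phantom_experiment(seed = 11, verbose = TRUE)
print(ex)
```

```
          
           test train validation
  negative  640  1920        400
  positive  160   720        100
  threshold: 0.1091
  test AUC: 0.9977, AP: 0.9901
  lesion hit rate: 1.00 (8 test lesions)
```

Reading this: the sampler reproduced the reference patch bookkeeping
exactly (800-patch test split: 160 positive / 640 negative); the
validation split selected an operating threshold of 0.109; on the held-out
test patches the classifier reached ROC AUC 0.998 and average precision
0.990 (confusion at the threshold: tp=158, fp=12, tn=628, fn=2); and every
one of the 8 held-out lesions was covered by at least one proposal box on
its own slice stack (hit rate 1.00).

Smaller pieces work standalone:

```r
case <- generate_case(phantom_params(seed = 7), "demo")   # one phantom
mcv  <- compose_channels(case$volume)                     # 3-channel 8-bit
pos  <- extract_positive_patches(mcv, case$lesion_centers[1, ],
                                 sampling_config(seed = 1), "demo")
infer_stage_shapes(network_spec())   # 16@8x32x32 / 32@4x16x16 / 64@2x8x8
```

A command-line wrapper lives at `inst/scripts/run-phantom-experiment.R`.

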