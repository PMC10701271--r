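---
title: "Closed-loop automated SRS planning: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop automated SRS planning: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Stereotactic radiosurgery (SRS) of a solitary brain metastasis delivers a
high dose (here 30 Gy in 5 fractions) to a small target (the PGTV) with a
very sharp fall-off, sparing the brainstem, optic apparatus, lenses, eyes
and hypophysis. `doseloop` implements a fully automated planning loop for
this setting:

1. **predict** a patient-specific 3D dose distribution from CT and
   contours with a 3D UNet or an attention-fusion UNet (AttUNet);
2. **mimic** that prediction with a deliverable plan: auto-configured
   coplanar beams, voxel-wise fluence optimization through a deposition
   matrix, and dual-layer orthogonal MLC sequencing;
3. **verify** the deliverable plan with the full dosimetric panel (DVH,
   D2%/D98%/D95%/D50%, HI, CI, R50%, D2cm, OAR doses) and 2D/3D gamma
   analysis at 3 mm/3%.

Because clinical DICOM-RT cohorts cannot be redistributed, the package
ships a phantom generator that produces synthetic head cases with the same
statistical and geometric structure the pipeline expects, so every stage
is exercised end-to-end by code alone.

## Dose-prediction models

Both networks are volumetric encoder–decoders. Each encoder level applies
two 3×3×3 convolutions, each followed by batch normalization and ReLU,
and levels are bridged by 2×2×2 max pooling; filter counts start at
`base_filters` and double per level, peaking at `base_filters * 2^depth`
in the bottleneck (the full-scale preset is depth 4, 32→512 filters). The
decoder mirrors the encoder with 2× nearest-neighbour upsampling and skip
connections; a pointwise convolution emits the single dose channel at
input resolution.

The **UNet** variant encodes the structure channel alone (a wiring switch
`include_ct` also accepts the CT channel, as both conventions are common).
The **AttUNet** variant runs separate structure and CT encoders and fuses
them at the bottleneck with multi-head cross attention: every bottleneck
voxel is a token, Queries come from the structure features, Keys/Values
from the CT features, and the full-scale preset uses 8 heads of 64
dimensions. Design choices worth stating explicitly:

* **Score scaling.** Scores are dot products divided by `sqrt(head_dim)`;
  the scaling is the numerically stable standard and can be disabled
  (`scale_attention = FALSE`) to recover raw dot products.
* **Fusion location.** Attention is applied at the bottleneck only, where
  the token count (e.g. 12×12×4 at desk scale) keeps the quadratic
  attention cost tractable.
* **Skips.** Decoder skip connections come from the structure encoder;
  a residual connection adds the structure bottleneck onto the attention
  output (`attn_residual`), which stabilizes early training.

Training uses mean squared error between predicted and reference dose on
the normalized scale, Adam at learning rate 1e-4, batch size 2, Kaiming
initialization, a plateau schedule dividing the learning rate by 10, and
early stopping after 100 epochs without validation improvement (1000
epoch ceiling). The data split holds out 20% of the training cases for
validation; with a single case the validation loss falls back to the
training loss. All of it is seed-deterministic.

The layer stack (3D convolution via im2col and BLAS, batch norm, pooling,
upsampling, attention, Adam) is implemented natively in R and verified by
finite-difference gradient checks; no external deep-learning runtime is
involved.

## Preprocessing

CT values are clipped to [−200, 300] HU and mapped affinely to [−1, 1]
(so −200→−1, 50→0, 300→+1). Dose is mapped affinely from
[0, `dose_ref_max`] to [−1, 1]; the ceiling defaults to 42 Gy (1.4× the
prescription), a global per-cohort convention chosen because observed
near-maximum doses (D2% ≈ 37 Gy) sit safely below it. Structures are
painted into one integer-label channel in a fixed priority order with the
PGTV last, so the target wins overlaps; a one-hot mode is available. The
label channel is rescaled to [−1, 1] so every input channel shares the
value range; the code map in `meta` restores the masks exactly.

Cases are resampled to 2.5 mm isotropic and cropped to a window centred
on the PGTV centroid — 224×224×32 voxels in the full-scale preset,
96×96×32 at desk scale. The window origin snaps to the resampling lattice
so that an identity-spacing crop is an exact sub-array, making
crop-then-restore lossless inside the window; windows that reach past the
volume are padded with air HU and zero dose. Cases with a PGTV of at most
20 cc form the `small` group (inclusive threshold), the rest `large`.

## Dose engine and mimicking

The engine is a deliberately simple analytic pencil-beam model, not a
transport code: per beamlet, dose falls off as
`exp(-mu_eff * depth) * exp(-lat^2 / (2 sigma^2)) * (SAD/(SAD+depth))^2`,
with water-equivalent depth measured by ray marching through the external
contour (the medium is homogeneous water inside the head; HU
heterogeneity is deliberately ignored). Defaults: `mu_eff` 0.004/mm,
penumbra sigma 3 mm, SAD 1000 mm, 5 mm beamlets, entries below 1e-4 of
their column maximum dropped from the sparse matrix. The point of this
engine is closed-loop self-consistency — planning, delivery and
verification all share the same physics — which is exactly what the test
suite needs; absolute dosimetric realism is out of scope.

Beams follow the clinical auto-configuration protocol: the primary beam
direction links the brain centre to the target centre (projected to the
axial plane; for phantoms the head-mask centroid stands in for the brain
contour), four more beams are added clockwise at 20° and four
counter-clockwise, giving nine uniformly spaced coplanar beams with the
isocentre at the PGTV centroid. Angles use IEC 61217 (gantry 0 = source
anterior, clockwise viewed from the feet); if the target centroid
coincides with the brain centre the primary defaults to gantry 0.

Fluence optimization minimizes the importance-weighted squared deviation
from the predicted dose subject to non-negativity, by projected gradient
descent with Barzilai–Borwein steps, a monotone backtracking safeguard,
a 1e-6 relative-objective tolerance and a 500-iteration cap. Weights
default to 10 inside the PGTV, 3 in a 20 mm shell, 1 elsewhere. MLC
sequencing quantizes each fluence map to 10 uniform levels and delivers
the super-level sets as segments of an idealized dual-layer orthogonal
MLC (per-row column intervals intersected with per-column row intervals;
binary transmission, no leakage or tongue-and-groove). For row/column-
convex level sets — which bell-shaped optimized fluences are in practice —
reconstruction is exact up to half a quantization step.

The final plan is renormalized so the delivered D95%(PGTV) equals the
prescription, the standard clinical plan normalization; this scales the
fluence, segment weights, and delivered dose jointly and leaves the
gamma comparison unaffected. Verification recomputes every field at
gantry 0 onto a simulated detector plane (50 mm water-equivalent depth,
2.5 mm pitch), composites the fields, and runs 2D gamma between the
planned and deliverable fluence maps; a 3D gamma between planned and
delivered volumetric dose is also reported.

## Gamma analysis conventions

The criteria are 3%/3 mm with global normalization to the reference
maximum, a 10% lower-dose threshold (points below it leave the
denominator), a search radius of 3× the DTA, and optional sub-voxel
refinement of the evaluated distribution by lattice interpolation
(3× refinement on 2D planes, none by default in 3D where the native
2.5 mm pitch is already well under the DTA). All of these materially
affect pass rates and are therefore explicit, configurable arguments.
Interpolation at the volume border excludes out-of-support candidates
rather than extrapolating.

## The phantom generator

Each case is a head-like ellipsoid (semi-axes 70×85×75 mm) with a 6 mm
skull shell, brain/tumor/skull/air HU of 40/60/700/−1000 and additive
Gaussian CT noise (sd 20 HU) that exercises the clipping path. Nine OARs
are geometric primitives (spheres and capsules) at anatomically plausible
offsets, deliberately separated from the sampled target locations;
anatomical fidelity is explicitly not a goal — only the relative geometry
matters. Targets are spheres with centres rejection-sampled inside the
brain, at least 2 mm clear of every OAR, radii set by the requested
volume (the dataset generator draws 2–18 cc for the small group and
23–58 cc for the large group, straddling the 20 cc threshold with a
margin so rasterization cannot flip a label). Masks rasterize a voxel
when its centre lies inside the primitive, so voxel-counted volumes
converge to the analytic volumes as the lattice refines.

The reference dose is produced by the package's own engine: fluence is
optimized against an idealized objective — 105% of the prescription
inside the PGTV with an exponential fall-off of 5 mm half-dose distance,
reflecting SRS-grade gradients — then renormalized to D95% = 30 Gy. The
resulting plans land in clinically familiar ranges (CI ≈ 0.9, R50% in the
2–4 band, D2cm around 10 Gy) and satisfy the planning criteria checker by
construction.

What the phantoms do **not** emulate: tissue heterogeneity, multi-lesion
cases, real contour irregularity, scanner artifacts, or inter-planner
variability in reference plans. Tests passing on phantoms therefore
demonstrate the pipeline's internal consistency and the correctness of
its algorithms, not clinical-grade prediction accuracy on real patients.

## Numerical choices and degenerate inputs

* Dose-at-volume interpolates linearly between order statistics (ties
  toward the lower dose, conservative for coverage); `q = 100` returns
  the minimum.
* D2cm uses an exact Euclidean distance transform (separable
  lower-envelope algorithm) and reads the maximum dose on the
  [20 mm, 20 mm + pitch) shell; a flag switches to the supremum over the
  whole ≥20 mm exterior, since both readings of "2 cm outside" are
  defensible. An empty shell (target at the volume border) is an error
  prompting padding.
* The Dice coefficient of two empty isodose volumes is defined as 1 and
  logged.
* A prescription isodose volume that is empty gives CI = 0 and is logged.
* Doses above the normalization ceiling are clipped with a log message;
  negative network outputs are clamped to zero Gy on denormalization.
* The optimizer's objective history is non-increasing by construction
  (backtracking), so descent is a testable invariant.

## Problem sizes

The default desk-scale configuration — 96×96×32 voxels at 2.5 mm, depth-3
models with 16 base filters — runs the full closed loop in minutes on one
CPU core. The test suite uses still smaller instances chosen for fast,
exhaustive oracle checking: 48×48×16 phantoms at 5 mm for engine and
mimicking tests, 16×16×16 crops with depth-2/8-filter models for the
learning-sanity checks (which reach the <5% overfit criterion well inside
the 300-epoch budget), and ≤16³ grids wherever a brute-force oracle is
compared exhaustively. The full-scale preset (224×224×32, depth 4,
32→512 filters) is provided for completeness but is GPU-class work and is
only construction-checked in the tests.

## Known limitations

The dose engine is analytic and homogeneous; absolute doses are
self-consistent, not traceable to measurement. The dual-layer MLC is
idealized as binary transmission. DICOM-RT import/export is not included
— volumetric I/O is NIfTI plus JSON sidecars. Training at the full-scale
preset is impractical without accelerator hardware, and nothing in this
package claims to reproduce clinical-cohort accuracy figures; the test
suite establishes definitional correctness, oracle equivalence and
closed-loop consistency on synthetic data.
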