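---
title: "Handling inter-modality misalignment in multi-modal prostate MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling inter-modality misalignment in multi-modal prostate MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bi-parametric prostate MRI pairs a high-resolution anatomical T2-weighted
volume with diffusion-weighted acquisitions (a high-b-value DWI and the
derived ADC map). The sequences are acquired minutes apart: patient
motion, bladder filling, bowel contraction and susceptibility-induced
geometric distortion all displace the diffusion images relative to the
T2w. Lesion annotations drawn on one modality therefore need not overlap
the same lesion's appearance on another, and a segmentation model trained
on stacked channels inherits that inconsistency.

`misalignr` implements three complementary responses and the measurement
apparatus around them:

1. **Misalignment augmentation** — during training, randomly displace the
   T2w channel *and its lesion annotation* relative to the diffusion
   channels, so the model learns features robust to the misalignments it
   will meet at test time.
2. **Registration** — reduce the misalignment before training, either
   intensity-based (mutual-information B-spline) or mask-driven
   (ground-truth matching).
3. **Evaluation** — quantify residual misalignment with inter-modality
   lesion Dice distributions, and quantify the diagnostic consequence with
   patient-level AUROC, bootstrap confidence intervals, the DeLong test
   and PI-RADS operating points.

Everything is exercised on synthetic phantoms with *known* ground-truth
misalignment, so each claim the package makes is testable without
clinical data.

## The augmentation model

A misalignment realization is the composition of three components, each
sampled independently and uniformly on a symmetric interval around the
identity:

* translation $t = (t_x, t_y, t_z)$ with $|t_i| \le (10, 10, 6)$ mm,
* rotation $\theta$, $|\theta| \le 15^\circ$, restricted to the in-plane
  (x–y) axes because the slice spacing (3 mm) is an order of magnitude
  coarser than the in-plane resolution,
* an affine "squeeze" along the dorsal–ventral axis with factor
  $s \in [0.9, 1.1]$, emulating the front–back distortion that
  magnetic-field inhomogeneity induces between T2w and echo-planar DWI.

The composed transform is

$$T = \mathrm{Translate}(t)\circ\mathrm{Rot}_z(\theta; c)\circ\mathrm{Scale}_y(s; c)$$

about a fixed point $c$. The order of composition is a package choice —
the three components are defined individually, not as an ordered product —
and at these amplitudes the commutator error between orders is sub-voxel,
which the image–label coherence test makes concrete. The fixed point
defaults to the geometric center of the voxel grid; a prostate-centroid
option exists because exams are prostate-cropped anyway, making the two
choices nearly identical in practice.

Gating is a single Bernoulli draw per exam with probability
$p \in \{0, 0.1, 0.2, 0.4\}$ (any $p \in [0,1]$ is accepted): either all
three components apply jointly, or the exam passes through bit-identical.
The draw order (gate, $t_x$, $t_y$, $t_z$, $\theta$, $s$) is fixed so a
seeded generator reproduces a pipeline exactly.

Two contracts matter for correctness:

* **Only the T2w side moves.** The augmentation displaces `t2w` and
  `lesion_mask_t2w`; the DWI-domain members are returned untouched (the
  tests assert bit-identity). This mirrors how the misalignment arises:
  the annotation follows the modality it was drawn on.
* **Before global augmentation.** `augmentation_pipeline()` refuses a
  stage ordering in which a global spatial augmentation precedes the
  misalignment stage, because resampling an already globally-transformed
  image a second time compounds interpolation artifacts and the
  misalignment is meant to model an acquisition-level offset that exists
  prior to any augmentation.

Transforms act in physical millimetres (spacing is anisotropic), with
backward (pull) resampling: linear interpolation for images, nearest-
neighbor for label volumes, out-of-domain voxels filled with the volume
minimum (0 for masks). An exactly-identity transform short-circuits to
the input array so that zero-amplitude configurations are bit-exact
no-ops.

## Registration

`register_bspline()` aligns the DWI domain to the T2w grid by maximizing
mutual information. The lowest-b-value DWI serves as the moving image —
among the diffusion acquisitions it is the most T2w-like in contrast, so
it carries the most registration signal — and the fitted transform is
then propagated unchanged to the high-b DWI and the ADC map
(`propagate()`), with nearest-neighbor interpolation for masks. The
implementation is a three-level multi-resolution scheme: at each level a
Nelder–Mead search over the misalignment family itself (translation,
in-plane rotation, dorsal–ventral scale) maximizes hard-binned MI
(32 bins); the result then initializes a cubic B-spline free-form
refinement (control spacing 40 mm) optimized by L-BFGS-B on soft-binned
(tent-kernel) MI with a small ridge penalty on the control
displacements. Soft binning makes the objective differentiable so
finite-difference gradients are meaningful; the penalty keeps the
refinement well-posed where the image carries no gradient. All knobs are
exposed in `reg_options()`.

`register_gt_matching()` is the mask-driven reference: an affine
transform maximizing the soft Dice of Gaussian-smoothed (σ = 1.5 mm)
prostate + lesion masks, lesions weighted 2:1 over the gland, initialized
by prostate-centroid alignment and polished at full resolution. It is
deterministic and uses no intensities, which is what makes it a fair
reference for judging the intensity-based method. If the fitted transform
fails to improve the hard prostate Dice it is discarded for the identity,
with a warning.

Two details matter for parameter recovery. First, both registrations fit
the correcting transform in the *reversed* component order
(Translate ∘ Scale$_y$ ∘ Rot$_z$): the inverse of a forward misalignment
lies exactly in that reversed family, so the fit carries no structural
parameterization error, and `transform_rotation_deg()` reads the in-plane
angle exactly off the fitted matrix. Second, both run a small rotation
multi-start at the coarsest level, because near-symmetric anatomy gives
overlap and MI surfaces a shallow competing optimum at the mirrored
angle.

Registration never touches the fixed (T2w-domain) data; only DWI-domain
members are resampled. On noise-free phantoms with injected misalignments
drawn from the full augmentation bounds, GT-matching recovers
translations to within one voxel and rotations to within 2°, and both
methods raise the mean inter-domain lesion Dice well above the
unregistered value — the direction expected of any functioning
registration, and the package's acceptance tests assert exactly that.

## Preprocessing

`resample_to_target()` brings every exam to a common grid (default
0.3125 mm in-plane, 3 mm slices — the slice distance is left unchanged by
convention since it is shared across acquisitions). `normalize_exam()`
z-scores T2w and DWI per exam (arbitrary units) but normalizes ADC with
mean/sd pooled across the training set, because ADC values map to a
physical quantity and the same value must normalize identically in every
exam; the pooled statistics default to prostate-masked voxels
(`adc_dataset_stats()`), with a whole-volume option. `crop_to_prostate()`
crops to the gland bounding box with a default 10 mm margin — the margin
is a package choice; cropping "to the prostate" needs some context for
the network, and 10 mm keeps the full peripheral zone and immediate
surroundings at every realistic gland size. `balanced_sampler()`
implements the class-balanced loader: class uniform first, exam uniform
within class, giving a long-run positive fraction of 1/2 at any
prevalence.

## Evaluation

Inter-modality annotation agreement is summarized by `lesionwise_dice()`:
lesions are paired greedily by maximal voxel overlap and unmatched
lesions score 0 — a lesion annotated in one modality only is a complete
disagreement, not a missing value. (Dropping orphans instead is available
behind a flag; the greedy rule is the default because the alternative
silently inflates agreement.) Both-empty masks score Dice 1: there is no
disagreement to penalize. `dice_distribution()` adds the sample mean/sd
and a Gaussian-kernel density on [0, 1] with boundary reflection
(Silverman bandwidth, floored at two grid cells so degenerate samples
remain integrable); reflection keeps the density mass on the unit
interval to within $10^{-3}$.

The patient-level score is the maximum of the predicted lesion
probability map (`patient_score()`). `auroc()` is the Mann–Whitney
statistic (ties count 1/2) computed from ranks, exact against an
exhaustive pairwise count. `bootstrap_auroc_ci()` gives a percentile
interval over 1000 case-resampled replicates (single-class replicates are
redrawn); the percentile type is a package choice among the standard
bootstrap interval types. `delong_test()` implements the
structural-component covariance estimator for paired AUROCs; a
numerically zero variance (e.g. identical score vectors) returns p = 1
with a warning, since the test statistic is undefined and "no evidence of
a difference" is the only defensible report. `pirads_operating_point()`
computes sensitivity/specificity at the clinically informative
thresholds PI-RADS ≥ 3 and ≥ 4, and `evaluate_configurations()` rolls
the pieces into a per-configuration table with a marked reference row.

## The phantom

`generate_phantom()` builds an idealized ellipsoid anatomy: a body
ellipsoid, a prostate with a transition-zone core (shifted anteriorly)
and a peripheral-zone shell, and spherical lesions placed inside the
gland without overlap (placement failures after bounded retries raise an
error naming the lesion). The gland has an absolute anatomical size
(about 34 × 28 × 24 mm) rather than scaling with the imaged volume, so
the caller chooses a field of view with enough margin for any
misalignment it intends to inject — a displaced gland that collides with
the volume boundary is truncated, which genuinely shifts the optimum of
any overlap- or intensity-based registration (the same thing happens in
real data when the acquisition coverage is tight). Contrast polarity
follows bi-parametric MRI: lesions are hyperintense against the gland on
high-b DWI, hypointense on ADC, hypointense on T2w within the peripheral
zone. The T2w additionally carries a smooth, spatially asymmetric texture
field inside the body: real T2w is rich in structural detail, and a
piecewise-constant phantom would be mirror-symmetric in-plane and hence
rotationally ambiguous to intensity registration. The lowest-b DWI is
synthesized as a smoothed, contrast-reduced blend of the (textured) T2w
structure, reproducing the T2w-likeness that the intensity-based
registration exploits. Noise is additive Gaussian, parameterized as a
fraction of the gland–lesion contrast; Rician magnitude bias is
deliberately not modeled because none of the tested operators is
sensitive to it. No bladder or rectum, no bias fields, no susceptibility
artifacts beyond the affine squeeze: only the geometric and contrast
structure that the operators under test actually consume.

A known misalignment can be injected into the DWI domain; it is recorded
as `truth_transform`, making the phantom a ground-truth generator for
registration benchmarks: the two mask domains are related exactly by the
recorded transform, up to nearest-neighbor resampling.

`write_phantom_dataset()` emits a NIfTI-backed cohort with a CSV
manifest. Labels are prevalence-controlled (default 34.4%, the csPCa
prevalence of the cohorts the phantom emulates); positive exams carry
full-contrast lesions, negative exams at most one low-contrast indolent
lesion. The synthetic PI-RADS score is a monotone function of lesion
volume × contrast plus reader noise, binned to 1–5 — enough structure to
exercise operating-point code, with no claim of clinical realism.

What passing phantom tests do **not** show: performance on real anatomy,
real noise spectra, elastic (non-affine) misalignment, or CNN training
behaviour. The phantom validates the *operators* — sampling laws,
geometry, propagation, statistics — not clinical effect sizes.

## The toy segmenter

`toy_segment()` is a transparent stand-in for a trained segmentation
network in end-to-end tests: the geometric mean of logistic
lesion-evidence maps from the three channels, restricted to the gland.
Because it multiplies evidence *across* modalities at the same voxel,
inter-modality misalignment directly erodes its scores — which is the
mechanism the evaluation stack is supposed to detect, and the end-to-end
test asserts the resulting AUROC ordering (aligned ≥ misaligned). CNN
training itself is out of scope; the augmentation is exposed as a batch
transform (`misalignment_stage()`) that drops into any pipeline.

## Problem sizes and numerical choices

The test suite and the acceptance script run most phantoms at 48×48×14
voxels with 1.25 mm in-plane spacing and 3 mm slices (a 60 × 60 × 42 mm
field of view: enough z headroom that misalignments up to the full
augmentation bounds never truncate the gland), which keeps the full
suite at interactive speed. The GT-matching parameter-recovery
experiment alone runs at 0.625 mm in-plane (96×96×14): recovery accuracy
is limited by mask voxel quantization, and at 1.25 mm the discretization
error alone approaches the 2° rotation bound, so the recovery claim is
made at a resolution where the estimator — not the rasterization — is
being tested (clinical reconstructions are finer still, 0.3125 mm).
Sampling-law checks use $10^5$ draws; gating uses $10^4$ exams against
the exact binomial interval; registration recovery uses 20 noise-free
phantoms; bootstrap coverage uses 200 simulated trials at B = 1000.
Tolerances are stated per test: one voxel for centroid recovery, 2° for
rotation recovery, $10^{-3}$ for density mass, exact (to floating point)
for the AUROC oracle.

Degenerate inputs are contracts, not surprises: zero-amplitude
augmentation is bit-exact; constant volumes give MI 0 with a warning;
empty prostate masks, single-class label vectors, empty manifests and
singular transforms raise classed errors; a missing low-b DWI falls back
to ADC as the registration moving image, with a warning.

## Known limitations

* The B-spline refinement's free-form capacity is intentionally modest
  (coarse control lattice, few iterations): the phantom's misalignments
  are affine, so the affine-family stage does most of the work, and the
  refinement exists to absorb small residuals rather than to model
  elastic deformation at clinical fidelity.
* GT-matching recovery along the slice axis is the least accurate
  (within one 3 mm slice, not one in-plane voxel): the 3 mm slice
  quantization of the masks is an order of magnitude coarser than the
  in-plane raster, and a gland that collides with a tight acquisition
  boundary biases the overlap optimum further. The same effects exist in
  real data.
* The greedy lesion pairing is not optimal matching; with the small
  lesion counts of prostate exams the two rarely differ, and greedy is
  deterministic and order-independent given distinct overlaps.
* Orientation is canonicalized to RAS on load, so all axis conventions
  (the dorsal–ventral squeeze in particular) are well-defined; original
  orientation is reported but not restored on write.
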