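---
title: "Structure-guided deformable augmentation and contour evaluation: models and methods"
author: "DefAug"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-guided deformable augmentation and contour evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In MR-guided online adaptive radiotherapy, the anatomy of the upper abdomen
changes between treatment sessions: bowel loops move and change filling,
the stomach expands or empties, organs shift by several millimetres. A
segmentation model that must re-contour the organs of interest (OoIs) on
each daily session image faces two obstacles: very small patient cohorts,
and the need to handle patient-specific anatomy, including asymmetric cases
such as a single kidney.

`DefAug` implements a three-part toolkit around that problem:

1. **Structure-guided deformation augmentation** — simulate plausible
   inter-fraction anatomy changes by composing per-organ random
   similarity-type deformation fields, plus MR acquisition-variability
   augmentations (histogram shift, intensity scaling, Gibbs ringing).
2. **Single-organ conditioning** — arrange a cohort into three-channel
   cases `[I_m, L_{m,o}, I_n]`: a prior image, its mask for one organ `o`,
   and the target image, with patient-level leave-one-out folds and an
   on-disk layout a segmentation trainer consumes.
3. **Contour evaluation** — geometric metrics (DSC, ASD, HD95) and
   dosimetric metrics (DVH, D0.1cm³, D50%, dPD, dose-gradient-weighted
   Dice) for comparing predicted contours against ground truth.

A synthetic abdominal phantom generator makes every component testable
end-to-end with no patient data.

## The deformation model

Let `I(x)` be a session image and `L(x) = {L_1(x), ..., L_N(x)}` its organ
labels. For each organ, a random similarity motion is drawn with each
component uniform within configurable bounds `p`:

* translation per axis in `[-p_disp, p_disp]` (mm),
* isotropic scale in `[1 - p_shrink, 1 + p_exp]`,
* Euler rotation angles in `[-p_rot, p_rot]` (degrees) about the organ
  centroid.

The operator `phi` converts a drawn motion on a single label into a dense
displacement field `u_1(x) = phi(L_1(x), p)`. The organs are visited once
each; at step `k` the label is first carried through the already-composed
field before its own field is generated,

```
u_k = phi(L_k(u_{k-1} o ... o u_1(x)), p),
```

and the total field `u_tot = u_N o ... o u_1` finally warps the image
(linear interpolation) and all labels (nearest-neighbour) once. Every
invocation of `phi` advances the random stream, so two organs with the same
bounds still receive distinct fields.

### How `phi` builds a dense field

The field construction is the one genuinely open design point, and is
resolved as follows. The drawn motion defines an affine map
`A(x) = R s (x - c) + c + t` about the organ centroid `c`. Under the
backward-warping convention (`T(x) = x + u(x)`, output at `x` samples the
input at `T(x)`), the exact field realizing `A` is `u(x) = A^{-1}(x) - x`.
To localize the motion to the organ, that displacement is weighted by

```
w(y) = exp(-d(y)^2 / (2 * influenceDecay^2)),   y = A^{-1}(x),
```

where `d` is the Euclidean distance from `y` to the organ mask (zero
inside). Evaluating the weight at the *sampled* position `y` rather than at
`x` makes the motion exact wherever the sampled point falls in or near the
organ — which is what lets a pure translation move the warped label
centroid by the drawn amount to within voxel quantization, and a pure
scale change the label volume like `s^3`. The weighted field is finally
Gaussian-smoothed (`fieldSmoothing`, mm) so that abrupt changes of the
distance map cannot inject kinks.

The "radial bending" sometimes used to describe per-structure deformation
is implemented as the rotation component of the similarity motion; a
dedicated bending operator is deliberately out of scope.

### Composition and its convention

Fields are displacements; composition follows the sequential-warp contract

```
warpImage(warpImage(I, u1), u2) == warpImage(I, composeFields(u1, u2))
```

realized as `u(x) = u2(x) + u1(x + u2(x))` with the off-grid lookup of
`u1` linearly interpolated and edge-clamped. Composing with a zero field
returns the other operand bit-exactly. In `simulateSession` the
accumulated field is updated as `composeFields(u_k, u_acc)`, which is
precisely the iterative sampling order written above.

The organ iteration order affects the composed field. The default is
ascending label code; the order used is returned with every simulation so
runs are auditable.

### Defaults and what they mean

| parameter | default | unit | role |
|---|---|---|---|
| `maxDisplacementMm` | 8 | mm | per-axis translation bound |
| `maxExpansion` / `maxShrinkage` | 0.15 / 0.15 | — | isotropic scale bounds |
| `maxRotationDeg` | 8 | deg | Euler-angle bound about the centroid |
| `influenceDecayMm` | 15 | mm | Gaussian decay of the organ's influence |
| `fieldSmoothingMm` | 4 | mm | Gaussian smoothing of the dense field |

The motion bounds are chosen as visually plausible inter-fraction abdominal
change at phantom scale; no published numeric bounds exist for this
augmentation, so they are free parameters of the toolkit, overridable per
run. The decay scale is of the order of an organ radius so neighbouring
anatomy is dragged along gently; the smoothing scale is a compromise
between field regularity and fidelity of the similarity motion (larger
values blunt the motion near the organ boundary).

### Folding

The composed field is not guaranteed diffeomorphic. `jacobianMin()`
computes the minimum determinant of the spatial Jacobian of `T(x) = x +
u(x)` by central differences in physical units; values at or below zero
indicate folding and produce a warning (or an error under
`strict = TRUE` in `simulateSession`). Plausibility, not diffeomorphism,
is the design goal; under the default bounds the minimum determinant on
the bundled phantom stays around 0.4–0.6.

## MR acquisition-variability augmentations

Three intensity-only augmentations emulate between-session acquisition
variability; none touches geometry or labels:

* **Histogram shift** — a monotone piecewise-linear remapping whose
  interior control points are uniformly perturbed (up to
  `histShiftStrength` of the intensity range) and re-sorted; the endpoints
  stay pinned, so the output range equals the input range and voxel rank
  order is preserved.
* **Intensity scaling** — one global factor drawn uniformly from
  `intensityScaleRange`.
* **Gibbs ringing** — k-space truncation: the fraction `alpha` of the
  highest spatial frequencies per axis (a centered box mask) is zeroed;
  `alpha = 0` reproduces the input to floating round-off and the DC
  component is always kept.

The application order is fixed (histogram → scale → Gibbs), each gated by
its own apply-probability (default 1), and logged on the result. No
published parameter ranges exist for these augmentations either; the
defaults (strength 0.1, scale 0.9–1.1, alpha 0–0.4) are deliberately mild.

## Conditioning and cohort arrangement

For a patient with sessions `1..k`, every ordered pair `(m, n)`, `m != n`,
yields conditioning inputs, so `k(k-1)` pairs per patient
(`scope = "all_ordered"`). Deployment typically conditions everything on
the first session (`scope = "first_to_rest"`, `k-1` pairs); both scopes
are provided because both usages occur in practice. Each case is the
concatenation `[I_m, L_{m,o}, I_n]` for one organ `o`; organs absent from
a source label map (e.g. a missing kidney) are skipped with a notice, so
the case count is the number of pairs times the organs present per source.
Cross-patient pairs are never formed.

Source sessions whose geometry differs from the target are resampled onto
the target grid (image linear, labels nearest-neighbour) before writing,
so all channels of a case share one grid. Folds are leave-one-out at the
patient level: each fold holds one validation patient; all sessions of a
patient stay together. The on-disk layout uses channel-suffix naming
(`_0000`/`_0001`/`_0002`), a `dataset.json` descriptor and a
`manifest.csv`, and round-trips losslessly.

The multi-prior ensembling utility (`ensembleVote`) uses majority voting
with ties counted as foreground; with two sources this reduces to the
union. This simple rule is a declared choice, not a published algorithm.

## Metrics and their conventions

* **DSC** `2|A n B| / (|A| + |B|)`; two empty masks score 1, exactly one
  empty scores 0.
* **Surface distances** — surfaces are a mask minus its 6-connected
  erosion; distances are voxel-center to voxel-center in mm via an exact
  Euclidean distance transform. ASD and HD95 are the mean and the
  95th percentile (linear interpolation between order statistics) of the
  *pooled bidirectional* distance multiset — symmetric by construction.
  Directionality conventions differ across the literature; the pooled
  convention is recorded in each report's header attribute.
* **DVH / dose-at-volume** — `DVH(d)` is the fraction of the structure
  receiving at least `d`. `D_v` sorts voxel doses descending and
  interpolates linearly on the cumulative-volume axis with voxel centers
  at `(k - 1/2)` voxel volumes; this makes D50% on a half/half two-level
  structure the interpolated median, and uniform dose gives exactly that
  dose for every request. Requests larger than the structure raise an
  error.
* **dPD** `|method - ground truth| / PD x 100`. Absolute value by default
  (published tables print non-negative values); a signed variant is
  available behind a flag.
* **mDice** — Dice with per-voxel weight `w(x) = ||grad dose(x)||`
  (central differences, Gy/mm). Under a spatially constant gradient
  magnitude it reduces exactly to DSC (this limit is a contract test); if
  the total weight over the union vanishes the unweighted DSC is returned
  with a notice. The precise published formula behind "dose gradient as a
  weighting factor" is not printed anywhere accessible, so this
  gradient-magnitude weighting is the declared interpretation.
* **Empty predictions** — an organ present in the ground truth but empty
  in the prediction is reported with DSC 0 and flagged undefined
  distances, never dropped and never fatal, so cohort evaluation always
  completes.

## The phantom: what it emulates, what it does not

The generator produces a stylized abdomen on a default 64 x 64 x 48 grid
at 2 mm isotropic spacing: liver right-superior, kidneys
posterior-lateral, spleen left-posterior, stomach left-anterior, spinal
canal posterior-midline, duodenum as a C-shaped tube adjacent to the
stomach, small and large bowel as anterior tube loops. Label codes are
1..9 in the fixed organ order; a single-kidney variant omits the right
kidney code. Images are per-organ mean intensities plus additive Gaussian
noise and an optional smooth multiplicative bias field (mimicking MR
shading that clinical preprocessing would remove). The dose phantom is an
isotropic Gaussian peak (1.1 x prescription at the target, 12 mm falloff)
centered by default on the duodenum, emulating a pancreatic target
abutting it.

What the phantom does *not* emulate: true organ shapes and contact
mechanics, MR pulse-sequence contrast, receive-coil profiles, peristalsis,
or realistic dose distributions from a treatment planning system. Passing
tests on phantoms therefore demonstrate the *correctness of the
operations* (warping, composition, counting, metric arithmetic), not
clinical segmentation accuracy. Intensity means and noise levels are free
parameters, not calibrated to any scanner.

## Numerical choices and degenerate inputs

* Out-of-domain sampling clamps to the nearest edge value — no background
  bleeding into the body.
* Nearest-neighbour sampling rounds half away from zero; a translation at
  an exact half-voxel multiple therefore lands on one of the two
  neighbouring voxel alignments (at most half-voxel centroid error).
* Identity draws short-circuit to an exactly zero field; zero fields make
  warps bit-exact identities, which is what makes the zero-bound
  simulation an exact fixed point.
* An organ that vanishes under the accumulated field is skipped with a
  warning (its draw is still consumed to keep streams aligned).
* Degenerate inputs error early with the offending name: empty masks for
  field generation or surface distances, constant images for
  normalization, non-positive prescriptions, geometry mismatches.
* All randomness flows through R's global RNG; every user-facing entry
  point takes an optional seed evaluated without disturbing the caller's
  stream, and the command-line tool derives per-stage child seeds
  deterministically from one root seed.

## Problem sizes used by the test-suite

The suite exercises phantoms between 24³ and the default 64 x 64 x 48
grid, 200-case randomized oracles for dose-at-volume, and 10^4-draw
Monte-Carlo checks of the uniform sampling law; the end-to-end pipeline
test builds two three-patient cohorts at 32 x 32 x 24 and checks
byte-identical reruns. These sizes are the package's own choices: large
enough that all nine organs are resolved, small enough that the whole
suite runs in a few minutes. One caveat worth knowing: at very coarse
grids (≲ 24³) the thin tubular organs are only 1–2 voxels across, and a
full-bound deformation can erase them — organ survival is a
resolution-dependent property of the stylized phantom, not of the method.

## Known limitations

* Fields are plausible but not guaranteed invertible; use
  `strict = TRUE` to reject folding fields.
* The similarity-motion `phi` cannot produce local bending or sliding;
  organ interiors move rigidly up to the influence decay.
* Nearest-neighbour label warping quantizes small displacements at coarse
  spacing.
* The segmentation network itself (training, inference) is out of scope;
  predicted labels enter only as inputs to the evaluation module.
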