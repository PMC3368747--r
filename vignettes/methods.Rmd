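---
title: "Methods: normalised volumetric SPECT/CT analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalised volumetric SPECT/CT analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what validation on synthetic phantoms does and does not
establish.

## The measurement model

The input is a co-registered pair of 3D volumes sharing one world
coordinate system (the DICOM patient/LPS convention, millimetres): a CT
volume in Hounsfield-like units and a SPECT volume of non-negative tracer
counts. Co-registration is assumed, not estimated — it is what a hybrid
scanner provides. The two grids may differ in spacing and extent; world
coordinates are their only common frame, and every cross-volume operation
goes through each volume's 4×4 affine (0-based voxel index → world mm,
index-centre convention).

Raw SPECT counts are not comparable between patients (overall uptake
varies more than tenfold) nor between scans (the patient lies differently
each time). The pipeline therefore normalises three things:

**Position.** An anatomical frame is an origin plus a right-handed
orthonormal triad (ML, AP, PROX) in world coordinates. The femoral frame
takes the knee centre (midpoint of the transepicondylar line) as origin,
the mechanical axis from knee centre to femoral head centre as PROX, and
completes the triad by cross products with the transepicondylar direction.
The tibial frame reuses the femoral ML axis (hinge-knee assumption) with
its long axis from the talus centre to the knee centre. All downstream
coordinates (region boxes, centroids, meshes) can be expressed in these
frames, making measurements independent of scanner pose — the package's
pose-equivariance tests state this formally: rigidly transforming all
landmarks transforms frames identically to within 1e-9.

**Intensity.** A reference region — an axis-aligned box in the femoral
frame spanning the mid-shaft, a site mechanically and metabolically remote
from the joint surfaces — supplies a count distribution with mean
`μ_ref` and standard deviation `σ_ref`. Three normalisation models are
implemented and none is declared canonical, because which correlates best
with clinical outcome is an open question: `scale_by_mean` (v/μ_ref),
`offset_by_mean` (v − μ_ref), and `zscore` ((v − μ_ref)/σ_ref). Thresholds
are `k·μ_ref` or `μ_ref + n·σ_ref`, returned in raw counts so they can be
applied directly to the volume. The fraction-of-maximum threshold
(`max_fraction_threshold()`) is also provided, precisely because its
failure mode — dependence on the single hottest voxel and on overall
uptake — motivates reference-region normalisation.

**Size.** With a calibrated threshold, segmentation reduces to
thresholding inside a rectangular region of interest; hotspot size is then
a voxel count and a physical volume, comparable across patients because
the threshold is.

Hotspot and reference distributions are compared with Welch's
unequal-variance two-sample *t* (Welch–Satterthwaite degrees of freedom,
two-sided p). Welch rather than pooled: a hotspot's variance has no reason
to match the reference region's. The statistic is computed from summary
statistics (n, mean, sd), since those are the module contract; the test
suite cross-checks it against `stats::t.test` on raw samples.

## Parameters, defaults, and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Reference region | PROX ∈ [150, 200], ML/AP ∈ [−25, 25], femoral frame | mm | mid-shaft for a ~350 mm femur, clear of both joint surfaces; spans the full bone cross-section |
| Threshold k (clinical) | 3 × μ_ref | – | marks clinically relevant uptake above background |
| Threshold k (core) | 4 × μ_ref | – | focuses on the hotspot core when reporting its mean |
| Bone iso level | +150 | HU | above soft tissue (~0–100 HU), below trabecular bone |
| CT fill value | −1024 | HU | reads as air outside the grid |
| SPECT fill value | 0 | counts | reads as "no counts" |
| Degeneracy: point separation | 1 | mm | far below anatomical scale, far above numerical noise |
| Degeneracy: axis angle | 1 | degree | same reasoning |
| Histogram bins | 64 over [0, global max] | – | shared edges make global/saved/local histograms directly comparable |

## Numerical choices

* **Voxel membership** in a region is by voxel *centre* in the half-open
  box `[min, max)` — adjacent boxes can never double count a voxel, and
  membership is exactly reproducible by a per-voxel loop (the suite checks
  bit-equality against such an oracle on 100 random volumes).
* **Thresholding is inclusive** (`≥`), fixing boundary behaviour
  deterministically.
* **Interpolation** is trilinear for both modalities when resampling into
  a frame; nearest-neighbour is available for masks. Resampling a linear
  field through a rotated frame is exact up to rounding, which the suite
  exploits as an oracle.
* **Sample SD** uses the n−1 denominator throughout.
* **Sphere fit** for the femoral head: algebraic linear least squares
  (singular for coplanar points, which is detected and rejected via the
  SVD of the centred points) followed by Gauss–Newton refinement of
  orthogonal-distance residuals (at most 10 steps, stop at 1e-10). The
  manual construction — intersecting head diameters in three planes — is
  not reproducible in code; direct input of the centre remains supported.
* **Axis sign conventions**: ML points medial→lateral, PROX
  distal→proximal, AP completes the right-handed triad; AP and ML are
  flipped jointly when needed so the convention holds for either limb
  side. The anatomical direction of +AP (anterior vs posterior in world
  space) is self-consistent but not validated against surgical convention.
* **Realignment angles**: total angle from the trace of the relative
  rotation, axial component as the signed angle of the ML axis's image
  projected into the transverse plane. Verified to 1e-9 against a
  quaternion oracle and against Rodrigues-constructed rotations.
* **Isosurfaces** use marching tetrahedra on the Kuhn 6-tetrahedron cube
  decomposition with linear interpolation along crossing edges. This
  variant is crack-free (shared cube faces are split identically from both
  sides) and deterministic; it is pinned as part of the package's
  reproducibility contract. Triangles are oriented outward (from the
  ≥ level side), so the divergence-theorem volume is signed correctly. On
  an analytic sphere of radius 20 mm at 1 mm pitch the suite requires area
  and enclosed volume within 2% of 4πr² and (4/3)πr³; the script
  `scripts/acceptance.R` reports the errors actually measured.
* **Connected components** use 26-connectivity with deterministic label
  order (descending size, ties by smallest linear index), checked against
  an independent flood fill.
* **Degenerate inputs** error early with specific messages: coincident
  epicondyles, head centre on the transepicondylar line, coplanar
  head-surface points, talus at the knee centre, empty region/volume
  intersections, non-orthonormal frame axes, non-invertible affines.
  An empty hotspot mask is not an error: metrics return count 0 and
  flagged-undefined intensity fields.

## File formats

NIfTI (via RNifti, sform code 2; the internal LPS affine is sign-flipped
to RAS on write and back on read, an exact operation) and NRRD (text
header written at full double precision, gzip payload; `space:
left-posterior-superior`) for volumes; DICOM for reading scanner exports,
scoped to single-frame-per-file uncompressed explicit-VR little-endian
series — slices are ordered by the projection of ImagePositionPatient onto
the slice normal rather than InstanceNumber, which survives shuffled
files. Note the asymmetry in round-trip guarantees: NRRD affines
round-trip exactly, NIfTI sforms are float32 on disk so round-trip to
~1e-7 relative precision. Landmarks, frames, statistics and run metadata
are JSON; meshes are ASCII PLY/OBJ/STL; configs are YAML (canonical) with
JSON accepted.

## The phantom: what it emulates, and what it does not

`make_phantom()` builds a knee scene in anatomical coordinates — femoral
shaft cylinder plus spherical head, two condylar spheres carrying the
epicondyle landmarks on their surfaces, tibial cylinder plus talus sphere,
all inside a soft-tissue cylinder — poses it rigidly (arbitrary rotation +
translation), and voxelises CT (bone +700 HU, soft tissue 0, air −1024)
and SPECT (background `b` counts in tissue, `b·r` inside each ellipsoidal
hotspot, 0 in air) on independent grids. Noise is Poisson per voxel
(SPECT is count data); optional Gaussian CT noise is off by default.
Hotspot edges are hard — no point-spread blur — so every downstream
quantity has a closed-form truth. All randomness flows through one seed;
identical specs are bit-identical, and the generator restores the global
RNG state.

Default conditions: background 100 counts, hotspot ratios ≥ 1 (the
two-patient scenario uses 4.5 for P1 and 5.5 for P2, with P2 larger, given
a secondary tibiofemoral lobe, and posed at 8° axial rotation — comfortably
beyond the 5° realignment threshold regarded as clinically meaningful),
CT at 2 mm, SPECT at 3 mm, femur ~350 mm. The scenario uses a left limb so
that the neutral pose's anatomical frame coincides with the scanner frame,
making the reported realignment angle exactly the injected pose. Tests
exercising the full pipeline use a shortened limb (200 mm femur, 3 mm
grids) so a run takes a fraction of a second; the two-patient acceptance
checks use the full-size defaults.

What the phantom deliberately does not model: realistic bone shape,
SPECT's 3–10 mm point-spread function (an optional Gaussian PSF could be
added for robustness studies; segmentation near the resolution limit will
behave worse on real data than on hard-edged phantoms), attenuation and
scatter, and reconstruction artefacts. Passing the suite therefore shows
the *analysis* is correct and invariant as claimed — not that its
clinical sensitivity/specificity on real scans matches the phantom's.

## Validation summary

The acceptance suite (in `tests/testthat/test-acceptance.R`) checks, on
the generated phantoms and random geometry: orthonormality and pose
equivariance of 1000 random landmark-derived frames (1e-9); exact recovery
of injected rotations and agreement with a quaternion oracle (1e-9);
bit-equality of region statistics and masks with brute-force loops;
invariance of normalised ratios, counts and *t* statistics under global
intensity rescaling by 0.1–25× (1e-9); exact recovery of a ratio-4 hotspot
without noise and unbiased recovery under Poisson noise (within 3 standard
errors from counting statistics over 20 seeds); pose invariance of counts
(5%) and centroids (one voxel) for a rotated-and-translated patient;
the two-patient contrast (P2 larger, hotter, ≥5° realigned) through the
complete file-based pipeline; and the sphere geometry above.

## Known limitations

* Landmarks are file inputs; no automatic detection from CT.
* Frames are defined for the knee (hip and ankle landmarks serve only as
  axis endpoints).
* DICOM support is read-oriented and deliberately narrow (no multi-frame
  or compressed transfer syntaxes).
* No SUV-style quantification: that needs injected dose and patient
  weight, outside this method's inputs.
* No partial-volume correction; mean ratios of small hotspots on real
  (blurred) data will underestimate their true contrast.
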