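---
title: "Lesion tracking and response assessment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion tracking and response assessment: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotrackr)
```

`neurotrackr` turns per-timepoint 3D segmentation masks of enhancing brain
metastases into per-lesion longitudinal measurements and treatment-response
labels. This vignette records the model behind each stage, the parameters
that matter, and the design decisions taken where the underlying clinical
conventions are genuinely underspecified. It states no empirical result
that the test suite does not itself compute.

## Input model and geometry conventions

The unit of input is a `label_volume`: a 3D integer lattice on an
`image_grid` (shape in voxels, spacing in mm/voxel, 4×4 voxel-to-mm
affine). Zero is background; any positive value is enhancing tumor — input
labels are flattened to a single tissue class before componentization,
because the masks represent one biological compartment. Necrotic-core or
edema sub-compartments are out of scope.

Two conventions are enforced rather than inferred:

* **The axial plane is spanned by the first two voxel axes**; the third
  axis is the slice index. All diameter measurements are in-plane and use
  `spacing[1:2]`; through-plane extent never enters a diameter.
* **Volumes are assumed co-registered through their stored affines.**
  `resample_labels()` performs nearest-neighbor pull-back resampling onto a
  reference grid (labels are categorical, so no interpolation or
  partial-volume handling; the output label set is always a subset of the
  input's). Rigid/deformable registration proper is a pipeline stage that
  belongs to the imaging platform, not this package.

NIfTI-1 reading/writing is implemented directly (348-byte header,
sform/qform affines, gzip transparently). Files with non-integral voxel
values, 4D shape or intensity rescaling are rejected: they are not label
volumes, and silently coercing them would corrupt every downstream count.

## Lesion extraction

`extract_lesions()` decomposes foreground into 3D connected components.
The default adjacency is 26 (vertex-touching voxels merge); anti-aliased
or re-sliced mask boundaries often leave single-voxel diagonal bridges,
and splitting one tumor across such a bridge is the worse failure mode.
Connectivity is configurable (6/18/26) for sensitivity analysis. Two truly
distinct metastases that abut voxel-to-voxel cannot be separated by any
connectivity rule and are treated as one component — a documented
limitation, not a parameter.

There is no minimum-size filter by default (`min_voxels = 1`):
sub-5 mm lesions are a first-class object of study here, not noise.

## DMAX: maximum orthogonal diameters

For each axial slice a lesion crosses, `slice_diameters()` computes:

* **longest diameter** — the maximum Euclidean distance between any two
  voxel *centers* of the cross-section, in mm, honoring anisotropic
  in-plane spacing. The farthest pair is found on the convex hull
  (equivalent to the O(n²) scan, which the test suite uses as an
  independent oracle on random blobs).
* **perpendicular diameter** — the caliper width (projection extent) of
  the cross-section orthogonal to the longest segment.

`dmax()` evaluates every slice and reports the one maximizing the longest
diameter (ties: lowest slice).

Numerical choices, each made for determinism on a discrete grid:

* **Center-to-center, not edge-to-edge.** A single-voxel lesion measures
  0 mm. The alternative (adding one voxel of "width") is equally
  defensible clinically but makes the ≥5 mm stratification depend on an
  arbitrary sub-voxel convention; center distances are exactly
  reproducible and oracle-checkable. Consumers should remember measured
  diameters run ~one voxel below the physical object size.
* **Caliper width rather than "longest chord within ±ε of
  perpendicular".** A perpendicular *chord* may not exist on a discrete
  contour; the projection extent always does, and matches clinical
  bidimensional practice closely. The reported perpendicular "endpoints"
  are the extreme caliper pair, which lie in the lesion but are not
  themselves an orthogonal segment.
* **Ties.** If several voxel pairs tie for longest, the pair whose
  orthogonal caliper width is largest is used (this makes the measurement
  invariant under 90° rotations that permute tied diagonals), with
  remaining ties broken by the lexicographically smallest endpoint pair.

## Longitudinal matching and tracks

`match_lesions()` solves a global one-to-one assignment between two
studies' lesion sets, maximizing total voxel overlap with centroid
distance as tie-break; pairs with zero overlap are admissible only within
a `gate_mm` centroid gate (default 10 mm). The gate exists for small
lesions whose registered footprints barely miss; overlap dominates
whenever it exists because the masks are co-registered. The solver is an
O(n³) Jonker–Volgenant implementation (no assignment solver exists among
the package's dependencies), verified in the tests against exhaustive
permutation search — a greedy matcher would be order-dependent and can be
globally suboptimal.

`build_tracks()` chains matchings across the series. A current-study
lesion with no match opens a new track; a track with no match records an
absent timepoint but remains eligible to re-match later **via its last
non-absent footprint**, so a lesion that shrinks below mask resolution and
regrows (a pseudo-progression pattern) stays one anatomic object. Merges
and splits of confluent lesions resolve to the single best assignment;
the leftovers become absence or new tracks.

## Per-lesion response classification

`classify_track()` applies RANO-BM-style target-lesion logic collapsed to
a single lesion, with thresholds in `response_config()`:

| parameter | default | meaning |
|---|---|---|
| `pd_threshold_pct` | +20 | growth over the *nadir* defining PD |
| `pr_threshold_pct` | −30 | change from *baseline* defining PR |
| `endpoint_months` | 12 | observation endpoint after the first study |

Baseline is the longest diameter at first appearance; the nadir at
timepoint *t* is the minimum over present timepoints strictly before *t*.
Rule order at each follow-up: absent/zero-diameter → **CR**; reappearance
after any absence → **PD** (CR is reversible by convention); growth from a
zero-diameter nadir → **PD**; pct-over-nadir > 20 → **PD**;
pct-from-baseline ≤ −30 → **PR**; else **SD**. First timepoints are
**NA** (baseline tracks) or **NEW** (tracks appearing later).

Deliberate deviations from patient-level RANO-BM, both configurable:
no sum-of-diameters (the package is per-lesion by design), and no ≥5 mm
absolute-change requirement — the populations of interest here include
lesions below 5 mm, for which an absolute gate would make PD/PR
unreachable. Percent-based rules also make every label invariant under a
common rescaling of a track's diameters (a property test).

`endpoint_response()` returns the label at the latest study within
`endpoint_months` of the series' first study — months are converted as
months/12 × 365.25 days, since calendar months are ambiguous — or the last
available study when follow-up is shorter; a track with no classified
follow-up inside the window is NA.

## Detection, overlap and agreement statistics

`match_detections()` scores a predicted lesion set against a reference by
the same optimal-assignment machinery; a true positive requires ≥1 shared
voxel (the most permissive overlap criterion — configurable, but any
stricter default would silently redefine published-style counts). Strata
are split at 5 mm, inclusive (≥5 mm is "measurable"); TP/FN follow the
*reference* lesion's diameter, FP their own, since a false positive has no
reference size. `dice_patient()` pools all of a patient's studies before
computing Dice, giving one number per patient; per-study medians are a
different statistic and deliberately not the default.

`paired_agreement()` fixes the intraclass correlation to ICC(2,1) —
two-way random effects, absolute agreement, single rater — the standard
form for two interchangeable human readers; it is computed from the
classical mean-squares decomposition and checked against an `aov()`
oracle in the tests. Bland–Altman limits use mean ± 1.96·SD without
small-sample bias correction. Consensus construction averages diameters of
lesions both readers found and defers single-reader findings to an
adjudication table: confirmed findings enter with adjudicated diameters,
unconfirmed ones are flagged and excluded.

## The phantom: what it emulates, what it does not

`generate_phantom()` renders seeded longitudinal series of digital
ellipsoids with known centers, per-timepoint equatorial diameters and
trajectory-implied response labels. Its defaults encode a realistic
stated world rather than tunable knobs: 3–8 studies per patient at ~90-day
intervals (about a year of quarterly follow-up), baseline diameters drawn
from 3–15 mm (spanning the sub-5 mm stratum through typical ~9 mm
lesions), 1 mm in-plane and 1 mm slices. Growth trajectories compound
25–40% per study and shrinkage 31–60% — rates that place progressors
clearly beyond the +20% PD threshold and responders beyond −30% PR, as a
generator of unambiguous ground truth should. Lesion centers are placed
with at least twice the larger of each pair's maximum diameters between
them, so lesions never become confluent at any timepoint; infeasible
requests fail loudly after 1000 attempts rather than degrading the truth.

`simulate_reader()` detects each lesion with probability
`plogis((d − midpoint)/slope)` and adds Gaussian noise to detected
diameters — small lesions are missed more often, which is the essential
reader behavior. `simulate_segmenter()` drops lesions with a
size-dependent probability, jitters kept radii by up to a configurable
voxel count, and adds Poisson-distributed small spurious blobs.

What the phantom does **not** emulate: irregular/lobulated lesion shapes
(ellipsoids give analytic diameter truth; a union-of-ellipsoids mode would
be the extension point), registration error between studies, MR intensity
or artifact simulation, and truly confluent metastases. A green
end-to-end test therefore establishes that the measurement, matching and
classification machinery is correct on well-separated convex lesions — it
does not certify performance on confluent or highly irregular disease,
nor quantify robustness to misregistration.

Because rendering is discrete, a digital sphere of diameter *d* measures
within about one voxel of *d* center-to-center; end-to-end label-recovery
tests use 9 mm baselines, where a one-voxel error (~11%) cannot move a
+30% grower below the +20% PD threshold or a −40% shrinker above the −30%
PR threshold.

## Degenerate inputs and numerical corners

* Empty masks extract to an empty lesion list; empty tracks are an error.
* A lesion shrinking to a single voxel measures 0 mm: treated as CR, and
  any regrowth as PD (growth from a zero nadir has undefined percent
  change; calling it anything but progression would hide a reappearing
  tumor).
* Undefined metric ratios (no predictions, no reference lesions) are NaN
  with a warning, never silently 0 or 1; Dice of two empty pooled masks is
  an error, not 1.
* All randomness (phantom, reader, segmenter) sits behind explicit seeds;
  identical seeds give bit-identical volumes and outputs, and run
  manifests echo the configuration for exact re-runs.

## Known limitations

Touching metastases merge; measurement is 2D axial only (no 3D maximum
diameter or volume-based response rules); the response rules are a
per-lesion adaptation — nadir-referenced PD and baseline-referenced PR —
of criteria whose "modified" clinical variants differ between sites;
and masks are trusted as given: no intensity information is consulted.
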