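---
title: "Measuring continuously erupting incisors from micro-CT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring continuously erupting incisors from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rodent incisors (and the whole rabbit dentition) are elodont: they erupt
continuously and are worn back by gnawing. Because the two hemi-mandibles
are joined by a non-bony symphysis, an animal can unload one side; a
unilateral mandible defect that degrades load-bearing on that side shows up
as ipsilateral neglect — most visibly, a longer erupted incisor crown.
Quantifying this requires (i) co-registering longitudinal micro-CT scans of
the same animal, (ii) placing every scan in a common anatomical frame, and
(iii) reproducible morphometric operators for the incisor, all validated
well enough that a few tenths of a millimetre of asymmetry is
interpretable.

mandimorph implements this pipeline and, because the underlying animal
scans are not publicly deposited, ships a voxel phantom generator whose
geometry is known in closed form. Every stage of the pipeline is tested
against those analytic ground truths; the statistical procedures are
validated by simulation.

## The measurement frame

The horizontal reference is the molar occlusal plane: the total
least-squares plane through the buccal cusp tips of the cheek teeth
(`fit_occlusal_plane()`), oriented so its normal points dorsally. The
volume is rotated so this plane becomes horizontal
(`reorient_to_occlusal()`). Follow-up scans are first rigidly co-registered
to the animal's baseline scan (`register_rigid()`); the registration and
the reorientation are composed into a single transform so each volume is
resampled exactly once — repeated linear interpolation visibly smears the
partial-volume edge ramps the landmark operators rely on.

## Rigid registration

Similarity is mutual information over the joint intensity histogram of all
overlapping voxels (no landmarks), with min–max intensity binning (64 bins
by default) and linear interpolation of the moving volume. Optimization is
a Nelder–Mead simplex over the six rigid parameters (intrinsic x–y–z
angles about the fixed-volume centroid, plus translations), with
convergence declared when the simplex size falls below 1e-3 normalized
units (1 unit = 1 degree = 1 mm) or after 500 iterations.

Three numerical choices matter and are worth stating plainly:

* **The optimized similarity is normalized MI.** Plain MI computed over
  the voxel overlap is not pose-invariant at the volume margins: shifting
  background voxels out of the overlap raises the entropy of what remains,
  so the MI maximum sits a fraction of a degree away from the true pose
  even for a volume registered to itself. The optimizer therefore
  maximizes the overlap-invariant form (H(fixed)+H(moving))/H(joint)
  (Studholme's NMI); the reported `mi` is plain MI in bits evaluated at
  the returned transform, and `mutual_information()` itself implements the
  textbook definition.
* **Simplex restarts.** A single Nelder–Mead run routinely collapses a few
  tenths of a degree short of the peak in 6 dimensions. The optimizer
  re-spans a fresh simplex (halved steps) at the incumbent until the gain
  drops below 1e-4 (4 rounds maximum). This is deterministic; the optional
  multi-start (`starts`) adds seeded jittered initializations for poses
  near the edge of the capture range (documented as roughly ±10° / ±5 mm).
* **Bins under noise.** With heavy noise (10% of the dynamic range) the
  64-bin histogram is undersampled and the MI surface gets rough; 32 bins
  restores reliable recovery. The default stays at 64; noisy acquisitions
  should lower `bins`.

On noise-free phantoms, applied poses (≤5°, ≤3 mm) are recovered within
0.12° / 0.11 mm at 0.3 mm voxels; with 10% noise and 32 bins, within
0.3° / 0.1 mm (see `test-acceptance.R`, criterion 3).

## Incisor morphometry

All incisor metrics are taken in the mid-sagittal slice of the incisor:
the slice through the centroid of its connected tooth component, normal to
the left–right axis. The outline is traced (Moore neighbour tracing), each
contour point is refined to sub-voxel precision by locating the local
half-maximum crossing along the intensity gradient, and the closed contour
is lightly smoothed (3-point moving average). Two refinement details
carry most of the accuracy:

* the crossing is computed on the *raw* slice (the blurred copy is used
  only for gradient directions) — a blurred ramp widens and biases the
  contour inward by most of a voxel;
* the crossing level is the local half-maximum between the two phases, so
  tooth–air and tooth–bone interfaces both land on the true surface
  (a fixed threshold is only the half-maximum of one of them).

Landmarks are operators, because anatomy alone does not define them on a
grid:

* **tip** — the most dorsal contour point, refined to the intersection of
  the occlusal-facet line with the circle fitted to the labial arc;
* **gnaw ridge** — the split point that minimizes the combined residual of
  a straight line (the facet) plus a circle (the lingual arc) fitted to
  the contour walk leaving the tip lingually. This split fit is
  scale-free; a naive "maximal straight run" detector overshoots the
  corner by millimetres at coarse voxels because a shallow arc stays
  within any fixed tolerance of a line over a long span;
* **alveolar edges** (labial and lingual) — the contour points nearest the
  most dorsal air/bone/tooth triple junction on that side: air pixels
  close to both solid bone and the incisor. "Solid bone" is the bone-band
  mask eroded twice against air, because partial-volume shells around the
  free crown fall in the bone intensity band (1–2 px wide after
  resampling) and would otherwise fake bone contact along the whole
  crown. A simpler "most dorsal bone voxel touching the labial contour"
  rule fails on curved roots, whose embedded outer arc rises dorsally
  again away from the true margin.

Path lengths are polyline arc lengths between landmarks (labial: alveolar
edge→tip; occlusal: gnaw ridge→tip; lingual: gnaw ridge→lingual edge). The
occlusal inclination angle is the total-least-squares line through the
facet points (trimming 10% at each end, where corner rounding lives)
against the horizontal, signed positive when the tip is dorsal to the
ridge. Cheek-tooth heights run from the top of the de-shelled alveolar
bone in the tooth's footprint to its highest buccal cusp voxel.

On noise-free phantoms the path lengths agree with the analytic truths
within 2 voxel edge-lengths and the angle within 1° at 0.2, 0.1 and
0.05 mm voxels, with errors shrinking as the voxel size halves.

## The phantom: a stated world

The phantom is two mirrored hemi-mandibles (body box, taller posterior
ramus, molar row, incisor) separated by a non-bony symphysis gap, so the
sides separate by connected-component labelling. The incisor is a tube of
radius `r_tube` around a planar circular-arc centerline, cut by a planar
bevel; the bevel edge on the lingual surface is the gnaw ridge. The
erupted crown is the part rostral to the flat anterior face of the body
(the alveolus plane). All landmark positions, path lengths and the
occlusal angle follow in closed form, and `GroundTruth` is computed from
the specification, never from the voxelization. Intensities are background
0, bone 1000, teeth 1400 a.u., with a one-voxel partial-volume ramp at
surfaces (the CT-like edge profile that makes sub-voxel refinement
honest); segmentation thresholds are 500 (bone) and 1200 (teeth).

Preset scales follow the study animals: rat voxels 0.046 mm, rabbit
0.09 mm (0.18 mm survey mode); rat labial crown length 12.66 mm — the
crown parameter *is* the labial path length, so cohort-level labial
differences pass through exactly — and rabbit 11.5 mm; rabbit cheek-tooth
heights 5.3/3.4/4.1/3.0 mm for teeth #2–#5. Two deliberate deviations
from a literal reading of the source numbers:

* The three rat baseline path lengths (12.66 / 1.67 / 5.85 mm) cannot
  coexist on an arc-plus-straight-bevel geometry: with labial 12.66 and
  lingual 1.67 the straight ridge-to-tip chord would be ~9 mm, not 5.85.
  The phantom matches the labial scale exactly and lets lingual (~7.9 mm)
  and occlusal (~3.1 mm) follow from the geometry; the printed means live
  in the parametric cohort simulator, which is where cohort-level
  statistics are validated.
* The rabbit cheek-tooth height table differs left vs right; the phantom
  is mirror-symmetric by construction (that symmetry is itself an
  invariant under test), so both sides carry the left-column heights.
  Cusp tips are coplanar — they define the occlusal plane — and the
  per-tooth alveolar collar height varies instead.

Defect modes are geometric only (no healing biology): CSD (rat 5 mm
sphere, rabbit 8×8 mm through-cylinder) and ID (rat 5×9 mm, rabbit 23 mm
ventral–dorsal, dorsal strut preserved) in the anterior ramus, CRO with a
1 mm or 3 mm gap separating the tooth-bearing body from the ramus (the
defect-side bone then falls into two components), and the rabbit 10×12 mm
body defect under the cheek teeth. Pose perturbations model repositioning
between longitudinal scans and are capped at ±10° / ±5 mm — the
registration capture range is documented, not unlimited.

What the phantom does **not** emulate: reconstruction physics (beam
hardening, scatter, ring artifacts), anatomical texture (trabecular bone,
enamel/dentin contrast), inter-animal shape variation, or tissue change
over time. A green phantom test therefore establishes that the operators
are correct and stable on CT-like data of known geometry — not that the
pipeline segments arbitrary real scans; on real data the bone/tooth
thresholds and component classification are the user's responsibility.

## The cohort simulator

`simulate_cohort()` draws per-animal values as animal mean (normal,
between-animal SD) ± half a left–right difference (normal, difference SD,
redrawn per timepoint), with a fixed additive shift on the defect side at
post-baseline timepoints. Defaults are the printed baseline cohorts: rat
labial 12.66 ± 0.59 mm, lingual 1.67 ± 0.25 mm, occlusal 5.85 ± 0.51 mm;
rabbit labial 11.5 ± 1.1 mm and occlusal angle difference SD 1.2°. The
true left–right correlation of baseline measures is not reported anywhere,
so between-animal SD and difference SD are independent knobs rather than a
guessed correlation; the rat labial difference SD defaults to 0.6 mm,
consistent with a 2.3 mm wide-gap-CRO excess scoring Z ≈ 3.8 (> 3). Effect
defaults follow the wide-gap CRO reports (rat labial +2.3 mm; rabbit
labial +1.25 mm).

## Statistics

Left–right symmetry is summarized by the mean paired difference with 90%
confidence intervals from (i) the paired t interval and (ii) a bootstrap
over resampled differences (resampling differences and resampling
(left, right) pairs are identical for this statistic). Post-defect
measures are described by Z scores against the baseline cohort of
left-minus-right differences (n−1 SD denominator); no significance is
claimed for single-animal Z scores and no multiple-testing adjustment is
applied by default.

One choice needs flagging: **the bootstrap interval defaults to the
expanded percentile type** (Hesterberg 2015), which widens the quantile
levels from α/2 to `pnorm(-qt(1-α/2, n-1)·sqrt(n/(n-1)))`. The plain
percentile interval of a mean at n = 8 covers only ~83% at nominal 90% —
not a small-sample curiosity but a 7-point gap (half-width ≈
1.645·s·sqrt(7/8)/sqrt(8) against a t₇ reference). The expanded interval
is still distribution-free, converges to the plain percentile as n grows,
and restores ~89–90% coverage at n = 8; the plain interval remains
available via `type = "percentile"`. `coverage_simulation()` reproduces
both behaviours.

Note also what a symmetry criterion can promise: under true symmetry a 90%
interval excludes zero for ~10% of metrics regardless of cohort size, so
"every CI contains 0" is an observation about a particular cohort (as in
the source study), not a guarantee; the calibrated statement is the
coverage simulation.

## Degenerate inputs and tie-breaks

Zero-SD difference vectors yield zero-width t intervals flagged
degenerate, and Z scores refuse a zero-SD baseline. Multi-start
registration breaks exact similarity ties toward the smaller parameter
norm. Landmark detection refuses profiles without an identifiable facet
(`gnaw_ridge` absent → lingual/occlusal lengths and the angle error out).
Volumes are validated for positive spacing; TIFF stacks are not read
(no TIFF codec in the supported stack — convert to NIfTI/MetaImage, whose
headers carry spacing).

## Known limitations

Single mid-sagittal slice (±1-slice averaging is deliberately not the
default; the planar reading is documented), no multi-resolution pyramid in
the registration, no deformable registration, no automatic tooth
identification beyond the phantom/segmentation contract, and rabbit
lingual/occlusal path lengths are not computed (the tooth shape makes the
direct measurement unreliable; the occlusal angle replaces them).
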