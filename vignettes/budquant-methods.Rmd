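---
title: "BudQuant methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BudQuant methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

BudQuant measures the early growth of embryonic mammary rudiments (MRs)
from serial transversal sections of BrdU-labelled mouse embryos. This
vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic phantom does and does not emulate, and the choices made where
the design was genuinely open.

## The measurement problem

A bud-stage rudiment is a multilayered epithelial ball, ~100–200 µm
across, sunk into mesenchyme beneath a single-layered surface ectoderm.
Sections of 5–6 µm are stained so that nuclei that were in S-phase during
a 2 h BrdU pulse carry a dark brown DAB precipitate, and all other nuclei
are counterstained blue with hematoxylin. Three quantities are derived:

1. a *proliferation proxy* per tissue compartment — the fraction of
   nuclear pixels that are BrdU⁺;
2. the *rudiment volume* — per-section epithelial areas integrated over
   cumulative section depth;
3. over a 24 h pulse–chase, the *expected vs observed fold volume
   increase*, which separates growth by ectodermal cell influx from
   growth by proliferation and hypertrophy.

All quantification is pixel-area based, never cell-count based: the DAB
reaction is run to saturation, so a labelled nucleus contributes a stable
pixel footprint even as label is diluted by division. This is also what
makes BrdU usable as a 24 h cell-tracing label: both daughters of a
labelled cell produce a full-size labelled footprint.

## Compartment segmentation

The segmentation is deliberately semi-manual: the analyst supplies the
basement-membrane polyline, the rudiment contour (plus neck contour when
a neck has formed), and the rudiment center; everything else is computed.

**Ectoderm (`refineEctoderm`).** The inner ectoderm boundary is the
drawn polyline; the outer boundary against the slide background is
evolved by a two-phase region competition in the Chan–Vese spirit:
pixels within a search band (twice the expected thickness, default
15 µm) are iteratively reassigned to the phase — tissue or background —
whose mean intensity they match, with a Gaussian-smoothed membership map
standing in for the curvature penalty. Iteration stops at a cap of 200
or when the energy changes by less than 1e-4 relative, whichever comes
first. Because stained nuclei make tissue intensity strongly bimodal,
the evolution runs on a copy blurred at roughly the nuclear scale
(σ = band/4 px), and the converged phase means then set the final
boundary on a lightly blurred copy (σ = 0.8 px) at a level biased 35%
of the way from background towards tissue — without this, dark nuclei
drag the boundary inward by one to two pixels. If the two phase means
differ by less than 0.05 (scale 0–1) the image is declared free of
tissue and an error is raised. With `maxIter = 0` the initialization
band is returned unchanged, giving a clean fixed-point behaviour.

**Mammary mesenchyme (`mammaryMesenchymeBand`).** The condensing
mesenchyme around the rudiment is taken as a dilation collar: the
rudiment (plus neck) mask dilated by a disc of radius
`round(15 µm / pixel size)` pixels, minus the epithelium and ectoderm.
The 15 µm default matches the few cell layers that condense into mammary
mesenchyme; at pixel sizes coarser than 15 µm the band is undefined and
an error is raised. Structuring elements are discrete discs with radii
rounded to the nearest pixel throughout.

**Core/periphery (`erodeToCore`).** On central sections the rudiment is
split into a cuboidal core and a columnar periphery by iterative unit-disc
erosion: the erosion depth whose core : whole-rudiment area ratio is
closest to 1:3 wins, ties going to the deeper erosion (smaller core). The
1:3 ratio is interpreted as core : whole (so periphery : core = 2:1); the
phrasing could also be read as core : periphery = 1:3, so the target is
an explicit argument (`targetRatio`). Masks that erode away before the
ratio ever reaches twice the target return an empty core with a warning
rather than an arbitrary level. The split is only applied where
`isCentralSection` is set; elsewhere the whole rudiment is one epithelial
compartment (`"mr"`), which the tabulation sums into the rudiment total.

**Dermal mesenchyme (`dermalWindow`).** The reference dermis is the
region between two lines parallel to the local ectoderm: one through the
rudiment center, one 65 µm deeper. "Parallel to the ectoderm" is
underdefined for a curved membrane, so the direction is the principal
direction of the polyline vertices within ±100 µm of the rudiment center.
The window excludes the epithelium and the mammary band, is clipped to
the image with a warning, and optional manual exclusion masks (e.g. for
somites) can be subtracted — line placement alone is not assumed to
exclude them.

**Dorsal/ventral arms (`splitEctoderm`).** The ectoderm is cut at the
rudiment attachment (columns where the dilated epithelium touches the
band); the arm labelled ventral comes from the annotation's orientation
flag (ventral to the left in the standard orientation). The attachment
zone itself belongs to neither arm.

`labelCompartments` composes these into one label map and emits a
quality-control overlay with a fixed colour key (dorsal ectoderm green,
ventral yellow, core orange, periphery red, neck purple, mammary
mesenchyme turquoise, dermal mesenchyme blue), mirroring the practice of
validating every automated segmentation by eye.

## BrdU thresholding and tabulation

Manual colour thresholding is modelled as channel rules on the 0–255
scale: BrdU⁺ pixels have luminance ≤ `brduLumMax` (default 120) and red
not below blue (brown, never blue); hematoxylin pixels have blue
exceeding red and luminance ≤ `nucleiLumMax` (default 200). The BrdU set
is forced to be a subset of the nuclear set. The defaults are tuned to
the phantom palette; on real slides they are set manually per staining
batch, which is the method's nature. Compartments with zero nuclear
pixels report an undefined (`NA`) fraction, never zero — a zero would
silently bias downstream means.

The ectoderm fraction used in the influx model pools the dorsal and
ventral arms (configurable by using the per-arm rows instead): the
source tables do not state a side, and pooling is the natural reading.

## Volumetry

Area profiles use nominal cumulative depths — section *i* sits at
(*i* − 1) × thickness — and lost sections leave gaps rather than
renumbering. The fitted models are

* Gaussian, *A* exp(−(*z* − *z*₀)²/2σ²): the default for dome-shaped
  buds; volume *A*σ√(2π).
* Parabolic, max(0, *k*(*R*² − (*z* − *z*₀)²)): exact for ellipsoids;
  volume 4/3 *kR*³.

The original implementation's functional form is not recorded anywhere,
so the model name travels inside every `VolumeEstimate` for provenance,
and both models are validated against analytic phantoms and against
trapezoidal integration of complete stacks. Initialisation is
*A* = max area, *z*₀ = argmax depth, σ = span/4; convergence is a
relative parameter change below 1e-8 or 500 Levenberg–Marquardt
iterations. Profiles with fewer positive samples than parameters fail
with a non-convergence error instead of returning a meaningless
degenerate fit; all-zero profiles return volume 0 without fitting. No
tissue-shrinkage correction is applied (none is defined for the
protocol), and no Cavalieri variance estimate is attempted.

## The influx and hypertrophy models

Fold increases follow the convention (X₂₄ − X₂)/X₂ (a doubling is 1.0),
verified against the published table rows. The expected fold increase

ΔV_exp = ((B₂₄ − B₂)/B₂) ÷ f_ect × f_mr

rests on the assumption that labelled and unlabelled ectodermal cells are
equally likely to enter the rudiment, so dividing the labelled influx by
f_ect estimates the total influx; multiplying by f_mr converts labelled
pixels into a fraction of rudiment volume. The estimator is *slightly
biased upward* when resident cells proliferate, because their divisions
also add BrdU⁺ pixels. Both properties are verified by simulation
(`simulateInfluxExperiment`): with no proliferation and no death the mean
estimate across replicates matches the true fold increase within
binomial error; switching proliferation on makes it overestimate. The
test and acceptance runs use 150 replicates of a 2000-cell rudiment with
1200 influxing cells.

The hypertrophy model treats the rudiment as a sphere of radius 5 cell
diameters whose outer cell layer doubles its diameter in a day, growing
the radius to 6: volume ratio (6/5)³ = 1.728, reported in the
literature's "≈1.7-fold" style as a ratio (not an increment).

The proliferation-contribution estimate had to be reconstructed, as the
source formulas are illegible in the available text. The package uses

contribution = ((embryo fold − 1) / ratio) / (rudiment fold − 1),

i.e. the rudiment gains 1/ratio of the embryo's relative growth
increment by proliferation (the single-layered ectoderm proliferates
isometrically with the embryo), and that gain is expressed as a share of
the rudiment's actual growth, clipped to [0, 1]. For a rudiment growing
isometrically with the embryo at a 5.9-fold lower rate this gives
1/5.9 ≈ 17%, and 1/24.8 ≈ 4% at a 24.8-fold lower rate — consistent with
the magnitudes reported for bud-stage rudiments. The interpretation
string is embedded in the result; the quantity is a rough bound and is
deliberately excluded from any acceptance comparison.

Rows of the bundled snapshot table whose published derived values are
not reproducible from their published *rounded* inputs (four of the five
E11.5 rows differ in the second decimal, e.g. 0.68 recomputed vs 0.66
printed, implying unrounded internal fractions) are flagged via
`consistent_exp`/`consistent_obs`, never forced into agreement.

## 3D reconstruction

Registration uses non-reflective similarity transforms (rotation +
uniform scale + translation; det = s² > 0 excludes mirroring) fitted to
three control points — two ectodermal landmarks plus the rudiment
center — by complex linear regression, which is the exact least-squares
solution. Images are resampled bilinearly; label masks nearest-neighbour.

Nucleus extraction inverts the ITU-R BT.601 luminance to a 0–1 scale
(the conversion formula itself is a choice; the convention is recorded
here) and thresholds at 0.65, which selects the near-black DAB nuclei
and rejects blue hematoxylin nuclei. Components are 26-connected in 3D
over the anisotropic voxel grid (pixel × pixel × section thickness) and
filtered to 0.3–3 × the expected single-section footprint of a nucleus
of the given radius.

Touching nuclei are split by a distance-transform-seeded geodesic
partition: seeds are clustered local maxima of an anisotropy-aware exact
Euclidean distance transform (maxima below 0.6 of the component's peak
are suppressed), and voxels join their geodesically nearest seed. This
is a documented stand-in for evolving-generalised-Voronoi-diagram
splitting with the same seeded-partition goal; it operates in 3D (the
alternative, per-section 2D splitting, would miss fusions across
sections). Single-seed components pass through untouched, and the split
labels partition the input foreground exactly.

Iso-surfaces triangulate the 0.5 level of a binary mask as its exposed
voxel faces in physical µm coordinates, consistently wound outward. The
surface is blocky compared to marching cubes, but it is watertight by
construction and its enclosed volume equals the voxel volume *exactly*,
which makes mesh-based volume checks sharp rather than approximate. For
smooth rendering a downstream viewer can subdivide or smooth; volume
fidelity was judged the more important property for a measurement
package.

## The phantom: what it emulates, and what it does not

`generateStack` renders: a single-layered ectoderm band (15 µm) across
the top of each image; an ellipsoidal rudiment (default semi-axes
60 × 50 × 50 µm) tangent to or joined by a cylindrical neck to the
band; a 15 µm mammary-mesenchyme collar and dermis below; elliptical
nuclei (radius 3 µm, axis jitter ±20%) with per-compartment BrdU⁺
probabilities (defaults: ectoderm 0.22, rudiment 0.045, mesenchyme
0.20 — the measured bud-stage values); DAB-brown/hematoxylin-blue
rendering over a faint eosin-like tissue tint; Gaussian pixel noise
(σ = 0.01); lost sections; and per-section similarity misalignments with
recorded transforms. Geometry is chosen for closed-form volumes
(ellipsoid + cylinder), so volumetry has an analytic oracle. Default
sampling is 5 µm sections at 1 µm/pixel.

Deliberately *not* emulated: chromatin texture and staining gradients
within nuclei, partial-volume antialiasing at nucleus borders, uneven
illumination, section folds and tears, eosinophilic structures that
confuse colour thresholding, and nuclei spanning multiple sections.
Consequently, passing phantom tests shows the geometry, arithmetic and
estimators are correct — it does not show that the default colour
thresholds transfer to any real staining batch (they will not; they are
manual by design), nor that segmentation survives real-world artefacts.

Phantom sizes used by the test and acceptance runs: 300 × 150 px
sections, 15–21 sections, roughly 500–1500 nuclei per stack — small
enough to run the full suite in well under a minute while leaving every
binomial check adequately powered.

## Statistical conventions

Summaries are mean ± sample SD with n. Comparisons are two-sided
Student's t-tests — paired when the BrdU-exposure conditions are the
same (littermates, tissues within a specimen), unpaired otherwise —
with significance marked at p < 0.05 by an asterisk. Unpaired tests
default to the classic equal-variance Student form, matching the
reporting convention of the era this pipeline reproduces; Welch's
correction is available by flag. Differences among the five rudiments
use one-way ANOVA. No multiple-testing correction is applied (none was
applied in the source convention); reports state this. Identical paired
samples are handled explicitly (t = 0, p = 1) since the standard test
errors on zero-variance differences.

## Known limitations

* The semi-manual contract is fundamental: no automatic rudiment
  detection is attempted.
* Colour thresholds are per-batch manual settings; no stain
  deconvolution is provided.
* The dermal window's "parallel to the ectoderm" uses a local linear
  fit of the membrane; strongly curved membranes near the rudiment
  center will bend the true anatomical window away from it.
* The influx estimator inherits the source model's assumptions — equal
  entry probability for labelled and unlabelled ectodermal cells, label
  saturation, negligible death — and overestimates when resident cells
  divide.
* Spatial directionality of influx is out of scope; the model is purely
  budget arithmetic.
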