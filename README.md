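# BudQuant

Quantitative morphometry of embryonic mammary rudiments from serial
histological sections.

Mouse mammary glands start as five pairs of rudiments (MR1–MR5) budding
from the surface ectoderm between embryonic day E11 and E12. Their early
growth is puzzling: the buds proliferate far *less* than the surrounding
ectoderm, yet they grow steadily. BudQuant implements the image-analysis
and arithmetic machinery needed to dissect this growth from serial
BrdU-immunostained sections: it measures per-compartment proliferation
proxies, reconstructs rudiment volumes, and tests whether growth is
explained by recruitment of ectodermal cells (influx), peripheral-cell
hypertrophy, or proliferation. It is aimed at developmental biologists
and image analysts working with semi-manually annotated section series of
embryonic skin appendages (mammary, hair, tooth and similar rudiments).

## What it computes

**Compartment segmentation.** From a manually drawn basement-membrane
polyline and rudiment contour, each section is partitioned into dorsal and
ventral ectoderm, rudiment core/periphery (by erosion of the rudiment mask
to a core : whole area ratio of 1:3 on central sections) and neck, a 15 µm
mammary-mesenchyme collar (morphological dilation), and a dermal-mesenchyme
window between two lines parallel to the ectoderm through the rudiment
center and 65 µm below it. The ectoderm's outer boundary is refined by a
region-based (Chan–Vese-style) active contour against the background.

**BrdU quantification.** Colour thresholding separates DAB-brown
BrdU⁺ pixels and all nuclear (brown + hematoxylin-blue) pixels; the
proliferation proxy is the pixel fraction

&nbsp;&nbsp;&nbsp;&nbsp;*f* = BrdU⁺ pixels / all nuclear pixels

per compartment (pixel areas, not cell counts, because the DAB
precipitate saturates).

**Volumetry.** Epithelial area is measured on every section, plotted
against cumulative section thickness *z*, and fitted by
Levenberg–Marquardt nonlinear least squares with a Gaussian model
*A* exp(−(*z*−*z*₀)²/2σ²) (or a parabolic model, exact for ellipsoids);
the rudiment volume is the area under the fitted curve, robust to lost
sections.

**Influx model.** Over a 24 h BrdU pulse–chase, the expected fold volume
increase if all new label came from ectodermal influx is

&nbsp;&nbsp;&nbsp;&nbsp;ΔV_exp = ((B₂₄ − B₂)/B₂) ÷ f_ect × f_mr

(B = BrdU⁺ rudiment pixels; f_ect, f_mr = labelled fractions at t = 2 h),
compared with the observed ΔV_obs = (V₂₄ − V₂)/V₂. Peripheral-cell
hypertrophy is modelled as a sphere of radius 5 cell diameters whose outer
layer doubles its diameter: volume ratio (6/5)³ ≈ 1.7-fold.

**3D reconstruction.** Sections are registered to the first section with
non-reflective similarity transforms fitted to three control points;
BrdU⁺ nuclei are extracted at a fixed inverted-grayscale threshold of
0.65, size-filtered, split (distance-transform-seeded geodesic partition)
and meshed as iso-surfaces, all in anisotropic µm coordinates.

A synthetic-histology phantom generator (`phantomSpec()`,
`generateStack()`) produces serial-section stacks with complete ground
truth — compartment masks, every nucleus with its BrdU status, analytic
volumes, applied misalignments — so the whole pipeline is testable
without microscope data.

## Worked example

Generate a phantom bud (22% BrdU⁺ ectoderm, 4.5% BrdU⁺ rudiment),
segment its central section and tabulate BrdU incorporation:

```r
library(BudQuant)
ph  <- generateStack(phantomSpec(nSections = 15))
i   <- 8                                   # central section
img <- ph$images[[match(i, ph$truth@keptSections)]]
seg <- labelCompartments(img, ph$truth@annotations[[i]], pixelSize = 1)
quantifySection(img, seg$labeling)
#>    compartment nuclear_pixels brdu_pixels fraction
#> 3         core           1208          27   0.0224
#> 4    periphery           2321         118   0.0508
#> 9           MR           3529         145   0.0411
#> 10    ectoderm           1641         445   0.2712
```

The rudiment's BrdU⁺ pixel fraction (0.041) recovers the generating 4.5%
within binomial error, and the ectoderm fraction (0.271) the generating
22%; their ratio is the fold difference in proliferation rate the
pipeline is designed to measure. Volumetry on a spherical phantom
(radius 50 µm, 5 µm sections):

```r
ap  <- truthAreaProfile(generateStack(phantomSpec(
         semiAxes = c(50, 50, 50), nSections = 21, noiseSd = 0))$truth)
fitProfile(buildProfile(ap$area_um2, 5), "parabolic")
#> VolumeEstimate: 5.233e+05 um^3 (parabolic fit, 21 samples, RMS 4.6 um^2)
```

against the analytic 4/3·π·50³ = 5.236 × 10⁵ µm³. The influx arithmetic
on the bundled published snapshot table:

```r
tab <- table3Report(table3Snapshots())
head(tab[, c("age","genotype","rudiment","dv_exp","dv_obs","note")], 3)
#>     age genotype rudiment dv_exp dv_obs note
#> 1 E11.5       wt        1  1.290  1.256    1
#> 2 E11.5       wt        3  0.676  0.537    1
#> 3 E11.5       wt        4  2.506  0.994    1
hypertrophyFold()
#> [1] 1.728
```

`note` classifies each rudiment (1: observed < expected, proliferation +
apoptosis; 2/3: observed > expected, hypertrophy); a `consistent_exp`
flag marks rows whose published derived value is reproducible from its
published rounded inputs.

## Documentation

The methods vignette (`vignettes/budquant-methods.Rmd`) describes the
models, the phantom's design and its limits, parameter defaults and
numerical choices in detail.
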