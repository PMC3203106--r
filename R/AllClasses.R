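#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

# Canonical compartment labels, in the colour-key order of the quality
# control overlays.  "mr" is the undivided epithelial compartment used on
# sections where the core/periphery erosion split is not applied.
.compartments <- c("background", "d.ect", "v.ect", "core", "periphery",
                   "neck", "mamm.mes", "derm.mes", "mr")

#' Compartment label vocabulary
#'
#' The fixed set of tissue compartments a section is segmented into:
#' dorsal/ventral ectoderm, rudiment core, periphery and neck, mammary and
#' dermal mesenchyme, plus `"mr"` (whole undivided rudiment epithelium, used
#' on non-central sections) and `"background"`.
#'
#' @return character vector of label names.
#' @export
compartmentNames <- function() .compartments

#' PhantomSpec: parameters of a synthetic serial-section phantom
#'
#' Describes a synthetic histology specimen: an ellipsoidal epithelial
#' rudiment (optionally with a cylindrical neck) embedded under a
#' single-band surface ectoderm, above mesenchyme, rendered as a stack of
#' transversal sections with DAB-brown BrdU-positive and hematoxylin-blue
#' BrdU-negative nuclei.
#'
#' @slot semiAxes numeric(3), ellipsoid semi-axes in micrometres:
#'   `a` (lateral, along image columns), `b` (depth, along rows),
#'   `c` (axial, along the stack).
#' @slot neckRadius,neckLength micrometres; a zero length means no neck.
#' @slot ectodermThickness micrometres.
#' @slot pixelSize micrometres per pixel.
#' @slot sectionThickness micrometres.
#' @slot nSections integer, number of nominal sections (>= 3).
#' @slot nucleusRadius named numeric, nuclear radius in micrometres for
#'   `ectoderm`, `core`, `periphery`, `mesenchyme` (an enlarged periphery
#'   radius emulates hypertrophic columnar cells).
#' @slot brduFraction named numeric in `[0, 1]`, per-compartment probability
#'   that a nucleus is BrdU-positive.
#' @slot nucleusDensity target fraction of compartment area covered by nuclei.
#' @slot allowTouching logical; permit touching/overlapping nuclei (used to
#'   exercise the nucleus-splitting stage).
#' @slot lostSections integer vector of 1-based section indices omitted from
#'   the rendered stack (but tracked in the ground truth).
#' @slot misalignment named numeric: `shift` (max |translation| px),
#'   `rot` (max |rotation| rad), `scale` (max |scale - 1|).
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot seed integer RNG seed; identical spec + seed give bit-identical
#'   stacks.
#' @export
setClass("PhantomSpec", representation(
  semiAxes = "numeric", neckRadius = "numeric", neckLength = "numeric",
  ectodermThickness = "numeric", pixelSize = "numeric",
  sectionThickness = "numeric", nSections = "integer",
  nucleusRadius = "numeric", brduFraction = "numeric",
  nucleusDensity = "numeric", allowTouching = "logical",
  lostSections = "integer", misalignment = "numeric",
  noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  need <- c("ectoderm", "core", "periphery", "mesenchyme")
  if (length(object@semiAxes) != 3 || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be 3 positive lengths (a, b, c)")
  for (f in c("ectodermThickness", "pixelSize", "sectionThickness"))
    if (slot(object, f) <= 0) msg <- c(msg, paste(f, "must be > 0"))
  if (object@neckRadius < 0 || object@neckLength < 0)
    msg <- c(msg, "neck dimensions must be >= 0")
  if (object@nSections < 3L) msg <- c(msg, "nSections must be >= 3")
  if (!all(need %in% names(object@nucleusRadius)) ||
      any(object@nucleusRadius[need] <= 0))
    msg <- c(msg, "nucleusRadius must be positive for ectoderm, core, periphery, mesenchyme")
  if (!all(need %in% names(object@brduFraction)) ||
      any(object@brduFraction[need] < 0 | object@brduFraction[need] > 1))
    msg <- c(msg, "brduFraction must lie in [0, 1] for every compartment")
  if (length(object@lostSections) &&
      (any(object@lostSections < 1L) || any(object@lostSections > object@nSections)))
    msg <- c(msg, "lostSections out of range")
  if (object@nSections - length(unique(object@lostSections)) < 3L)
    msg <- c(msg, "fewer than 3 sections would remain after losses")
  if (!all(c("shift", "rot", "scale") %in% names(object@misalignment)) ||
      any(object@misalignment < 0))
    msg <- c(msg, "misalignment needs non-negative shift, rot, scale entries")
  if (length(msg)) msg else TRUE
})

#' AnnotationSet: manual contours for one section
#'
#' The semi-manual inputs the segmentation stage consumes: a closed rudiment
#' contour, an optional closed neck contour, the open basement-membrane
#' polyline tracing the ectoderm's inner boundary, the rudiment center, and
#' orientation/centrality flags.  All coordinates are (row, col) pixels,
#' 1-based.
#'
#' @slot mrContour closed polygon, n x 2 matrix.
#' @slot neckContour optional closed polygon or `NULL`.
#' @slot basementMembrane open polyline, n x 2 matrix (>= 2 vertices).
#' @slot mrCenter numeric(2) (row, col), inside `mrContour`.
#' @slot isCentralSection logical; the core/periphery erosion split is only
#'   applied on central sections.
#' @slot ventralSide `"left"` or `"right"`: which ectodermal arm is ventral.
#' @slot mesenchymeSplitLine optional open polyline manually subdividing the
#'   mammary-mesenchyme band, or `NULL`.
#' @export
setClass("AnnotationSet", representation(
  mrContour = "matrix", neckContour = "matrixOrNULL",
  basementMembrane = "matrix", mrCenter = "numeric",
  isCentralSection = "logical", ventralSide = "character",
  mesenchymeSplitLine = "matrixOrNULL"))

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (nrow(object@mrContour) < 3) msg <- c(msg, "mrContour needs >= 3 vertices")
  if (nrow(object@basementMembrane) < 2)
    msg <- c(msg, "basementMembrane needs >= 2 vertices")
  if (length(object@mrCenter) != 2) msg <- c(msg, "mrCenter must be (row, col)")
  if (!object@ventralSide %in% c("left", "right"))
    msg <- c(msg, "ventralSide must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' CompartmentLabeling: per-pixel compartment label map
#'
#' @slot map integer matrix; values index [compartmentNames()] minus one
#'   (0 = background).
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("CompartmentLabeling",
         representation(map = "matrix", pixelSize = "numeric"))

setValidity("CompartmentLabeling", function(object) {
  v <- unique(as.integer(object@map))
  if (any(v < 0L | v >= length(.compartments)))
    return("label codes out of range")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  TRUE
})

#' GroundTruth: full per-stack truth for a phantom
#'
#' @slot labelings list of [CompartmentLabeling-class], one per nominal
#'   section (lost sections included here even though their images are
#'   omitted from the rendered stack).
#' @slot nuclei data.frame with one row per rendered nucleus: `section`,
#'   `row`, `col` (px), `z_um`, `compartment`, `brdu` (logical).
#' @slot volume analytic rudiment volume in cubic micrometres
#'   (ellipsoid 4/3*pi*a*b*c plus neck cylinder).
#' @slot transforms list of [SimilarityTransform2D-class] applied per kept
#'   section (identity when no misalignment was requested).
#' @slot annotations list of [AnnotationSet-class] per nominal section
#'   (`NULL` entries where the rudiment is absent from the section).
#' @slot spec the generating [PhantomSpec-class].
#' @slot keptSections integer indices of sections present in the image list.
#' @export
setClass("GroundTruth", representation(
  labelings = "list", nuclei = "data.frame", volume = "numeric",
  transforms = "list", annotations = "list", spec = "PhantomSpec",
  keptSections = "integer"))

#' AreaProfile: epithelial area against cumulative section depth
#'
#' @slot samples data.frame with `depth` (micrometres, strictly increasing)
#'   and `area` (square micrometres, >= 0).
#' @slot lostDepths depths (micrometres) of lost sections (gaps, not
#'   renumbered).
#' @slot sectionThickness micrometres.
#' @export
setClass("AreaProfile", representation(
  samples = "data.frame", lostDepths = "numeric",
  sectionThickness = "numeric"))

setValidity("AreaProfile", function(object) {
  s <- object@samples
  if (!all(c("depth", "area") %in% names(s)))
    return("samples needs 'depth' and 'area' columns")
  if (any(diff(s$depth) <= 0)) return("depths must be strictly increasing")
  if (any(s$area < 0)) return("areas must be >= 0")
  TRUE
})

#' VolumeEstimate: fitted area profile and integrated volume
#'
#' @slot model model name (`"gaussian"` or `"parabolic"`).
#' @slot pars named fitted parameters.
#' @slot volume cubic micrometres, area under the fitted curve.
#' @slot rms root-mean-square fit residual (square micrometres).
#' @slot nSamples number of profile samples used.
#' @export
setClass("VolumeEstimate", representation(
  model = "character", pars = "numeric", volume = "numeric",
  rms = "numeric", nSamples = "integer"))

#' SimilarityTransform2D: non-reflective similarity transform
#'
#' Rotation by `theta`, uniform scaling by `s` and translation, acting on
#' (row, col) points as `p' = s * R(theta) p + t`.  The determinant of the
#' linear part is `s^2 > 0`, so reflections are excluded by construction.
#'
#' @slot s scale (> 0).
#' @slot theta rotation, radians.
#' @slot tx,ty translation along rows / columns, pixels.
#' @export
setClass("SimilarityTransform2D", representation(
  s = "numeric", theta = "numeric", tx = "numeric", ty = "numeric"))

setValidity("SimilarityTransform2D", function(object) {
  if (object@s <= 0) return("scale must be > 0 (non-reflective)")
  TRUE
})

#' NucleusSet: labelled nuclei in an anisotropic voxel grid
#'
#' @slot labels 3D integer array `[row, col, section]`; 0 is background.
#' @slot table data.frame per nucleus: `id`, centroid in micrometres
#'   (`row_um`, `col_um`, `z_um`), `voxels`.
#' @slot spacing numeric(3), voxel spacing in micrometres
#'   (pixel, pixel, section thickness).
#' @export
setClass("NucleusSet", representation(
  labels = "array", table = "data.frame", spacing = "numeric"))

#' SurfaceMesh: triangulated tissue surface
#'
#' @slot vertices n x 3 matrix of vertex coordinates in micrometres.
#' @slot faces m x 3 integer matrix of vertex indices (consistently wound,
#'   outward normals).
#' @slot tag tissue tag: `"ectoderm"`, `"MR"` or `"nuclei"`.
#' @export
setClass("SurfaceMesh", representation(
  vertices = "matrix", faces = "matrix", tag = "character"))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must be n x 3")
  if (ncol(object@faces) != 3) return("faces must be m x 3")
  if (nrow(object@faces) &&
      (max(object@faces) > nrow(object@vertices) || min(object@faces) < 1))
    return("faces index invalid vertices")
  TRUE
})

## show methods ---------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  ax <- object@semiAxes
  cat("PhantomSpec:", sprintf("ellipsoid %g x %g x %g um", ax[1], ax[2], ax[3]),
      if (object@neckLength > 0)
        sprintf("+ neck r=%g um, L=%g um", object@neckRadius, object@neckLength)
      else "(no neck)", "\n")
  cat(sprintf("  %d sections x %g um, %g um/px; %d lost\n",
              object@nSections, object@sectionThickness, object@pixelSize,
              length(object@lostSections)))
  cat("  BrdU fractions:",
      paste(names(object@brduFraction), signif(object@brduFraction, 3),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "CompartmentLabeling", function(object) {
  tab <- table(factor(.compartments[object@map + 1L], levels = .compartments))
  cat(sprintf("CompartmentLabeling %d x %d px (%g um/px)\n",
              nrow(object@map), ncol(object@map), object@pixelSize))
  print(tab[tab > 0])
})

setMethod("show", "VolumeEstimate", function(object) {
  cat(sprintf("VolumeEstimate: %.4g um^3 (%s fit, %d samples, RMS %.3g um^2)\n",
              object@volume, object@model, object@nSamples, object@rms))
})

setMethod("show", "SimilarityTransform2D", function(object) {
  cat(sprintf("SimilarityTransform2D: s=%.6g, theta=%.6g rad, t=(%.4g, %.4g) px\n",
              object@s, object@theta, object@tx, object@ty))
})

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d nuclei in %s grid, spacing %s um\n",
              nrow(object@table), paste(dim(object@labels), collapse = " x "),
              paste(object@spacing, collapse = " x ")))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh '%s': %d vertices, %d faces\n",
              object@tag, nrow(object@vertices), nrow(object@faces)))
})

## accessors ------------------------------------------------------------

#' @rdname accessors
#' @param object an object of the relevant class.
#' @export
setGeneric("volume", function(object) standardGeneric("volume"))

#' Accessors for BudQuant classes
#'
#' `volume()` returns the integrated (or analytic ground-truth) volume in
#' cubic micrometres; `labelMap()` the integer label matrix;
#' `compartmentMask()` the logical mask of one named compartment;
#' `nucleusTable()` the per-nucleus table; `profileSamples()` the
#' depth/area samples of a profile.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("volume", "VolumeEstimate", function(object) object@volume)

#' @rdname accessors
#' @export
setMethod("volume", "GroundTruth", function(object) object@volume)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' @rdname accessors
#' @export
setMethod("labelMap", "CompartmentLabeling", function(object) object@map)

#' @rdname accessors
#' @param name a compartment name from [compartmentNames()].
#' @export
setGeneric("compartmentMask", function(object, name)
  standardGeneric("compartmentMask"))

#' @rdname accessors
#' @export
setMethod("compartmentMask", "CompartmentLabeling", function(object, name) {
  code <- match(name, .compartments) - 1L
  if (is.na(code)) stop("unknown compartment: ", name)
  object@map == code
})

#' @rdname accessors
#' @export
setGeneric("nucleusTable", function(object) standardGeneric("nucleusTable"))

#' @rdname accessors
#' @export
setMethod("nucleusTable", "NucleusSet", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("profileSamples", function(object) standardGeneric("profileSamples"))

#' @rdname accessors
#' @export
setMethod("profileSamples", "AreaProfile", function(object) object@samples)

# internal: build a CompartmentLabeling from a named list of masks
labelingFromMasks <- function(masks, dim, pixelSize) {
  map <- matrix(0L, dim[1], dim[2])
  for (nm in names(masks)) {
    code <- match(nm, .compartments) - 1L
    if (is.na(code)) stop("unknown compartment: ", nm)
    map[masks[[nm]]] <- code
  }
  new("CompartmentLabeling", map = map, pixelSize = pixelSize)
}
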