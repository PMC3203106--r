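# BrdU-incorporation quantification by colour thresholding.
#
# The proliferation-rate proxy is a pixel-area fraction, not a cell count:
# the DAB immuno-precipitate saturates, so the BrdU-positive pixel area per
# labelled nucleus is stable while intensity is not.  Fractions are the
# ratio of BrdU-positive pixels among all nuclear (DAB brown + hematoxylin
# blue) pixels within a compartment.

#' Colour-threshold parameters for nuclear segmentation
#'
#' Channel rules selecting dark-brown DAB (BrdU-positive) pixels and all
#' stained nuclear (brown or blue hematoxylin) pixels.  Thresholds are on
#' the 0-255 scale.  A pixel is BrdU-positive when its luminance is at most
#' `brduLumMax` and its red channel is not below blue (brown, not blue);
#' it is a blue nucleus when blue exceeds red by at least `blueExcessMin`
#' and luminance is at most `nucleiLumMax`.  The BrdU set is a subset of
#' the nuclear set by construction.
#'
#' Defaults are tuned to the phantom palette; thresholds for real slides
#' are set manually, mirroring manual colour thresholding practice.
#'
#' @param brduLumMax,nucleiLumMax luminance ceilings (0-255).
#' @param blueExcessMin minimum B - R excess for hematoxylin pixels.
#' @return a named list of class `"thresholdParams"`.
#' @export
thresholdParams <- function(brduLumMax = 120, nucleiLumMax = 200,
                            blueExcessMin = 1) {
  stopifnot(brduLumMax >= 0, brduLumMax <= 255,
            nucleiLumMax >= 0, nucleiLumMax <= 255)
  structure(list(brduLumMax = brduLumMax, nucleiLumMax = nucleiLumMax,
                 blueExcessMin = blueExcessMin),
            class = "thresholdParams")
}

#' Segment BrdU-positive and all-nuclei pixels
#'
#' @param image RGB array `[row, col, 3]` in `[0, 1]`.
#' @param params a [thresholdParams()] list.
#' @return list with logical masks `brdu` and `nuclei`;
#'   `brdu` is guaranteed to be a subset of `nuclei`.
#' @export
thresholdNuclei <- function(image, params = thresholdParams()) {
  if (length(dim(image)) != 3L)
    stop("colour thresholding requires an RGB image, not grayscale")
  lum <- luminance(image) * 255
  R <- image[, , 1] * 255; B <- image[, , 3] * 255
  brdu <- lum <= params$brduLumMax & (R - B) >= 0
  blue <- (B - R) >= params$blueExcessMin & lum <= params$nucleiLumMax
  nuclei <- brdu | blue
  brdu <- brdu & nuclei
  list(brdu = brdu, nuclei = nuclei)
}

#' Tabulate per-compartment nuclear and BrdU-positive pixel counts
#'
#' Counts nuclear and BrdU-positive pixels within each compartment of a
#' labeling and reports the BrdU-positive fraction of all nuclear pixels.
#' A whole-rudiment `"MR"` row is appended as the exact sum of the core,
#' periphery, neck and undivided-rudiment compartments, and an
#' `"ectoderm"` row pools the dorsal and ventral arms.  Compartments with
#' zero nuclear pixels get an `NA` fraction (undefined, never zero).
#'
#' @param labeling a [CompartmentLabeling-class].
#' @param brduMask,nucleiMask masks from [thresholdNuclei()], same shape as
#'   the label map.
#' @return data.frame with `compartment`, `nuclear_pixels`, `brdu_pixels`,
#'   `fraction`.
#' @export
tabulateCompartments <- function(labeling, brduMask, nucleiMask) {
  map <- labelMap(labeling)
  if (!identical(dim(map), dim(brduMask)) ||
      !identical(dim(map), dim(nucleiMask)))
    stop("masks and labeling must share the same shape")
  if (any(brduMask & !nucleiMask))
    stop("brdu mask is not a subset of the nuclei mask")
  comps <- setdiff(.compartments, "background")
  lev <- factor(.compartments[map + 1L], levels = comps)
  nuc <- tapply(as.vector(nucleiMask), lev, sum)
  brd <- tapply(as.vector(brduMask), lev, sum)
  nuc[is.na(nuc)] <- 0L; brd[is.na(brd)] <- 0L
  out <- data.frame(compartment = comps,
                    nuclear_pixels = as.integer(nuc),
                    brdu_pixels = as.integer(brd),
                    stringsAsFactors = FALSE)
  pooled <- function(name, members) {
    i <- out$compartment %in% members
    data.frame(compartment = name,
               nuclear_pixels = sum(out$nuclear_pixels[i]),
               brdu_pixels = sum(out$brdu_pixels[i]))
  }
  out <- rbind(out,
               pooled("MR", c("core", "periphery", "neck", "mr")),
               pooled("ectoderm", c("d.ect", "v.ect")))
  out$fraction <- ifelse(out$nuclear_pixels > 0,
                         out$brdu_pixels / out$nuclear_pixels, NA_real_)
  out
}

#' Ventral-minus-dorsal BrdU fraction difference
#'
#' The per-embryo side-bias statistic: the BrdU-positive fraction of the
#' dorsal ectodermal arm subtracted from that of the ventral arm.
#'
#' @param ventralFraction,dorsalFraction fractions in `[0, 1]` (NA
#'   propagates).
#' @return signed difference, `NA` when either side is undefined.
#' @export
dvDifference <- function(ventralFraction, dorsalFraction) {
  ifelse(is.na(ventralFraction) | is.na(dorsalFraction), NA_real_,
         ventralFraction - dorsalFraction)
}

#' Ectoderm-over-rudiment fold difference in proliferation rate
#'
#' @param ectodermFraction,mrFraction BrdU-positive fractions.
#' @return the fold difference (ectoderm / rudiment); `Inf` with a warning
#'   when the rudiment fraction is zero.
#' @export
ectodermMrRatio <- function(ectodermFraction, mrFraction) {
  if (any(!is.na(mrFraction) & mrFraction == 0)) {
    warning("rudiment fraction is zero; returning Inf")
  }
  ectodermFraction / mrFraction
}

#' One-call BrdU quantification of a section
#'
#' Convenience wrapper: thresholds the image and tabulates per-compartment
#' counts in one step.
#'
#' @inheritParams thresholdNuclei
#' @param labeling a [CompartmentLabeling-class].
#' @return as [tabulateCompartments()].
#' @export
quantifySection <- function(image, labeling, params = thresholdParams()) {
  m <- thresholdNuclei(image, params)
  tabulateCompartments(labeling, m$brdu, m$nuclei)
}
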