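# Compartment segmentation of a stained section from manual contours.
#
# The pipeline mirrors semi-manual bud-stage morphometry: the analyst draws
# the basement membrane polyline, the rudiment contour (plus neck contour
# where a neck exists) and marks the rudiment center; the remaining
# geometry is computed -- the ectoderm band by a region-based active
# contour against the background, the mammary-mesenchyme collar by a 15 um
# dilation, the core/periphery split by erosion to a 1:3 area ratio on
# central sections, and the dermal-mesenchyme window by two lines parallel
# to the ectoderm through the rudiment center and 65 um below it.

# default tunables (micrometres unless noted)
segmentationParams <- function(bandUm = 15, windowUm = 65, coreRatio = 1 / 3,
                               ectBandUm = 15, cvMaxIter = 200,
                               cvTol = 1e-4, cvSmooth = 0.02) {
  list(bandUm = bandUm, windowUm = windowUm, coreRatio = coreRatio,
       ectBandUm = ectBandUm, cvMaxIter = cvMaxIter, cvTol = cvTol,
       cvSmooth = cvSmooth)
}

#' Refine the ectoderm mask with a region-based active contour
#'
#' Starting from a prior band of expected thickness resting on the
#' basement-membrane polyline, a Chan-Vese-style two-phase region contour
#' evolves the outer (tissue/background) boundary: pixels are iteratively
#' reassigned to the phase whose mean intensity they match, with a Gaussian
#' smoothness term standing in for the curvature penalty.  Evolution stops
#' at `maxIter` iterations or when the relative energy change drops below
#' `tol`, whichever comes first.  The mask stays bounded internally by the
#' polyline.
#'
#' @param image RGB array or grayscale matrix in `[0, 1]`.
#' @param basementMembrane open polyline, n x 2 (row, col) matrix tracing
#'   the ectoderm's inner boundary.
#' @param bandPrior expected ectoderm thickness in micrometres (also the
#'   initialisation band); the search region extends to twice this.
#' @param pixelSize micrometres per pixel.
#' @param side which side of the polyline the ectoderm lies on, in image
#'   row terms (`"up"` = towards row 1).
#' @param maxIter,tol iteration cap and relative-energy tolerance;
#'   `maxIter = 0` returns the initialisation unchanged.
#' @param minContrast minimum |tissue - background| mean-intensity contrast;
#'   below it the image is considered empty of tissue and an error is
#'   raised.
#' @return logical ectoderm mask.
#' @export
refineEctoderm <- function(image, basementMembrane, bandPrior = 15,
                           pixelSize = 1, side = c("up", "down"),
                           maxIter = 200, tol = 1e-4, minContrast = 0.05) {
  side <- match.arg(side)
  lum <- if (length(dim(image)) == 3) luminance(image) else image
  H <- nrow(lum); W <- ncol(lum)
  if (nrow(basementMembrane) < 2) stop("polyline needs >= 2 vertices")
  if (any(basementMembrane[, 1] < 1) || any(basementMembrane[, 1] > H) ||
      any(basementMembrane[, 2] < 1) || any(basementMembrane[, 2] > W))
    stop("basement-membrane polyline outside image")
  mrows <- polylineRowAt(basementMembrane, seq_len(W))
  MB <- matrix(mrows, H, W, byrow = TRUE)
  R <- matrix(seq_len(H), H, W)
  d <- if (side == "up") MB - R else R - MB
  bandPx <- max(1, bandPrior / pixelSize)
  roi <- !is.na(d) & d > 0 & d <= 2 * bandPx
  mask <- !is.na(d) & d > 0 & d <= bandPx
  if (maxIter == 0) return(mask)
  # blur at roughly the nuclear scale so the contour follows the tissue
  # band rather than individual stained nuclei
  ls <- as.matrix(EBImage::gblur(lum, sigma = max(2, bandPx / 4)))
  mu <- 0.02
  eOld <- Inf
  for (it in seq_len(maxIter)) {
    inside <- mask & roi
    outside <- roi & !mask
    c1 <- mean(ls[inside]); c2 <- mean(ls[outside])
    if (!is.finite(c2)) c2 <- c1
    if (abs(c1 - c2) < minContrast)
      stop("no tissue contrast along the basement membrane (empty tissue region)")
    G <- as.matrix(EBImage::gblur(mask * 1, sigma = 2))
    score <- (ls - c2)^2 - (ls - c1)^2 + mu * (2 * G - 1)
    mask <- roi & (score > 0)
    e <- sum((ls[mask] - c1)^2) + sum((ls[roi & !mask] - c2)^2)
    if (is.finite(eOld) && abs(eOld - e) <= tol * abs(eOld)) break
    eOld <- e
  }
  if (!any(mask)) stop("active contour collapsed: empty tissue region")
  # final boundary decision at the converged region means, taken on a
  # lightly smoothed image: the heavy blur localises the band but drags
  # the boundary inward where stained nuclei darken the tissue mean, so
  # the cut level is biased towards the background phase
  inside <- mask & roi
  ls1 <- as.matrix(EBImage::gblur(lum, sigma = 0.8))
  c1 <- mean(ls1[inside]); c2 <- mean(ls1[roi & !inside])
  if (is.finite(c2) && abs(c2 - c1) >= minContrast) {
    lo <- min(c1, c2); hi <- max(c1, c2)
    tissueIsDark <- c1 < c2
    cut <- if (tissueIsDark) hi - 0.35 * (hi - lo) else lo + 0.35 * (hi - lo)
    mask <- roi & (if (tissueIsDark) ls1 < cut else ls1 > cut)
  }
  # keep the connected component adjacent to the membrane
  comp <- as.matrix(EBImage::bwlabel(mask))
  near <- comp[d > 0 & d <= 2 & comp > 0]
  if (!length(near)) stop("no tissue adjacent to the basement membrane")
  keep <- as.integer(names(which.max(table(near))))
  comp == keep
}

#' Mammary-mesenchyme band around the rudiment
#'
#' The few condensing mesenchyme layers adjacent to the rudiment are taken
#' as a 15 um dilation collar: the rudiment (plus neck) mask dilated by a
#' disc of radius `round(bandUm / pixelSize)` pixels, minus the rudiment
#' itself and minus the ectoderm.
#'
#' @param mrMask logical rudiment (or rudiment + neck) mask.
#' @param pixelSize micrometres per pixel.
#' @param ectMask optional logical ectoderm mask to exclude.
#' @param bandUm band width in micrometres (default 15).
#' @return logical band mask.
#' @export
mammaryMesenchymeBand <- function(mrMask, pixelSize, ectMask = NULL,
                                  bandUm = 15) {
  if (!any(mrMask)) stop("empty rudiment mask")
  radius <- round(bandUm / pixelSize)
  if (radius < 1)
    stop("resolution too coarse: ", bandUm, " um is below one pixel")
  band <- as.matrix(EBImage::dilate(mrMask, discBrush(radius))) > 0.5
  band <- band & !mrMask
  if (!is.null(ectMask)) band <- band & !ectMask
  band
}

#' Erode the rudiment to its core at a target area ratio
#'
#' Iteratively erodes the rudiment mask with the unit disc and returns the
#' erosion level whose core/rudiment area ratio is closest to
#' `targetRatio` (ties broken towards the smaller core).  The split
#' reflects the histology of bud-stage rudiments: cuboidal core cells
#' surrounded by larger columnar peripheral cells, with the core occupying
#' about a third of the central cross-section.
#'
#' @param mrMask logical rudiment mask with positive area.
#' @param targetRatio target core : whole-rudiment area ratio (default 1/3;
#'   see the methods vignette for the interpretation).
#' @param isCentralSection must be `TRUE`: the split is only defined on
#'   central sections.
#' @return list with `core` and `periphery` masks, achieved `ratio`,
#'   erosion `level`, all per-level `ratios`, and `degenerate` flag (TRUE
#'   when the mask eroded away before reaching a ratio of
#'   `2 * targetRatio`, in which case the core is empty and a warning is
#'   issued).
#' @export
erodeToCore <- function(mrMask, targetRatio = 1 / 3,
                        isCentralSection = TRUE) {
  if (!isCentralSection)
    stop("core/periphery erosion is only applied to central sections")
  A <- sum(mrMask)
  if (A == 0) stop("rudiment mask has zero area")
  brush <- discBrush(1)
  masks <- list(mrMask)
  ratios <- 1
  cur <- mrMask
  repeat {
    cur <- as.matrix(EBImage::erode(cur, brush)) > 0.5
    if (!any(cur)) break
    masks[[length(masks) + 1L]] <- cur
    ratios <- c(ratios, sum(cur) / A)
  }
  if (min(ratios) > 2 * targetRatio) {
    warning("mask eroded to empty before approaching the target ratio; ",
            "returning empty core")
    return(list(core = mrMask & FALSE, periphery = mrMask, ratio = NA_real_,
                level = NA_integer_, ratios = ratios, degenerate = TRUE))
  }
  dev <- abs(ratios - targetRatio)
  # ties toward the smaller core = the deeper erosion level
  best <- max(which(dev == min(dev)))
  core <- masks[[best]]
  list(core = core, periphery = mrMask & !core, ratio = ratios[best],
       level = best - 1L, ratios = ratios, degenerate = FALSE)
}

#' Dermal-mesenchyme window below the rudiment
#'
#' The dermal-mesenchyme reference region between two automatically placed
#' lines parallel to the local ectoderm direction: one through the rudiment
#' center and one `offsetUm` (default 65 um) deeper.  The local ectoderm
#' direction is the principal direction of the basement-membrane polyline
#' within 100 um of the rudiment center.  The window is intersected with
#' the sub-membrane tissue and any masks in `exclude` (rudiment, neck,
#' mammary band) are removed.
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param mrCenter numeric(2) rudiment center (row, col), inside the image.
#' @param basementMembrane open polyline matrix.
#' @param pixelSize micrometres per pixel.
#' @param offsetUm window depth in micrometres.
#' @param exclude list of logical masks to exclude.
#' @return logical window mask; a warning is issued when the window is
#'   clipped by the image bounds.
#' @export
dermalWindow <- function(dim, mrCenter, basementMembrane, pixelSize = 1,
                         offsetUm = 65, exclude = list()) {
  H <- dim[1]; W <- dim[2]
  if (mrCenter[1] < 1 || mrCenter[1] > H || mrCenter[2] < 1 ||
      mrCenter[2] > W) stop("rudiment center outside image")
  v <- basementMembrane
  dd <- sqrt((v[, 1] - mrCenter[1])^2 + (v[, 2] - mrCenter[2])^2)
  loc <- v[dd <= 100 / pixelSize, , drop = FALSE]
  if (nrow(loc) < 2) loc <- v
  cv <- stats::cov(loc)
  u <- eigen(cv, symmetric = TRUE)$vectors[, 1]   # local membrane direction
  nrm <- c(-u[2], u[1])
  # orient the normal towards deeper tissue (from membrane to center)
  mb <- polylineRowAt(basementMembrane, mrCenter[2])
  if (is.na(mb)) mb <- mean(v[, 1])
  if (sum(nrm * c(mrCenter[1] - mb, 0)) < 0) nrm <- -nrm
  R <- matrix(seq_len(H), H, W)
  C <- matrix(seq_len(W), H, W, byrow = TRUE)
  depth <- ((R - mrCenter[1]) * nrm[1] + (C - mrCenter[2]) * nrm[2]) *
    pixelSize
  win <- depth >= 0 & depth <= offsetUm
  # below the membrane only
  mrows <- polylineRowAt(basementMembrane, seq_len(W))
  MB <- matrix(mrows, H, W, byrow = TRUE)
  win <- win & !is.na(MB) & R > MB
  # clipping check against the image bounds
  far <- mrCenter + nrm * offsetUm / pixelSize
  if (far[1] < 1 || far[1] > H || far[2] < 1 || far[2] > W)
    warning("dermal window clipped to image bounds")
  for (m in exclude) win <- win & !m
  win
}

#' Split the ectoderm into dorsal and ventral arms
#'
#' Partitions the ectoderm at the rudiment attachment into its two arms and
#' assigns dorsal/ventral from the annotation's orientation flag (by
#' convention the ventral ectoderm is to the left in standard transversal
#' orientation).
#'
#' @param ectMask logical ectoderm mask.
#' @param mrMask logical rudiment (+ neck) mask.
#' @param ventralSide `"left"` or `"right"`.
#' @param requireAdjacent error when the rudiment does not touch the
#'   ectoderm (when `FALSE`, the split falls back to the rudiment center
#'   column).
#' @return list with logical masks `ventral`, `dorsal`, and the attachment
#'   `gap` column range.
#' @export
splitEctoderm <- function(ectMask, mrMask, ventralSide = c("left", "right"),
                          requireAdjacent = TRUE) {
  ventralSide <- match.arg(ventralSide)
  touching <- as.matrix(EBImage::dilate(mrMask, discBrush(2))) > 0.5
  att <- which(touching & ectMask, arr.ind = TRUE)
  if (nrow(att)) {
    gap <- range(att[, 2])
  } else if (requireAdjacent) {
    stop("rudiment is not adjacent to the ectoderm")
  } else {
    cc <- mean(which(mrMask, arr.ind = TRUE)[, 2])
    gap <- c(cc, cc)
  }
  W <- ncol(ectMask)
  left <- ectMask & matrix(seq_len(W) < gap[1], nrow(ectMask), W, byrow = TRUE)
  right <- ectMask & matrix(seq_len(W) > gap[2], nrow(ectMask), W, byrow = TRUE)
  if (ventralSide == "left") list(ventral = left, dorsal = right, gap = gap)
  else list(ventral = right, dorsal = left, gap = gap)
}

#' Full compartment labeling of one annotated section
#'
#' Composes the segmentation sub-steps into one per-pixel label map over
#' the compartments of [compartmentNames()], and renders a quality-control
#' overlay with the standard colour key (dorsal ectoderm green, ventral
#' ectoderm yellow, core orange, periphery red, neck purple, mammary
#' mesenchyme turquoise, dermal mesenchyme blue).
#'
#' On central sections the rudiment is split into core and periphery by
#' [erodeToCore()]; elsewhere the whole rudiment is labelled `"mr"`.  When
#' the annotation carries a manual mesenchyme split line the mammary band
#' halves are returned in `details$bandHalves`.
#'
#' @param image RGB section array.
#' @param ann an [AnnotationSet-class].
#' @param pixelSize micrometres per pixel.
#' @param params parameter list, see `segmentationParams()` defaults.
#' @return list with `labeling` (a [CompartmentLabeling-class]), `overlay`
#'   (RGB array) and `details`.
#' @export
labelCompartments <- function(image, ann, pixelSize,
                              params = segmentationParams()) {
  validObject(ann)
  p <- utils::modifyList(segmentationParams(), params)
  dimHW <- dim(image)[1:2]
  ect <- refineEctoderm(image, ann@basementMembrane,
                        bandPrior = p$ectBandUm, pixelSize = pixelSize,
                        maxIter = p$cvMaxIter, tol = p$cvTol)
  mr <- fillPolygon(ann@mrContour, dimHW) & !ect
  if (!any(mr)) stop("rudiment contour encloses no area")
  neck <- if (!is.null(ann@neckContour))
    fillPolygon(ann@neckContour, dimHW) & !ect & !mr
  else matrix(FALSE, dimHW[1], dimHW[2])
  epith <- mr | neck
  band <- mammaryMesenchymeBand(epith, pixelSize, ect, p$bandUm)
  details <- list()
  masks <- list()
  if (ann@isCentralSection) {
    ec <- erodeToCore(mr, p$coreRatio, TRUE)
    masks$core <- ec$core
    masks$periphery <- ec$periphery
    details$coreRatio <- ec$ratio
    details$coreDegenerate <- ec$degenerate
  } else {
    masks$mr <- mr
  }
  if (any(neck)) masks$neck <- neck
  masks$mamm.mes <- band
  dv <- splitEctoderm(ect, epith, ann@ventralSide, requireAdjacent = FALSE)
  masks$v.ect <- dv$ventral
  masks$d.ect <- dv$dorsal
  masks$derm.mes <- dermalWindow(dimHW, ann@mrCenter, ann@basementMembrane,
                                 pixelSize, p$windowUm,
                                 exclude = list(epith, band, ect))
  if (!is.null(ann@mesenchymeSplitLine)) {
    srows <- polylineRowAt(ann@mesenchymeSplitLine, seq_len(dimHW[2]))
    SB <- matrix(srows, dimHW[1], dimHW[2], byrow = TRUE)
    R <- matrix(seq_len(dimHW[1]), dimHW[1], dimHW[2])
    above <- band & !is.na(SB) & R <= SB
    details$bandHalves <- list(a = above, b = band & !above)
  }
  labeling <- labelingFromMasks(masks, dimHW, pixelSize)
  list(labeling = labeling, overlay = qcOverlay(image, labeling),
       details = details)
}

# colour key of the quality-control overlays
.qcColors <- list(
  d.ect = c(0, 0.8, 0), v.ect = c(1, 0.9, 0), core = c(1, 0.55, 0),
  periphery = c(1, 0, 0), mr = c(1, 0, 0), neck = c(0.6, 0, 0.8),
  mamm.mes = c(0, 0.85, 0.85), derm.mes = c(0, 0.2, 1))

#' Quality-control overlay for a compartment labeling
#'
#' Draws each compartment's boundary over the section image in the
#' standard colour key, for visual verification of the segmentation.
#'
#' @param image RGB section array.
#' @param labeling a [CompartmentLabeling-class].
#' @return RGB array.
#' @export
qcOverlay <- function(image, labeling) {
  out <- image
  for (nm in names(.qcColors)) {
    m <- compartmentMask(labeling, nm)
    if (!any(m)) next
    b <- maskBoundary(m)
    for (k in 1:3) {
      ch <- out[, , k]
      ch[b] <- .qcColors[[nm]][k]
      out[, , k] <- ch
    }
  }
  out
}
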