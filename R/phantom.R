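# Synthetic serial-section histology phantoms with full ground truth.
#
# The phantom emulates a transversally sectioned embryonic flank: a
# single-layered surface ectoderm band across the top of each image, an
# ellipsoidal epithelial rudiment (optionally joined to the ectoderm by a
# cylindrical neck) sunk into the underlying mesenchyme, and elliptical
# nuclei rendered in a DAB/hematoxylin-like palette -- BrdU-positive nuclei
# dark brown, BrdU-negative nuclei blue, on a faintly tinted tissue
# background.  Every geometric quantity (compartment masks, nucleus records,
# analytic rudiment volume, applied transforms) is returned as ground truth.

# phantom palette (chosen so that colour thresholding separates the classes
# with wide margins; luminances: brown 0.20, blue 0.42, tissue 0.84, bg 0.97)
.palette <- list(
  background = c(250, 248, 245) / 255,
  tissue     = c(222, 180, 190) / 255,
  brdu       = c(70, 45, 30) / 255,
  negative   = c(80, 110, 170) / 255)

#' Specify a synthetic serial-section phantom
#'
#' Builds a validated [PhantomSpec-class]. Defaults describe a bud-stage
#' rudiment under the conditions the package is designed for: a
#' 60 x 50 x 50 um ellipsoid under a 15 um single-layered ectoderm, 5 um
#' sections at 1 um/pixel, 22% BrdU-positive nuclei in the ectoderm and
#' 4.5% in the rudiment epithelium (the measured bud-stage proliferation
#' proxy), 20% in mesenchyme.
#'
#' @param semiAxes ellipsoid semi-axes `c(a, b, c)` in micrometres
#'   (lateral, depth, axial).
#' @param neckRadius,neckLength neck cylinder joining rudiment to ectoderm,
#'   micrometres; `neckLength = 0` disables the neck.
#' @param ectodermThickness,pixelSize,sectionThickness micrometres.
#' @param nSections number of nominal sections.
#' @param nucleusRadius,brduFraction named numerics over compartments
#'   `ectoderm`, `core`, `periphery`, `mesenchyme`.
#' @param nucleusDensity target fraction of compartment area covered.
#' @param allowTouching allow nuclei to touch/overlap.
#' @param lostSections 1-based indices of sections missing from the stack.
#' @param misalignment named numeric `c(shift=, rot=, scale=)`: maxima of
#'   per-section random rigid+scale misalignment.
#' @param noiseSd additive Gaussian pixel noise SD.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nSections = 9)
#' spec
#' @export
phantomSpec <- function(semiAxes = c(a = 60, b = 50, c = 50),
                        neckRadius = 15, neckLength = 0,
                        ectodermThickness = 15, pixelSize = 1,
                        sectionThickness = 5, nSections = 25,
                        nucleusRadius = c(ectoderm = 3, core = 3,
                                          periphery = 3, mesenchyme = 3),
                        brduFraction = c(ectoderm = 0.22, core = 0.045,
                                         periphery = 0.045, mesenchyme = 0.2),
                        nucleusDensity = 0.5, allowTouching = FALSE,
                        lostSections = integer(),
                        misalignment = c(shift = 0, rot = 0, scale = 0),
                        noiseSd = 0.01, seed = 1L) {
  new("PhantomSpec", semiAxes = unname(semiAxes), neckRadius = neckRadius,
      neckLength = neckLength, ectodermThickness = ectodermThickness,
      pixelSize = pixelSize, sectionThickness = sectionThickness,
      nSections = as.integer(nSections), nucleusRadius = nucleusRadius,
      brduFraction = brduFraction, nucleusDensity = nucleusDensity,
      allowTouching = allowTouching,
      lostSections = as.integer(sort(unique(lostSections))),
      misalignment = misalignment, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# continuous-pixel geometry shared by generation and ground truth
.phantomGeometry <- function(spec) {
  px <- spec@pixelSize
  a <- spec@semiAxes[1] / px; b <- spec@semiAxes[2] / px
  ectPx <- max(1, round(spec@ectodermThickness / px))
  ectTop <- 9L
  mbRow <- ectTop + ectPx - 0.5            # basement-membrane row (boundary)
  neckPx <- spec@neckLength / px
  r0 <- mbRow + neckPx + b                 # rudiment center row
  W <- as.integer(2 * ceiling(a) + 180)
  H <- as.integer(ceiling(max(r0 + b, r0 + 65 / px) + 12))
  z0 <- (spec@nSections - 1) / 2 * spec@sectionThickness
  list(px = px, ectTop = ectTop, ectPx = ectPx, mbRow = mbRow,
       r0 = r0, cc = W / 2, W = W, H = H, z0 = z0)
}

# erosion-equivalent core mask: pixels deeper than the margin that brings
# the core : whole-rudiment area ratio closest to `ratio`
.coreByDistance <- function(mrMask, ratio = 1 / 3) {
  if (!any(mrMask)) return(mrMask)
  d <- as.matrix(EBImage::distmap(mrMask))
  lv <- sort(unique(round(d[mrMask], 4)))
  areas <- vapply(lv, function(m) sum(d >= m & mrMask), numeric(1))
  best <- lv[which.min(abs(areas / sum(mrMask) - ratio))]
  d >= best & mrMask
}

# per-section geometry masks; returns NULL entries where absent
.sectionMasks <- function(spec, g, z) {
  rel <- (z - g$z0) / spec@semiAxes[3]
  dimHW <- c(g$H, g$W)
  empty <- matrix(FALSE, g$H, g$W)
  ectAll <- empty; ectAll[g$ectTop:(g$ectTop + g$ectPx - 1L), ] <- TRUE
  mr <- empty; neck <- empty
  az <- bz <- 0
  if (abs(rel) < 1) {
    shrink <- sqrt(1 - rel^2)
    az <- spec@semiAxes[1] / g$px * shrink
    bz <- spec@semiAxes[2] / g$px * shrink
    if (az >= 0.5 && bz >= 0.5)
      mr <- fillEllipse(empty, g$r0, g$cc, bz, az)
  }
  dz <- (z - g$z0) / g$px
  if (spec@neckLength > 0 && abs(z - g$z0) < spec@neckRadius) {
    wz <- sqrt((spec@neckRadius / g$px)^2 - dz^2)
    rTop <- ceiling(g$mbRow + 0.5)
    rBot <- floor(g$r0 - bz)
    c0 <- max(1L, ceiling(g$cc - wz)); c1 <- min(g$W, floor(g$cc + wz))
    if (rTop <= rBot && c0 <= c1) neck[rTop:rBot, c0:c1] <- TRUE
    neck <- neck & !mr
  }
  list(rel = rel, az = az, bz = bz, ect = ectAll, mr = mr, neck = neck)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Renders the phantom described by `spec` as a list of RGB section images
#' plus a [GroundTruth-class] holding per-section compartment labelings,
#' every rendered nucleus (centroid, compartment, BrdU status), per-section
#' contour annotations, the analytic rudiment volume, and the per-section
#' misalignment transforms (identity unless requested).  Lost sections are
#' omitted from the image list but retain their ground-truth entries.
#'
#' Output is fully deterministic: the same spec and seed give bit-identical
#' stacks.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `images` (list of `[row, col, 3]` arrays in
#'   `[0, 1]`, one per kept section), `truth` (a [GroundTruth-class]) and
#'   `depths` (cumulative depth in micrometres of each kept section).
#' @examples
#' ph <- generateStack(phantomSpec(nSections = 9, noiseSd = 0))
#' length(ph$images)
#' volume(ph$truth)
#' @export
generateStack <- function(spec) {
  validObject(spec)
  g <- .phantomGeometry(spec)
  n <- spec@nSections
  withSeed(spec@seed, {
    images <- vector("list", n)
    labelings <- vector("list", n)
    annotations <- vector("list", n)
    nucRows <- list()
    for (i in seq_len(n)) {
      z <- (i - 1) * spec@sectionThickness
      sm <- .sectionMasks(spec, g, z)
      isCentral <- abs(z - g$z0) <= spec@sectionThickness / 2
      comp <- .compartmentMasksForSection(spec, g, sm, isCentral)
      labelings[[i]] <- labelingFromMasks(comp$labels, c(g$H, g$W), g$px)
      annotations[[i]] <- comp$annotation
      nuc <- .placeSectionNuclei(spec, g, comp, i, z)
      nucRows[[i]] <- nuc
      images[[i]] <- .renderSection(spec, g, comp, nuc)
    }
    nuclei <- do.call(rbind, nucRows)
    rownames(nuclei) <- NULL
    vol <- 4 / 3 * pi * prod(spec@semiAxes) +
      pi * spec@neckRadius^2 * spec@neckLength
    kept <- setdiff(seq_len(n), spec@lostSections)
    images <- images[kept]
    transforms <- replicate(length(kept), similarityTransform(),
                            simplify = FALSE)
    if (any(spec@misalignment > 0)) {
      pert <- perturbStack(images,
                           maxShift = spec@misalignment[["shift"]],
                           maxRot = spec@misalignment[["rot"]],
                           maxScale = spec@misalignment[["scale"]],
                           seed = spec@seed + 1L)
      images <- pert$stack
      transforms <- pert$transforms
    }
    truth <- new("GroundTruth", labelings = labelings, nuclei = nuclei,
                 volume = vol, transforms = transforms,
                 annotations = annotations, spec = spec,
                 keptSections = as.integer(kept))
    list(images = images, truth = truth,
         depths = (kept - 1) * spec@sectionThickness)
  })
}

# ground-truth compartment masks + annotation for one section
.compartmentMasksForSection <- function(spec, g, sm, isCentral) {
  px <- g$px
  epith <- sm$mr | sm$neck
  # attachment gap: columns where the epithelium reaches the membrane
  touchRows <- which(epith[ceiling(g$mbRow + 0.5), ])
  if (length(touchRows)) gap <- range(touchRows) else gap <- c(g$cc, g$cc)
  cols <- seq_len(g$W)
  left <- sm$ect & matrix(cols < gap[1], g$H, g$W, byrow = TRUE)
  right <- sm$ect & matrix(cols > gap[2], g$H, g$W, byrow = TRUE)
  # ventral = left arm by convention
  labels <- list(v.ect = left, d.ect = right)
  annotation <- NULL
  if (any(sm$mr)) {
    bandR <- round(15 / px)
    band <- as.matrix(EBImage::dilate(epith, discBrush(bandR))) > 0.5
    band <- band & !epith & !sm$ect
    if (isCentral) {
      core <- .coreByDistance(sm$mr)
      labels$core <- core
      labels$periphery <- sm$mr & !core
    } else {
      labels$mr <- sm$mr
    }
    if (any(sm$neck)) labels$neck <- sm$neck
    labels$mamm.mes <- band
    # dermal window: between the (horizontal) line through the rudiment
    # center and a parallel line 65 um deeper
    win <- matrix(FALSE, g$H, g$W)
    w0 <- max(1L, ceiling(g$r0)); w1 <- min(g$H, floor(g$r0 + 65 / px))
    if (w0 <= w1) win[w0:w1, ] <- TRUE
    labels$derm.mes <- win & !epith & !band & !sm$ect
    mb <- cbind(rep(g$mbRow, 40), seq(1, g$W, length.out = 40))
    neckPoly <- NULL
    if (any(sm$neck)) {
      idx <- which(sm$neck, arr.ind = TRUE)
      neckPoly <- cbind(c(min(idx[, 1]) - 0.5, min(idx[, 1]) - 0.5,
                          max(idx[, 1]) + 0.5, max(idx[, 1]) + 0.5),
                        c(min(idx[, 2]) - 0.5, max(idx[, 2]) + 0.5,
                          max(idx[, 2]) + 0.5, min(idx[, 2]) - 0.5))
    }
    annotation <- new("AnnotationSet",
                      mrContour = ellipsePolygon(g$r0, g$cc, sm$bz, sm$az),
                      neckContour = neckPoly, basementMembrane = mb,
                      mrCenter = c(g$r0, g$cc), isCentralSection = isCentral,
                      ventralSide = "left", mesenchymeSplitLine = NULL)
  }
  # filler mesenchyme: rendered tissue below the membrane not in any
  # annotated compartment (nuclei there carry compartment NA)
  below <- matrix(FALSE, g$H, g$W)
  below[(ceiling(g$mbRow + 0.5)):(g$H), ] <- TRUE
  labelled <- Reduce(`|`, labels)
  list(labels = labels, annotation = annotation,
       filler = below & !labelled, tissue = sm$ect | below)
}

# dart-throwing nucleus placement within one section
.placeSectionNuclei <- function(spec, g, comp, section, z) {
  rad <- spec@nucleusRadius / g$px
  frac <- spec@brduFraction
  # map ground-truth compartments to nucleus classes
  classOf <- c(v.ect = "ectoderm", d.ect = "ectoderm", core = "core",
               periphery = "periphery", mr = "core", neck = "core",
               mamm.mes = "mesenchyme", derm.mes = "mesenchyme")
  rows <- list()
  place <- function(mask, cls, compName) {
    area <- sum(mask)
    if (area == 0) return(NULL)
    r <- rad[[cls]]
    nTarget <- round(spec@nucleusDensity * area / (pi * r^2))
    if (nTarget == 0) return(NULL)
    idx <- which(mask)
    cand <- idx[sample.int(length(idx), min(length(idx), 6 * nTarget),
                           replace = FALSE)]
    cr <- (cand - 1) %% g$H + 1
    cc <- (cand - 1) %/% g$H + 1
    minD <- if (spec@allowTouching) 1.4 * r else 2.3 * r
    keepR <- numeric(0); keepC <- numeric(0)
    for (k in seq_along(cand)) {
      if (length(keepR) >= nTarget) break
      if (!length(keepR) ||
          min((keepR - cr[k])^2 + (keepC - cc[k])^2) >= minD^2) {
        keepR <- c(keepR, cr[k]); keepC <- c(keepC, cc[k])
      }
    }
    nk <- length(keepR)
    if (!nk) return(NULL)
    data.frame(section = section, row = keepR, col = keepC, z_um = z,
               compartment = compName,
               brdu = stats::runif(nk) < frac[[cls]],
               radius_px = r, stringsAsFactors = FALSE)
  }
  for (nm in names(comp$labels)) {
    cls <- classOf[[nm]]
    rows[[nm]] <- place(comp$labels[[nm]], cls, nm)
  }
  rows$filler <- place(comp$filler, "mesenchyme", NA_character_)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(section = integer(), row = numeric(), col = numeric(),
                      z_um = numeric(), compartment = character(),
                      brdu = logical(), radius_px = numeric())
  out
}

# render one RGB section from its masks and nuclei
.renderSection <- function(spec, g, comp, nuc) {
  img <- array(0, c(g$H, g$W, 3))
  for (k in 1:3) {
    ch <- matrix(.palette$background[k], g$H, g$W)
    ch[comp$tissue] <- .palette$tissue[k]
    img[, , k] <- ch
  }
  if (nrow(nuc)) {
    blue <- matrix(FALSE, g$H, g$W)
    brown <- matrix(FALSE, g$H, g$W)
    for (j in seq_len(nrow(nuc))) {
      r <- nuc$radius_px[j]
      e <- 0.8 + 0.4 * ((nuc$row[j] * 7 + nuc$col[j] * 13) %% 10) / 10
      th <- ((nuc$row[j] * 3 + nuc$col[j]) %% 31) / 31 * pi
      if (nuc$brdu[j])
        brown <- fillEllipse(brown, nuc$row[j], nuc$col[j], r * e, r / e, th)
      else
        blue <- fillEllipse(blue, nuc$row[j], nuc$col[j], r * e, r / e, th)
    }
    blue <- blue & !brown   # DAB precipitate dominates where nuclei overlap
    for (k in 1:3) {
      ch <- img[, , k]
      ch[blue] <- .palette$negative[k]
      ch[brown] <- .palette$brdu[k]
      img[, , k] <- ch
    }
  }
  if (spec@noiseSd > 0) {
    img <- img + stats::rnorm(length(img), 0, spec@noiseSd)
    img[img < 0] <- 0; img[img > 1] <- 1
  }
  img
}

#' Misalign a section stack with recorded similarity transforms
#'
#' Applies one random (or supplied) non-reflective similarity transform per
#' section and records it; applying the recorded inverse restores the
#' original section up to interpolation error.  Used to exercise the
#' stack-registration stage.
#'
#' @param stack nonempty list of section images.
#' @param maxShift,maxRot,maxScale maxima of |translation| (px),
#'   |rotation| (rad) and |scale - 1| drawn uniformly per section.
#' @param seed RNG seed.
#' @param transforms optional list of [SimilarityTransform2D-class] to apply
#'   verbatim (recorded exactly as given); overrides the random draw.
#' @param fixFirst keep the first section as the untouched reference
#'   (identity transform).
#' @return list with `stack` (transformed images) and `transforms`.
#' @export
perturbStack <- function(stack, maxShift = 3, maxRot = 0.05,
                         maxScale = 0.02, seed = 1L, transforms = NULL,
                         fixFirst = TRUE) {
  if (!length(stack)) stop("empty stack")
  n <- length(stack)
  if (is.null(transforms)) {
    transforms <- withSeed(seed, lapply(seq_len(n), function(i) {
      if (i == 1L && fixFirst) return(similarityTransform())
      similarityTransform(
        s = 1 + stats::runif(1, -maxScale, maxScale),
        theta = stats::runif(1, -maxRot, maxRot),
        tx = stats::runif(1, -maxShift, maxShift),
        ty = stats::runif(1, -maxShift, maxShift))
    }))
  } else if (length(transforms) != n)
    stop("need one transform per section")
  out <- lapply(seq_len(n), function(i) {
    if (isIdentityTransform(transforms[[i]])) stack[[i]]
    else transformImage(stack[[i]], transforms[[i]], bg = 1)
  })
  list(stack = out, transforms = transforms)
}

#' Ground-truth area profile of a phantom rudiment
#'
#' Per-section epithelial area (rudiment + neck pixels, in square
#' micrometres) from the ground-truth labelings, for validating the
#' volumetry stage.  Areas are reported for all nominal sections, with the
#' lost flag set where sections are missing from the rendered stack.
#'
#' @param truth a [GroundTruth-class].
#' @return data.frame with `section`, `depth_um`, `area_um2`, `lost`.
#' @export
truthAreaProfile <- function(truth) {
  spec <- truth@spec
  epithCodes <- match(c("core", "periphery", "neck", "mr"), .compartments) - 1L
  areas <- vapply(truth@labelings, function(lb)
    sum(lb@map %in% epithCodes) * spec@pixelSize^2, numeric(1))
  n <- spec@nSections
  data.frame(section = seq_len(n),
             depth_um = (seq_len(n) - 1) * spec@sectionThickness,
             area_um2 = areas,
             lost = seq_len(n) %in% spec@lostSections)
}
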