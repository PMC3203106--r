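# 3D reconstruction from aligned serial sections: stack registration via
# control points, BrdU-positive nucleus extraction in an anisotropic voxel
# grid, splitting of touching nuclei, and iso-surface meshes.

#' Align a section stack to its first section
#'
#' Each section carries matched control points (typically two ectodermal
#' reference points plus the rudiment center); the non-reflective
#' similarity transform mapping a section's points onto the first
#' section's points is fitted by least squares and the section resampled
#' into the reference frame.  Sections without control points are skipped
#' with a warning.
#'
#' @param images list of section images (matrices or RGB arrays).
#' @param controlPoints list of n x 2 (row, col) matrices, one per
#'   section; `NULL` entries mark missing points.
#' @param reference index of the reference section (default 1).
#' @return list with `stack` (aligned images), `transforms` (per kept
#'   section) and `kept` (indices of retained sections).  A single-section
#'   stack is returned unchanged.
#' @export
alignStack <- function(images, controlPoints, reference = 1L) {
  n <- length(images)
  if (n == 0) stop("empty stack")
  if (n == 1)
    return(list(stack = images, transforms = list(similarityTransform()),
                kept = 1L))
  if (length(controlPoints) != n)
    stop("need control points for each section")
  if (is.null(controlPoints[[reference]]))
    stop("reference section has no control points")
  ref <- controlPoints[[reference]]
  kept <- integer(0); stack <- list(); transforms <- list()
  for (i in seq_len(n)) {
    if (is.null(controlPoints[[i]])) {
      warning("section ", i, " has no control points; skipped")
      next
    }
    tf <- fitSimilarity(controlPoints[[i]], ref)
    kept <- c(kept, i)
    transforms[[length(transforms) + 1L]] <- tf
    stack[[length(stack) + 1L]] <-
      if (isIdentityTransform(tf)) images[[i]]
      else transformImage(images[[i]], tf, bg = 1)
  }
  list(stack = stack, transforms = transforms, kept = kept)
}

# 26-connected labelling of a 3D logical array (graph components over
# face/edge/corner-adjacent foreground voxels)
.label3d <- function(mask) {
  d <- dim(mask)
  idx <- array(seq_along(mask), d)
  offs <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), ]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    r1 <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    c1 <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    z1 <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- mask[r1, c1, z1, drop = FALSE]
    b <- mask[r1 + o[1], c1 + o[2], z1 + o[3], drop = FALSE]
    both <- a & b
    if (!any(both)) next
    ia <- idx[r1, c1, z1, drop = FALSE][both]
    ib <- idx[r1 + o[1], c1 + o[2], z1 + o[3], drop = FALSE][both]
    edges[[length(edges) + 1L]] <- cbind(ia, ib)
  }
  fg <- which(mask)
  lab <- array(0L, d)
  if (!length(fg)) return(lab)
  vid <- integer(length(mask)); vid[fg] <- seq_along(fg)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::graph_from_edgelist(cbind(vid[e[, 1]], vid[e[, 2]]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_along(fg)
  lab[fg] <- as.integer(comp)
  lab
}

# squared Euclidean distance transform of one sampled line (lower envelope
# of parabolas); f holds squared distances so far, w the sample spacing
.dt1d <- function(f, w) {
  n <- length(f)
  if (n == 1) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  x <- (seq_len(n) - 1) * w
  for (q in 2:n) {
    s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    while (k > 1 && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + x[q]^2) - (f[v[k]] + x[v[k]]^2)) / (2 * x[q] - 2 * x[v[k]])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s; z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1L
    out[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  out
}

# anisotropy-aware squared EDT (distance to background) of a 3D mask
.edt3d <- function(mask, spacing) {
  d <- dim(mask)
  big <- sum((d * spacing)^2) * 4   # finite stand-in for +Inf
  f <- array(ifelse(mask, big, 0), d)
  for (ax in 1:3) {
    w <- spacing[ax]
    f <- apply(f, setdiff(1:3, ax), .dt1d, w = w)
    # apply() collapses the transformed axis to dim 1; restore order
    f <- aperm(array(f, c(d[ax], d[setdiff(1:3, ax)])),
               order(c(ax, setdiff(1:3, ax))))
  }
  f
}

#' Extract BrdU-positive nuclei as labelled 3D voxels
#'
#' Converts each aligned section to inverted grayscale (1 - luminance,
#' ITU-R BT.601 weights), thresholds the dark BrdU-positive pixels at a
#' fixed inverted-gray value (default 0.65), stacks the masks into an
#' anisotropic voxel grid, labels 26-connected components, and removes
#' components outside the expected nuclear size window.
#'
#' @param stack list of aligned RGB or grayscale sections.
#' @param threshold inverted-grayscale threshold in (0, 1).
#' @param spacing voxel spacing `c(pixel, pixel, section)` in micrometres.
#' @param sizeWindow `c(min, max)` component size in voxels; the default is
#'   0.3-3 times the single-section footprint of a nucleus of radius
#'   `nucleusRadiusUm`.
#' @param nucleusRadiusUm prior nuclear radius in micrometres.
#' @return a [NucleusSet-class].
#' @export
extractLabelVoxels <- function(stack, threshold = 0.65,
                               spacing = c(1, 1, 5), sizeWindow = NULL,
                               nucleusRadiusUm = 3) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (!length(stack)) stop("empty stack")
  if (is.null(sizeWindow)) {
    foot <- pi * nucleusRadiusUm^2 / (spacing[1] * spacing[2])
    sizeWindow <- c(0.3, 3) * foot
  }
  masks <- lapply(stack, function(im) {
    g <- if (length(dim(im)) == 3) luminance(im) else im
    (1 - g) > threshold
  })
  vox <- array(FALSE, c(dim(masks[[1]]), length(masks)))
  for (i in seq_along(masks)) vox[, , i] <- masks[[i]]
  lab <- .label3d(vox)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < sizeWindow[1] | sizes > sizeWindow[2])
    if (length(drop)) lab[lab %in% drop] <- 0L
    # compact ids
    old <- sort(unique(lab[lab > 0]))
    if (length(old)) lab[lab > 0] <- match(lab[lab > 0], old)
  }
  .nucleusSet(lab, spacing)
}

# build a NucleusSet from a label array
.nucleusSet <- function(lab, spacing) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids)) {
    w <- which(lab > 0)
    d <- dim(lab)
    r <- (w - 1) %% d[1] + 1
    cc <- ((w - 1) %/% d[1]) %% d[2] + 1
    z <- (w - 1) %/% (d[1] * d[2]) + 1
    id <- lab[w]
    tab <- data.frame(
      id = ids,
      row_um = tapply((r - 0.5) * spacing[1], id, mean)[as.character(ids)],
      col_um = tapply((cc - 0.5) * spacing[2], id, mean)[as.character(ids)],
      z_um = tapply((z - 0.5) * spacing[3], id, mean)[as.character(ids)],
      voxels = as.integer(tabulate(id)[ids]))
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(id = integer(), row_um = numeric(),
                      col_um = numeric(), z_um = numeric(),
                      voxels = integer())
  }
  new("NucleusSet", labels = lab, table = tab, spacing = spacing)
}

#' Split touching nuclei by distance-transform-seeded geodesic partition
#'
#' Fused components are split by an anisotropy-aware partition: seeds are
#' clustered local maxima of the 3D Euclidean distance transform (maxima
#' below `minSeedFrac` of the component's peak distance are suppressed),
#' and each voxel is assigned to its nearest seed in geodesic (within-mask)
#' distance.  Components with a single seed pass through unchanged, and
#' the union of the split labels equals the input foreground exactly.
#' This partition is a documented stand-in for evolving generalised
#' Voronoi diagram splitting, with the same seeded-partition goal.
#'
#' @param ns a [NucleusSet-class].
#' @param minSeedFrac suppression level for secondary distance maxima,
#'   as a fraction of the component's maximum distance.
#' @return a [NucleusSet-class] with fused components split.
#' @export
splitTouching <- function(ns, minSeedFrac = 0.6) {
  lab <- ns@labels
  d <- dim(lab)
  ids <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  nextId <- 1L
  for (i in ids) {
    w <- which(lab == i, arr.ind = FALSE)
    coords <- cbind((w - 1) %% d[1] + 1,
                    ((w - 1) %/% d[1]) %% d[2] + 1,
                    (w - 1) %/% (d[1] * d[2]) + 1)
    lo <- pmax(apply(coords, 2, min) - 1L, 1L)
    hi <- pmin(apply(coords, 2, max) + 1L, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == i
    dim(sub) <- hi - lo + 1L
    pieces <- .partitionComponent(sub, ns@spacing, minSeedFrac)
    np <- max(pieces)
    sel <- pieces > 0
    tgt <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dim(tgt) <- dim(pieces)
    tgt[sel] <- pieces[sel] + (nextId - 1L)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- tgt
    nextId <- nextId + np
  }
  .nucleusSet(out, ns@spacing)
}

# partition one cropped component into seeded geodesic regions
.partitionComponent <- function(sub, spacing, minSeedFrac) {
  d2 <- .edt3d(sub, spacing)
  dmax <- max(d2)
  # local maxima of the distance transform (>= all 26 neighbours)
  isMax <- sub & d2 >= (minSeedFrac^2) * dmax
  dd <- dim(sub)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    r1 <- max(1, 1 - o[1]):min(dd[1], dd[1] - o[1])
    c1 <- max(1, 1 - o[2]):min(dd[2], dd[2] - o[2])
    z1 <- max(1, 1 - o[3]):min(dd[3], dd[3] - o[3])
    nb <- array(0, dd)
    nb[r1, c1, z1] <- d2[r1 + o[1], c1 + o[2], z1 + o[3]]
    isMax <- isMax & d2 >= nb
    if (!any(isMax)) break
  }
  seeds <- .label3d(isMax)
  nSeeds <- max(seeds)
  if (nSeeds <= 1) return(array(as.integer(sub), dd))
  # multi-source geodesic assignment by iterated chamfer relaxation
  gdist <- array(Inf, dd)
  glab <- array(0L, dd)
  gdist[seeds > 0] <- 0
  glab[seeds > 0] <- seeds[seeds > 0]
  wlen <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                 (offs[, 3] * spacing[3])^2)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      r1 <- max(1, 1 - o[1]):min(dd[1], dd[1] - o[1])
      c1 <- max(1, 1 - o[2]):min(dd[2], dd[2] - o[2])
      z1 <- max(1, 1 - o[3]):min(dd[3], dd[3] - o[3])
      cand <- array(Inf, dd)
      cand[r1, c1, z1] <- gdist[r1 + o[1], c1 + o[2], z1 + o[3]] + wlen[k]
      better <- sub & cand < gdist
      if (any(better)) {
        changed <- TRUE
        gdist[better] <- cand[better]
        lsrc <- array(0L, dd)
        lsrc[r1, c1, z1] <- glab[r1 + o[1], c1 + o[2], z1 + o[3]]
        glab[better] <- lsrc[better]
      }
    }
    if (!changed) break
  }
  glab[!sub] <- 0L
  # voxels unreachable from any seed (shouldn't occur in a connected
  # component) keep a fallback assignment to seed 1
  glab[sub & glab == 0L] <- 1L
  glab
}

#' Iso-surface mesh of a binary voxel mask
#'
#' Triangulates the 0.5 level of the binary mask as the set of exposed
#' voxel faces in physical micrometre coordinates (voxel `i` spans
#' `[(i-1), i] * spacing` along each axis).  Faces are consistently wound
#' with outward normals, so the mesh is watertight and its signed volume
#' equals the voxel volume of the mask.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing voxel spacing in micrometres, `c(row, col, section)`.
#' @param tag tissue tag (`"ectoderm"`, `"MR"` or `"nuclei"`).
#' @return a [SurfaceMesh-class].
#' @export
isosurface <- function(mask, spacing = c(1, 1, 5), tag = "MR") {
  mask <- mask > 0.5
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  cornerId <- function(i, j, k) i + (d[1] + 1) * (j + (d[2] + 1) * k) + 1
  quads <- list()
  addFaces <- function(w, dpad, axis, positive) {
    # voxel (1-based in padded array); true voxel index = padded - 1
    r <- (w - 1) %% dpad[1]
    cc <- ((w - 1) %/% dpad[1]) %% dpad[2]
    z <- (w - 1) %/% (dpad[1] * dpad[2])
    # voxel spans corners (r-1..r, c-1..c, z-1..z) in 0-based corner coords
    x0 <- r - 1; x1 <- r; y0 <- cc - 1; y1 <- cc; z0 <- z - 1; z1 <- z
    if (axis == 1) { xf <- if (positive) x1 else x0
      A <- cornerId(xf, y0, z0); B <- cornerId(xf, y1, z0)
      C <- cornerId(xf, y1, z1); D <- cornerId(xf, y0, z1)
      if (!positive) { tmp <- B; B <- D; D <- tmp }
    } else if (axis == 2) { yf <- if (positive) y1 else y0
      A <- cornerId(x0, yf, z0); B <- cornerId(x0, yf, z1)
      C <- cornerId(x1, yf, z1); D <- cornerId(x1, yf, z0)
      if (!positive) { tmp <- B; B <- D; D <- tmp }
    } else { zf <- if (positive) z1 else z0
      A <- cornerId(x0, y0, zf); B <- cornerId(x1, y0, zf)
      C <- cornerId(x1, y1, zf); D <- cornerId(x0, y1, zf)
      if (!positive) { tmp <- B; B <- D; D <- tmp }
    }
    cbind(A, B, C, D)
  }
  dpad <- dim(pad)
  for (axis in 1:3) for (positive in c(TRUE, FALSE)) {
    o <- c(0L, 0L, 0L); o[axis] <- if (positive) 1L else -1L
    shifted <- array(FALSE, dpad)
    r1 <- max(1, 1 - o[1]):min(dpad[1], dpad[1] - o[1])
    c1 <- max(1, 1 - o[2]):min(dpad[2], dpad[2] - o[2])
    z1 <- max(1, 1 - o[3]):min(dpad[3], dpad[3] - o[3])
    shifted[r1, c1, z1] <- pad[r1 + o[1], c1 + o[2], z1 + o[3]]
    face <- which(pad & !shifted)
    if (length(face))
      quads[[length(quads) + 1L]] <- addFaces(face, dpad, axis, positive)
  }
  q <- do.call(rbind, quads)
  ids <- sort(unique(as.vector(q)))
  remap <- match(q, ids)
  dim(remap) <- dim(q)
  # corner id -> physical coordinates
  i <- (ids - 1) %% (d[1] + 1)
  j <- ((ids - 1) %/% (d[1] + 1)) %% (d[2] + 1)
  k <- (ids - 1) %/% ((d[1] + 1) * (d[2] + 1))
  verts <- cbind(i * spacing[1], j * spacing[2], k * spacing[3])
  faces <- rbind(remap[, c(1, 2, 3)], remap[, c(1, 3, 4)])
  new("SurfaceMesh", vertices = verts,
      faces = matrix(as.integer(faces), ncol = 3), tag = tag)
}

#' Signed volume enclosed by a surface mesh
#'
#' Divergence-theorem volume (sum of signed origin tetrahedra); positive
#' for a watertight mesh with outward normals.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return enclosed volume in cubic micrometres.
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}
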