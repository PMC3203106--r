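# Internal geometry and image helpers shared across modules.
#
# Image convention used throughout the package: a grayscale section is a
# numeric matrix [row, col] with values in [0, 1]; an RGB section is a numeric
# array [row, col, 3].  Row 1 is the top of the image (skin surface up in the
# standard transversal orientation); points are (row, col) pairs, 1-based.
# Section index i sits at cumulative depth (i - 1) * section thickness.

#' Luminance of an RGB image
#'
#' Converts an RGB array to luminance using ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B).
#'
#' @param img numeric array `[row, col, 3]` with values in `[0, 1]`.
#' @return numeric matrix of luminance values in `[0, 1]`.
#' @export
luminance <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB array [row, col, 3]")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Jaccard overlap of two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return intersection-over-union; 1 when both masks are empty.
#' @export
jaccardIndex <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards so library calls do not perturb user-level randomness.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Scanline (even-odd) polygon fill.  `poly` is an n x 2 matrix of (row, col)
# vertices of a closed polygon (last vertex implicitly joined to the first);
# pixel centers are at integer coordinates.  Returns a logical matrix.
fillPolygon <- function(poly, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  n <- nrow(poly)
  if (n < 3) return(out)
  ry <- poly[, 1]; cx <- poly[, 2]
  r0 <- max(1L, floor(min(ry))); r1 <- min(dim[1], ceiling(max(ry)))
  if (r0 > r1) return(out)
  jnext <- c(2:n, 1)
  for (r in r0:r1) {
    y1 <- ry; y2 <- ry[jnext]
    # edges crossing the scanline (half-open rule avoids double-counting
    # vertices lying exactly on the line)
    cross <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
    if (!any(cross)) next
    t <- (r - y1[cross]) / (y2[cross] - y1[cross])
    xs <- sort(cx[cross] + t * (cx[jnext][cross] - cx[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1L, ceiling(xs[k])); c1 <- min(dim[2], floor(xs[k + 1]))
      if (c0 <= c1) out[r, c0:c1] <- TRUE
    }
  }
  out
}

# Closed polygon approximating an ellipse (row0, col0 center; semi-axes in
# rows/cols; optional rotation in radians), as an n x 2 (row, col) matrix.
ellipsePolygon <- function(row0, col0, semiRow, semiCol, theta = 0, n = 72L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- semiRow * sin(t); c <- semiCol * cos(t)
  if (theta != 0) {
    rr <- r * cos(theta) - c * sin(theta)
    cc <- r * sin(theta) + c * cos(theta)
    r <- rr; c <- cc
  }
  cbind(row0 + r, col0 + c)
}

# Fill an ellipse directly into a logical matrix (faster than polygon fill
# for the many small nuclei the phantom renders).
fillEllipse <- function(mask, row0, col0, semiRow, semiCol, theta = 0) {
  rad <- max(semiRow, semiCol)
  r0 <- max(1L, floor(row0 - rad)); r1 <- min(nrow(mask), ceiling(row0 + rad))
  c0 <- max(1L, floor(col0 - rad)); c1 <- min(ncol(mask), ceiling(col0 + rad))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- (r0:r1) - row0
  cc <- (c0:c1) - col0
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  u <- R * cos(theta) + C * sin(theta)
  v <- -R * sin(theta) + C * cos(theta)
  inside <- (u / semiRow)^2 + (v / semiCol)^2 <= 1
  sub <- mask[r0:r1, c0:c1]
  mask[r0:r1, c0:c1] <- sub | inside
  mask
}

# Interpolate the row coordinate of an open polyline parameterised by column.
# Vertices are (row, col); columns outside the polyline's extent give NA.
polylineRowAt <- function(polyline, cols) {
  ord <- order(polyline[, 2])
  px <- polyline[ord, 2]; py <- polyline[ord, 1]
  stats::approx(px, py, xout = cols, rule = 1, ties = mean)$y
}

# Disc-shaped structuring element of the given pixel radius (odd width).
discBrush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Boundary of a binary mask (pixels in the mask adjacent to its complement).
maskBoundary <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box")) > 0.5
  mask & !er
}

# round() away from the banker's rule: the tables this package reproduces
# were rounded half-up, and printed-value comparisons must follow suit.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
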