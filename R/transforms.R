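# Non-reflective similarity transforms for serial-section registration.
#
# A transform acts on (row, col) points as p' = s R(theta) p + t with
# det(s R) = s^2 > 0.  In complex coordinates z = row + i col this is
# z' = alpha z + beta with alpha = s exp(i theta), which is what makes the
# least-squares control-point fit a plain linear regression.

#' Construct a non-reflective similarity transform
#'
#' @param s scale factor (> 0).
#' @param theta rotation in radians.
#' @param tx,ty translation along rows / columns in pixels.
#' @return a [SimilarityTransform2D-class] object.
#' @examples
#' tf <- similarityTransform(s = 1.02, theta = 0.05, tx = 3, ty = -2)
#' transformPoints(tf, cbind(10, 20))
#' @export
similarityTransform <- function(s = 1, theta = 0, tx = 0, ty = 0) {
  new("SimilarityTransform2D", s = s, theta = theta, tx = tx, ty = ty)
}

#' @rdname similarityTransform
#' @param object a transform.
#' @return `isIdentityTransform`: logical.
#' @export
isIdentityTransform <- function(object, tol = 1e-9) {
  abs(object@s - 1) < tol && abs(object@theta) < tol &&
    abs(object@tx) < tol && abs(object@ty) < tol
}

# 2 x 2 linear part in row-vector convention: p' = p %*% A + t
.linearPart <- function(tf) {
  tf@s * matrix(c(cos(tf@theta), sin(tf@theta),
                  -sin(tf@theta), cos(tf@theta)), 2, 2, byrow = TRUE)
}

#' Apply a similarity transform to points
#'
#' @param tf a [SimilarityTransform2D-class].
#' @param points n x 2 matrix of (row, col) points.
#' @return n x 2 matrix of transformed points.
#' @export
transformPoints <- function(tf, points) {
  points <- rbind(points)
  sweep(points %*% .linearPart(tf), 2, c(tf@tx, tf@ty), "+")
}

#' Compose two transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first,
#' then `a`.
#'
#' @param a,b transforms.
#' @return a [SimilarityTransform2D-class].
#' @export
composeTransforms <- function(a, b) {
  similarityTransform(
    s = a@s * b@s,
    theta = a@theta + b@theta,
    tx = a@s * (cos(a@theta) * b@tx - sin(a@theta) * b@ty) + a@tx,
    ty = a@s * (sin(a@theta) * b@tx + cos(a@theta) * b@ty) + a@ty)
}

#' Invert a transform
#'
#' @param tf a transform.
#' @return the inverse [SimilarityTransform2D-class]; composing a transform
#'   with its inverse gives the identity to floating-point precision.
#' @export
invertTransform <- function(tf) {
  s <- 1 / tf@s; th <- -tf@theta
  t2 <- -s * c(cos(th) * tf@tx - sin(th) * tf@ty,
               sin(th) * tf@tx + cos(th) * tf@ty)
  similarityTransform(s = s, theta = th, tx = t2[1], ty = t2[2])
}

#' Least-squares similarity transform from control-point pairs
#'
#' Fits the non-reflective similarity transform mapping `src` points onto
#' `dst` points, by complex linear regression (`dst = alpha src + beta`).
#' With three control points (two ectodermal reference points plus the
#' rudiment center, as used when registering consecutive sections) the fit
#' is exact whenever the pairs are truly similarity-related.
#'
#' @param src,dst n x 2 matrices of matched (row, col) points, n >= 3.
#' @return a [SimilarityTransform2D-class]; the mean squared residual is
#'   attached as attribute `"rss"`.
#' @export
fitSimilarity <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) != nrow(dst) || nrow(src) < 3)
    stop("need >= 3 matched control-point pairs")
  if (anyDuplicated(src) || anyDuplicated(dst))
    stop("duplicate control points")
  # collinearity: all cross products of edge vectors ~ 0
  v <- sweep(src, 2, src[1, ])
  cr <- v[2, 1] * v[, 2] - v[2, 2] * v[, 1]
  spread <- max(abs(v))
  if (spread == 0 || all(abs(cr) < 1e-9 * spread^2))
    stop("control points are collinear")
  zs <- complex(real = src[, 1], imaginary = src[, 2])
  zd <- complex(real = dst[, 1], imaginary = dst[, 2])
  ms <- mean(zs); md <- mean(zd)
  alpha <- sum(Conj(zs - ms) * (zd - md)) / sum(Mod(zs - ms)^2)
  beta <- md - alpha * ms
  tf <- similarityTransform(s = Mod(alpha), theta = Arg(alpha),
                            tx = Re(beta), ty = Im(beta))
  fit <- transformPoints(tf, src)
  attr(tf, "rss") <- sum((fit - dst)^2)
  tf
}

#' Resample an image under a similarity transform
#'
#' Applies the forward transform to the image content: a feature at point
#' `p` in the input appears at `transformPoints(tf, p)` in the output.
#' Bilinear interpolation for grayscale/RGB images, nearest-neighbour for
#' label masks.
#'
#' @param img numeric matrix or `[row, col, 3]` array.
#' @param tf a [SimilarityTransform2D-class].
#' @param filter `"bilinear"` or `"none"` (nearest-neighbour, for labels).
#' @param bg background fill value.
#' @return transformed image of the same shape.
#' @export
transformImage <- function(img, tf, filter = c("bilinear", "none"), bg = 0) {
  filter <- match.arg(filter)
  A <- .linearPart(tf)
  # EBImage::affine uses pixel centers at half-integers; shift the offset so
  # that a feature at 1-based point p lands exactly at transformPoints(tf, p)
  off <- c(tf@tx, tf@ty) + 0.5 * colSums(A) - 0.5
  m <- rbind(A, off)
  warp1 <- function(ch) {
    out <- EBImage::affine(ch, m, filter = filter, bg.col = bg,
                           output.dim = dim(ch))
    as.matrix(out)
  }
  if (length(dim(img)) == 3) {
    out <- img
    for (k in seq_len(dim(img)[3])) out[, , k] <- warp1(img[, , k])
    out
  } else warp1(img)
}
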