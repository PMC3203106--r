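# Rudiment volumetry from per-section epithelial areas.
#
# Epithelial area is measured on every consecutive section through the
# rudiment and plotted against cumulative section thickness; a
# Levenberg-Marquardt fit of a smooth unimodal model bridges lost
# sections, and the volume is the area under the fitted curve.

#' Build an area-versus-depth profile
#'
#' Section `i` (1-based) sits at cumulative depth `(i - 1) * thickness`
#' using nominal indices: lost sections leave gaps at their nominal depths,
#' they are never renumbered.
#'
#' @param areas per-section epithelial areas in square micrometres, one per
#'   nominal section (values at lost positions are ignored).
#' @param thickness section thickness in micrometres.
#' @param lost logical vector flagging lost sections (default none).
#' @return an [AreaProfile-class].
#' @export
buildProfile <- function(areas, thickness, lost = rep(FALSE, length(areas))) {
  if (length(lost) != length(areas))
    stop("lost flags must match the number of sections")
  if (any(areas[!lost] < 0)) stop("negative section area")
  if (thickness <= 0) stop("thickness must be > 0")
  depths <- (seq_along(areas) - 1) * thickness
  if (sum(!lost) < 3)
    stop("fewer than 3 sections: the fit is under-determined")
  new("AreaProfile",
      samples = data.frame(depth = depths[!lost], area = areas[!lost]),
      lostDepths = depths[lost], sectionThickness = thickness)
}

.profileModels <- list(
  gaussian = list(
    fn = function(z, p) p[["A"]] * exp(-(z - p[["z0"]])^2 / (2 * p[["sigma"]]^2)),
    formula = area ~ A * exp(-(depth - z0)^2 / (2 * sigma^2)),
    start = function(s) list(A = max(s$area),
                             z0 = s$depth[which.max(s$area)],
                             sigma = diff(range(s$depth)) / 4),
    integral = function(p) p[["A"]] * abs(p[["sigma"]]) * sqrt(2 * pi)),
  parabolic = list(
    fn = function(z, p) pmax(0, p[["k"]] * (p[["R"]]^2 - (z - p[["z0"]])^2)),
    formula = area ~ pmax(0, k * (R^2 - (depth - z0)^2)),
    start = function(s) {
      R0 <- diff(range(s$depth)) / 2
      list(k = max(s$area) / R0^2, z0 = s$depth[which.max(s$area)], R = R0)
    },
    integral = function(p) p[["k"]] * 4 / 3 * abs(p[["R"]])^3))

#' Fit an area profile and integrate the volume
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' [minpack.lm::nlsLM()]) of a smooth unimodal model to the area profile;
#' the volume is the analytic integral of the fitted curve over the depths
#' where it is non-negative.  The default `"gaussian"` model
#' `A exp(-(z - z0)^2 / (2 sigma^2))` suits dome-shaped rudiments; the
#' `"parabolic"` alternative `max(0, k (R^2 - (z - z0)^2))` is exact for
#' spherical (and ellipsoidal) specimens.  The model name is recorded in
#' the estimate for provenance.
#'
#' @param profile an [AreaProfile-class].
#' @param model `"gaussian"` or `"parabolic"`.
#' @param maxIter Levenberg-Marquardt iteration cap.
#' @param tol relative convergence tolerance on the parameters.
#' @return a [VolumeEstimate-class].
#' @export
fitProfile <- function(profile, model = c("gaussian", "parabolic"),
                       maxIter = 500, tol = 1e-8) {
  validObject(profile)
  model <- match.arg(model)
  s <- profile@samples
  if (all(s$area == 0))
    return(new("VolumeEstimate", model = model, pars = numeric(),
               volume = 0, rms = 0, nSamples = nrow(s)))
  m <- .profileModels[[model]]
  if (sum(s$area > 0) < 3)
    stop("non-convergence: fewer positive samples than model parameters",
         " (last residual RMS ", signif(stats::sd(s$area), 4), ")")
  fit <- tryCatch(
    minpack.lm::nlsLM(m$formula, data = s, start = m$start(s),
                      control = minpack.lm::nls.lm.control(
                        maxiter = maxIter, ptol = tol)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("non-convergence after ", maxIter, " iterations: ",
         conditionMessage(fit))
  p <- stats::coef(fit)
  vol <- m$integral(p)
  new("VolumeEstimate", model = model, pars = p, volume = vol,
      rms = sqrt(mean(stats::resid(fit)^2)), nSamples = nrow(s))
}

#' Evaluate a fitted profile model
#'
#' @param estimate a [VolumeEstimate-class].
#' @param depths depths (micrometres) at which to evaluate the fitted
#'   curve.
#' @return fitted areas (square micrometres).
#' @export
fittedCurve <- function(estimate, depths) {
  if (!length(estimate@pars)) return(rep(0, length(depths)))
  .profileModels[[estimate@model]]$fn(depths, estimate@pars)
}

#' Trapezoidal volume of a complete profile
#'
#' Baseline integration of the raw samples, defined only for complete
#' stacks (no lost sections); serves as the model-free reference the
#' curve-fit estimate is checked against.
#'
#' @param profile an [AreaProfile-class].
#' @return volume in cubic micrometres.
#' @export
trapezoidVolume <- function(profile) {
  if (length(profile@lostDepths))
    stop("trapezoidal volume is undefined with lost sections")
  s <- profile@samples
  pracma::trapz(s$depth, s$area)
}
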