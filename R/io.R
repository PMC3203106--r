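# Reading and writing the pipeline's external formats: numbered TIFF/PNG
# section stacks with JSON ground-truth sidecars, JSON contour annotations
# (0-based row/col, following the image-processing convention of the
# original tooling), CSV count and profile tables, PLY meshes and JSON
# transform logs.

#' Write a section stack to numbered image files
#'
#' @param stack list of RGB arrays in `[0, 1]`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, the written file paths.
#' @export
writeStack <- function(stack, dir, prefix = "section",
                       format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack))
  for (i in seq_along(stack)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d.%s", prefix, i, format))
    if (format == "png") png::writePNG(stack[[i]], paths[i])
    else tiff::writeTIFF(stack[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a numbered section stack
#'
#' @param dir directory of numbered `.png`/`.tif`/`.tiff` files.
#' @param pattern filename regular expression.
#' @return list of image arrays, in lexicographic filename order.
#' @export
readStack <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no section images found in ", dir)
  lapply(files, function(f) {
    if (grepl("png$", f)) png::readPNG(f) else tiff::readTIFF(f)
  })
}

# annotations: JSON uses 0-based (row, col) vertex lists
.annToList <- function(ann) {
  z <- function(m) if (is.null(m)) NULL else unname(m - 1)
  list(mr_contour = z(ann@mrContour),
       neck_contour = z(ann@neckContour),
       basement_membrane = z(ann@basementMembrane),
       mr_center = unname(ann@mrCenter - 1),
       is_central_section = ann@isCentralSection,
       ventral_side = ann@ventralSide,
       mesenchyme_split_line = z(ann@mesenchymeSplitLine))
}

.annFromList <- function(x) {
  m <- function(v) if (is.null(v) || !length(v)) NULL else
    matrix(unlist(v), ncol = 2, byrow = !is.matrix(v)) + 1
  mm <- function(v) { r <- m(v); if (is.null(r)) NULL else r }
  new("AnnotationSet",
      mrContour = m(x$mr_contour),
      neckContour = mm(x$neck_contour),
      basementMembrane = m(x$basement_membrane),
      mrCenter = unlist(x$mr_center) + 1,
      isCentralSection = isTRUE(x$is_central_section),
      ventralSide = if (is.null(x$ventral_side)) "left" else x$ventral_side,
      mesenchymeSplitLine = mm(x$mesenchyme_split_line))
}

#' Write / read per-section annotations as JSON
#'
#' Vertex coordinates are stored 0-based (row, col); `NULL` entries mark
#' sections without a rudiment.
#'
#' @param annotations list of [AnnotationSet-class] (or `NULL`s).
#' @param path JSON file path.
#' @return `readAnnotations` returns the list of annotations.
#' @export
writeAnnotations <- function(annotations, path) {
  jsonlite::write_json(lapply(annotations, function(a)
    if (is.null(a)) NULL else .annToList(a)), path,
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) if (is.null(x)) NULL else .annFromList(x))
}

#' Write per-compartment counts to CSV
#'
#' One row per (specimen, section, compartment), matching the tabulated
#' counts format.
#'
#' @param counts data.frame from [tabulateCompartments()], optionally with
#'   `specimen` / `section` columns prepended.
#' @param path CSV path.
#' @export
writeCountsCsv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' Read an area profile from CSV
#'
#' Expects columns `section_index`, `area_um2` and `lost` (plus optional
#' `depth_um`, ignored in favour of nominal indices).
#'
#' @param path CSV path.
#' @param thickness section thickness in micrometres.
#' @return an [AreaProfile-class].
#' @export
readAreaProfileCsv <- function(path, thickness) {
  d <- utils::read.csv(path)
  d <- d[order(d$section_index), ]
  buildProfile(d$area_um2, thickness, as.logical(d$lost))
}

#' Write a volume estimate and its fitted curve
#'
#' Writes the estimate as JSON and, optionally, sampled fitted-curve values
#' as CSV alongside.
#'
#' @param estimate a [VolumeEstimate-class].
#' @param path JSON path.
#' @param curveDepths optional depths at which to also write a
#'   `<path>_curve.csv` of fitted areas.
#' @export
writeVolumeEstimate <- function(estimate, path, curveDepths = NULL) {
  jsonlite::write_json(list(model = estimate@model,
                            pars = as.list(estimate@pars),
                            volume_um3 = estimate@volume,
                            rms_um2 = estimate@rms,
                            n_samples = estimate@nSamples),
                       path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curveDepths)) {
    utils::write.csv(data.frame(depth_um = curveDepths,
                                area_um2 = fittedCurve(estimate, curveDepths)),
                     sub("\\.json$", "_curve.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Write a transform log as JSON
#'
#' @param transforms list of [SimilarityTransform2D-class].
#' @param path JSON path.
#' @export
writeTransformLog <- function(transforms, path) {
  jsonlite::write_json(lapply(transforms, function(tf)
    list(s = tf@s, theta = tf@theta, tx = tf@tx, ty = tf@ty)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output `.ply` path.
#' @export
writeMeshPLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("comment tissue", mesh@tag),
               paste("element vertex", nrow(mesh@vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh@faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(mesh@vertices, con, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(cbind(3L, mesh@faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read segmentation/threshold parameters from a JSON config
#'
#' Reads a flat JSON object of parameter overrides and merges it over the
#' package defaults (`segmentationParams()` values plus threshold
#' settings), so analyses can pin their tunables in a version-controlled
#' file.
#'
#' @param path JSON file; missing keys keep their defaults.
#' @return named list with `segmentation` and `thresholds` components.
#' @export
readParamsJson <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- utils::modifyList(segmentationParams(),
                           cfg[names(cfg) %in% names(segmentationParams())])
  thr <- thresholdParams()
  thr[names(cfg)[names(cfg) %in% names(thr)]] <-
    cfg[names(cfg) %in% names(thr)]
  list(segmentation = seg, thresholds = thr)
}
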