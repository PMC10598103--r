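# Planar contour structure sets.
#
# Clinical delineations travel as planar closed polygons grouped by ROI
# name, with vertices as patient-coordinate (x, y, z) triplets where z is
# the slice position. This package ingests a plain-text JSON dialect of
# that layout (DICOM RT structure sets carry the same information in
# binary form):
#
#   {"frame_of_reference": "...",
#    "rois": [{"name": "GTV",
#              "contours": [{"points": [[x,y,z], [x,y,z], ...]}, ...]}]}
#
# The mapping to the package's (slice, row, column) convention is
# z -> slice position, y -> row mm, x -> column mm.

#' A closed planar contour polygon
#'
#' @param slice_position_mm position along the slice axis, in mm.
#' @param vertices numeric matrix with columns `(row_mm, col_mm)`; at
#'   least 3 rows; implicitly closed.
#' @return An object of class `contour_polygon`.
#' @export
contour_polygon <- function(slice_position_mm, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3)
    stop("a contour polygon needs at least 3 vertices")
  if (ncol(vertices) != 2 || anyNA(vertices))
    stop("'vertices' must be an n x 2 numeric matrix of (row_mm, col_mm)")
  structure(list(slice_position_mm = as.numeric(slice_position_mm),
                 vertices = unname(vertices)),
            class = "contour_polygon")
}

#' Parse a structure-set file
#'
#' Reads the JSON planar-contour dialect described above, groups contours
#' by ROI name, converts the patient-coordinate triplets to the package's
#' mm convention, and checks planarity: within one polygon the slice
#' coordinate may vary by at most 1e-3 mm.
#'
#' @param path a structure-set JSON file.
#' @return A list of class `structure_set`: `frame_of_reference` and
#'   `rois`, a named list (unique ROI names) of lists of
#'   [contour_polygon()].
#' @export
parse_structure_set <- function(path) {
  if (!file.exists(path)) stop("no such structure-set file: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("unreadable structure set ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(doc$rois)) stop("structure set without 'rois': ", path)
  rois <- list()
  for (roi in doc$rois) {
    nm <- roi$name
    if (is.null(nm)) stop("ROI without a name in ", path)
    if (nm %in% names(rois)) stop("duplicate ROI name '", nm, "' in ", path)
    if (is.null(roi$contours) || length(roi$contours) == 0)
      stop("ROI '", nm, "' has no contour data in ", path)
    polys <- lapply(roi$contours, function(ct) {
      pts <- ct$points
      if (is.null(pts) || length(pts) < 3)
        stop("ROI '", nm, "': contour with fewer than 3 points in ", path)
      m <- do.call(rbind, lapply(pts, function(p) as.numeric(unlist(p))))
      if (ncol(m) != 3 || anyNA(m))
        stop("ROI '", nm, "': points must be (x,y,z) triplets in ", path)
      z <- m[, 3]
      if (diff(range(z)) > 1e-3)
        stop(sprintf(
          "ROI '%s': non-planar contour (slice coordinate varies by %.4g mm) in %s",
          nm, diff(range(z)), path))
      contour_polygon(mean(z), cbind(m[, 2], m[, 1]))  # (row, col) = (y, x)
    })
    rois[[nm]] <- polys
  }
  structure(list(frame_of_reference = doc$frame_of_reference %||% "",
                 rois = rois),
            class = "structure_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a structure-set file
#'
#' Serialises ROIs to the JSON planar-contour dialect read by
#' [parse_structure_set()]. Used to synthesise fixtures and to export
#' contours produced by the cohort simulator.
#'
#' @param rois named list; each element a list of [contour_polygon()].
#' @param path output file.
#' @param frame_of_reference free-text frame-of-reference label.
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(rois, path, frame_of_reference = "synthetic") {
  doc <- list(
    frame_of_reference = frame_of_reference,
    rois = lapply(names(rois), function(nm) list(
      name = nm,
      contours = lapply(rois[[nm]], function(p) list(
        points = lapply(seq_len(nrow(p$vertices)), function(i)
          c(p$vertices[i, 2], p$vertices[i, 1], p$slice_position_mm))
      ))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
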