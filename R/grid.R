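#' Voxel lattice geometry
#'
#' An `image_grid` describes the voxel lattice that masks live on: the array
#' shape, the voxel spacing in millimetres, and the physical position of the
#' centre of voxel `(1,1,1)` (R indexing; index `(0,0,0)` in zero-based
#' terms). Axis order is fixed as (slice, row, column) throughout the
#' package, and the physical position of zero-based voxel index `(i,j,k)` is
#' `origin + (i,j,k) * spacing` componentwise (voxel-centre convention).
#'
#' @param shape integer vector of length 3, all `>= 1`; array extent along
#'   (slice, row, column).
#' @param spacing_mm numeric vector of length 3, all `> 0`; voxel pitch in mm.
#' @param origin_mm numeric vector of length 3; physical mm position of the
#'   centre of the first voxel. Defaults to `c(0, 0, 0)`.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 64), spacing_mm = c(3, 0.98, 0.98))
#' g
#' @export
image_grid <- function(shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (length(spacing_mm) != 3L || anyNA(spacing_mm) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive reals")
  if (length(origin_mm) != 3L || anyNA(origin_mm))
    stop("'origin_mm' must be three reals")
  structure(
    list(shape = shape, spacing_mm = spacing_mm, origin_mm = origin_mm),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf(
    "<image_grid> shape %s, spacing %s mm, origin (%s) mm\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$spacing_mm), collapse = "x"),
    paste(format(x$origin_mm), collapse = ", ")
  ))
  invisible(x)
}

#' Compare two grids within the package's geometry tolerances
#'
#' Grids are considered equal when shapes match exactly, spacings agree
#' within 1e-6 mm and origins within 1e-3 mm. The tolerances absorb format
#' round-trip noise without accepting genuinely different geometry.
#'
#' @param a,b `image_grid` objects.
#' @return `TRUE` or `FALSE`.
#' @export
grids_equal <- function(a, b) {
  stopifnot(inherits(a, "image_grid"), inherits(b, "image_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) <= 1e-6) &&
    all(abs(a$origin_mm - b$origin_mm) <= 1e-3)
}

# Stop with a message naming the first geometry component that differs.
check_same_grid <- function(a, b, what = "masks") {
  ga <- a$grid; gb <- b$grid
  if (!identical(ga$shape, gb$shape))
    stop(sprintf("grid mismatch between %s: shape %s vs %s", what,
                 paste(ga$shape, collapse = "x"),
                 paste(gb$shape, collapse = "x")))
  if (any(abs(ga$spacing_mm - gb$spacing_mm) > 1e-6))
    stop(sprintf("grid mismatch between %s: spacing (%s) vs (%s) mm", what,
                 paste(format(ga$spacing_mm), collapse = ", "),
                 paste(format(gb$spacing_mm), collapse = ", ")))
  if (any(abs(ga$origin_mm - gb$origin_mm) > 1e-3))
    stop(sprintf("grid mismatch between %s: origin (%s) vs (%s) mm", what,
                 paste(format(ga$origin_mm), collapse = ", "),
                 paste(format(gb$origin_mm), collapse = ", ")))
  invisible(TRUE)
}

# Physical mm coordinates of voxel centres along one axis (zero-based index).
axis_centers_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}
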