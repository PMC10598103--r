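#' Rasterize planar contour polygons to a binary mask
#'
#' A voxel is set iff its centre lies inside an odd number of that slice's
#' polygons (even-odd rule): disjoint polygons on a slice union, nested
#' polygons carve holes, with one rule covering both. A voxel centre
#' exactly on a polygon edge counts as inside regardless of parity, which
#' keeps the result deterministic across platforms and independent of
#' vertex orientation. Each polygon is assigned to the slice index whose
#' centre is nearest its slice position, provided that is within half a
#' slice spacing; otherwise the polygon is dropped with a warning. A
#' polygon that covers no voxel centre contributes nothing and is
#' reported with a warning.
#'
#' @param polys list of [contour_polygon()] (may be empty: empty mask).
#' @param grid an [image_grid()] to rasterize onto.
#' @return A [binary_mask()] on `grid`.
#' @export
rasterize_contours <- function(polys, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (length(polys) == 0) return(binary_mask(array(FALSE, grid$shape), grid))
  stopifnot(all(vapply(polys, inherits, logical(1), "contour_polygon")))
  sp <- grid$spacing_mm
  out <- array(FALSE, grid$shape)
  # row/col voxel-centre coordinate grids for one slice plane
  yy <- matrix(axis_centers_mm(grid, 2), grid$shape[2], grid$shape[3])
  xx <- matrix(axis_centers_mm(grid, 3), grid$shape[2], grid$shape[3],
               byrow = TRUE)
  slice_of <- integer(length(polys))
  for (pi in seq_along(polys)) {
    z <- polys[[pi]]$slice_position_mm
    i <- round((z - grid$origin_mm[1]) / sp[1])
    if (i < 0 || i > grid$shape[1] - 1 ||
        abs(z - (grid$origin_mm[1] + i * sp[1])) > sp[1] / 2 + 1e-9) {
      warning(sprintf(
        "contour at slice position %.3f mm is not within half a slice spacing of any slice; dropped",
        z), call. = FALSE)
      slice_of[pi] <- NA_integer_
    } else slice_of[pi] <- as.integer(i) + 1L
  }
  for (si in unique(slice_of[!is.na(slice_of)])) {
    parity <- matrix(FALSE, grid$shape[2], grid$shape[3])
    on_edge <- matrix(FALSE, grid$shape[2], grid$shape[3])
    for (pi in which(!is.na(slice_of) & slice_of == si)) {
      ins <- point_in_polygon_grid(polys[[pi]]$vertices, yy, xx)
      if (!any(ins$inside | ins$edge))
        warning("a contour polygon covers no voxel centre", call. = FALSE)
      parity <- xor(parity, ins$inside)
      on_edge <- on_edge | ins$edge
    }
    out[si, , ] <- parity | on_edge
  }
  binary_mask(out, grid)
}

# Vectorised crossing-number (even-odd) test of all points (yy, xx)
# against one polygon given as an n x 2 (row_mm, col_mm) vertex matrix.
# Returns strict-interior parity and an exact on-edge indicator; callers
# decide that on-edge means inside.
point_in_polygon_grid <- function(verts, yy, xx) {
  n <- nrow(verts)
  inside <- matrix(FALSE, nrow(yy), ncol(yy))
  edge <- matrix(FALSE, nrow(yy), ncol(yy))
  for (e in seq_len(n)) {
    y1 <- verts[e, 1]; x1 <- verts[e, 2]
    f <- if (e == n) 1L else e + 1L
    y2 <- verts[f, 1]; x2 <- verts[f, 2]
    # on-segment: zero cross product and parameter within the segment
    dy <- y2 - y1; dx <- x2 - x1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      cr <- (xx - x1) * dy - (yy - y1) * dx
      tt <- ((xx - x1) * dx + (yy - y1) * dy)
      tol <- 1e-9 * max(1, sqrt(len2))
      edge <- edge | (abs(cr) <= tol & tt >= -tol & tt <= len2 + tol)
    }
    if (dy != 0) {
      crosses <- (y1 > yy) != (y2 > yy)
      xi <- x1 + (yy - y1) / dy * dx
      inside <- xor(inside, crosses & (xx < xi))
    }
  }
  list(inside = inside, edge = edge)
}
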