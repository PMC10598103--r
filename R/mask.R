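#' Binary delineation mask on an image grid
#'
#' A `binary_mask` couples a logical 3-D array of voxel membership with the
#' [image_grid()] it lives on. It is the unit that all agreement metrics
#' consume; GTV, ITV and PTV delineations are all represented this way.
#' Empty masks are representable; metric operations that cannot handle them
#' say so explicitly.
#'
#' @param voxels logical array (or anything coercible) whose `dim` equals
#'   `grid$shape`; `TRUE` marks a delineated voxel.
#' @param grid an [image_grid()].
#' @return An object of class `binary_mask`.
#' @examples
#' g <- image_grid(c(5, 5, 5), c(1, 1, 1))
#' v <- array(FALSE, g$shape); v[2:3, 2:4, 2:3] <- TRUE
#' m <- binary_mask(v, g)
#' mask_volume_ml(m)
#' @export
binary_mask <- function(voxels, grid) {
  stopifnot(inherits(grid, "image_grid"))
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (is.null(dim(voxels)) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop(sprintf("voxel array dim %s does not match grid shape %s",
                 paste(dim(voxels), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  if (anyNA(voxels)) stop("'voxels' must not contain NA")
  structure(list(voxels = voxels, grid = grid), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d voxels set on %s grid, %.3f ml\n",
              sum(x$voxels), paste(x$grid$shape, collapse = "x"),
              mask_volume_ml(x)))
  invisible(x)
}

#' Volume of a mask in millilitres
#'
#' `voxel_count * prod(spacing_mm) / 1000`. Additive over disjoint masks on
#' the same grid.
#'
#' @param m a [binary_mask()].
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(m) {
  stopifnot(inherits(m, "binary_mask"))
  sum(m$voxels) * prod(m$grid$spacing_mm) / 1000
}

#' Voxelwise overlap counts for a mask pair
#'
#' Counts the confusion-matrix cells between two masks on an identical grid:
#' `tp = |A intersect B|`, `fp = |A \\ B|`, `fn = |B \\ A|`, and
#' `tn` the background remainder. All agreement metrics downstream use only
#' `tp`, `fp`, `fn`: true negatives are excluded, so padding the grid with
#' background never changes a metric.
#'
#' @param a,b [binary_mask()] objects on identical grids (within
#'   [grids_equal()] tolerances).
#' @return A list of class `overlap_counts` with integer-valued fields
#'   `tp`, `fp`, `fn`, `tn` summing to the grid's voxel count.
#' @examples
#' g <- image_grid(c(1, 1, 8), c(1, 1, 1))
#' a <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), g$shape), g)
#' b <- binary_mask(array(c(FALSE, FALSE, rep(TRUE, 4), FALSE, FALSE), g$shape), g)
#' overlap_counts(a, b)  # tp=2 fp=2 fn=2 tn=2
#' @export
overlap_counts <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  check_same_grid(a, b)
  tp <- sum(a$voxels & b$voxels)
  fp <- sum(a$voxels) - tp
  fn <- sum(b$voxels) - tp
  tn <- prod(a$grid$shape) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "overlap_counts")
}

#' @export
print.overlap_counts <- function(x, ...) {
  cat(sprintf("<overlap_counts> tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Nearest-neighbour resampling of a mask onto another grid
#'
#' Each target voxel takes the membership of the source voxel whose centre
#' is nearest (in physical mm) to the target voxel centre. Exact midpoints
#' break ties toward the lower source index. Target voxels whose centres
#' fall outside the source's physical extent (beyond half a voxel outside
#' the boundary voxel centres) become background. Resampling is an explicit
#' step -- metrics refuse mismatched grids rather than resampling silently,
#' because resampling can change metric values and must stay auditable.
#'
#' @param m a [binary_mask()].
#' @param target an [image_grid()] to resample onto.
#' @return A [binary_mask()] on `target`.
#' @export
resample_nearest <- function(m, target) {
  stopifnot(inherits(m, "binary_mask"), inherits(target, "image_grid"))
  src <- m$grid
  idx <- vector("list", 3L)
  ok <- vector("list", 3L)
  for (ax in 1:3) {
    # continuous source index of each target centre; ties at .5 go down
    pos <- axis_centers_mm(target, ax)
    cont <- (pos - src$origin_mm[ax]) / src$spacing_mm[ax]
    i <- ceiling(cont - 0.5)           # nearest, half-way -> lower index
    ok[[ax]] <- i >= 0 & i <= src$shape[ax] - 1L
    i[!ok[[ax]]] <- 0L
    idx[[ax]] <- i + 1L
  }
  out <- array(FALSE, target$shape)
  if (all(vapply(ok, any, logical(1)))) {
    sub <- m$voxels[idx[[1]][ok[[1]]], idx[[2]][ok[[2]]], idx[[3]][ok[[3]]],
                    drop = FALSE]
    out[ok[[1]], ok[[2]], ok[[3]]] <- sub
  }
  binary_mask(out, target)
}

#' Pad a mask with background voxels on every face
#'
#' Embeds the mask in a grid enlarged by `k` background voxels on each side
#' of every axis, keeping the physical position of every original voxel
#' (the origin moves by `-k * spacing`). Only `tn` changes; all agreement
#' metrics are invariant under this operation.
#'
#' @param m a [binary_mask()].
#' @param k non-negative integer padding width (voxels per face).
#' @return A [binary_mask()] on the enlarged grid.
#' @export
pad_mask <- function(m, k) {
  stopifnot(inherits(m, "binary_mask"), k >= 0)
  k <- as.integer(k)
  if (k == 0L) return(m)
  g <- m$grid
  ng <- image_grid(g$shape + 2L * k, g$spacing_mm,
                   g$origin_mm - k * g$spacing_mm)
  out <- array(FALSE, ng$shape)
  out[k + seq_len(g$shape[1]), k + seq_len(g$shape[2]),
      k + seq_len(g$shape[3])] <- m$voxels
  binary_mask(out, ng)
}

#' Construct a mask pair realizing prescribed overlap counts
#'
#' Builds two masks as intervals on a `1 x 1 x n` line grid (1 mm
#' spacing) whose overlap counts are exactly the requested `tp`, `fp`,
#' `fn` (plus `tn` trailing background voxels). Useful for reproducing
#' metric values that are forced by the count formulas.
#'
#' @param tp,fp,fn,tn non-negative integer overlap counts; `tp + fp + fn`
#'   must be positive.
#' @return List with [binary_mask()] elements `a` (the first `tp + fp`
#'   voxels) and `b` (voxels `fp + 1` through `fp + tp + fn`).
#' @examples
#' p <- line_mask_pair(tp = 3, fp = 1, fn = 1)
#' probabilistic_distance(p$a, p$b)  # 1/3
#' @export
line_mask_pair <- function(tp, fp, fn, tn = 0) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn > 0)
  n <- tp + fp + fn + tn
  g <- image_grid(c(1L, 1L, n), c(1, 1, 1))
  ia <- seq_len(tp + fp)                      # A first, overlap after A\B
  ib <- fp + seq_len(tp + fn)
  va <- array(FALSE, g$shape); va[1, 1, ia] <- TRUE
  vb <- array(FALSE, g$shape); if (tp + fn > 0) vb[1, 1, ib] <- TRUE
  list(a = binary_mask(va, g), b = binary_mask(vb, g))
}

# Zero-based inclusive bounding box of the union of set voxels across masks,
# expanded by `pad` voxels and clipped to the grid. NULL if all empty.
# The default pad of 0 keeps the crop -- and hence every floating-point
# operation downstream -- independent of how much background surrounds
# the masks (exact TN invariance).
union_bbox <- function(masks, pad = 0L) {
  g <- masks[[1]]$grid
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  any_set <- FALSE
  for (m in masks) {
    if (!any(m$voxels)) next
    any_set <- TRUE
    w <- which(m$voxels, arr.ind = TRUE)
    lo <- pmin(lo, apply(w, 2, min) - 1L)
    hi <- pmax(hi, apply(w, 2, max) - 1L)
  }
  if (!any_set) return(NULL)
  lo <- pmax(as.integer(lo) - pad, 0L)
  hi <- pmin(as.integer(hi) + pad, g$shape - 1L)
  list(lo = lo, hi = hi)
}

# Crop a mask to a bbox (zero-based inclusive), adjusting the grid origin so
# voxel centres keep their physical positions. Exact: tp/fp/fn and all
# voxel-centre distances are unchanged as long as the bbox covers all set
# voxels of both masks being compared.
crop_mask <- function(m, bbox) {
  g <- m$grid
  rs <- Map(function(l, h) (l:h) + 1L, bbox$lo, bbox$hi)
  ng <- image_grid(bbox$hi - bbox$lo + 1L, g$spacing_mm,
                   g$origin_mm + bbox$lo * g$spacing_mm)
  binary_mask(m$voxels[rs[[1]], rs[[2]], rs[[3]], drop = FALSE], ng)
}
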