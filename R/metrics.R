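#' @useDynLib segagree, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd rnorm runif
NULL

# Shared precondition for the overlap-based metrics: identical grids and at
# least one non-empty mask. Returns the overlap counts.
metric_counts <- function(a, b, metric) {
  check_same_grid(a, b)
  if (!any(a$voxels) && !any(b$voxels))
    stop(sprintf("%s is undefined when both masks are empty", metric))
  overlap_counts(a, b)
}

#' Dice-Sorensen coefficient
#'
#' The standard overlap metric of medical image segmentation,
#' `2*tp / (2*tp + fp + fn)`, in `[0, 1]`; higher is better agreement.
#' Equals 1 iff the masks are identical and non-empty, 0 iff disjoint.
#'
#' @param a,b [binary_mask()] objects on identical grids; not both empty.
#' @return Dice coefficient (dimensionless).
#' @seealso [jaccard()], [metric_quartet()]
#' @export
dice <- function(a, b) {
  cc <- metric_counts(a, b, "DSC")
  2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
}

#' Jaccard index
#'
#' `tp / (tp + fp + fn)`, in `[0, 1]`. Related to Dice by
#' `JCI = DSC / (2 - DSC)`.
#'
#' @inheritParams dice
#' @return Jaccard index (dimensionless).
#' @export
jaccard <- function(a, b) {
  cc <- metric_counts(a, b, "Jaccard index")
  cc$tp / (cc$tp + cc$fp + cc$fn)
}

#' Probabilistic distance
#'
#' For binary masks, `(fp + fn) / (2*tp)`: a probabilistic metric that
#' strongly penalises alignment errors -- a correctly sized but poorly
#' overlapping volume scores badly. Lower is better; 0 iff the masks are
#' identical and non-empty. Disjoint non-empty masks (`tp = 0`) yield
#' `+Inf`. Whenever `tp > 0` it satisfies the identity
#' `PBD = (1 - DSC) / DSC`.
#'
#' @inheritParams dice
#' @return Probabilistic distance (dimensionless, `>= 0`, possibly `Inf`).
#' @export
probabilistic_distance <- function(a, b) {
  cc <- metric_counts(a, b, "PBD")
  if (cc$tp == 0) return(Inf)
  (cc$fp + cc$fn) / (2 * cc$tp)
}

#' Volumetric similarity
#'
#' `1 - |fp - fn| / (2*tp + fp + fn)`, equivalently
#' `1 - ||A| - |B|| / (|A| + |B|)`: compares only the sizes of the two
#' delineations, assuming alignment is optimal -- overlap is not
#' considered. In `[0, 1]`; 1 whenever the volumes are equal (even if
#' disjoint), 0 iff exactly one mask is empty. Always `VS >= DSC`, with
#' equality iff `min(fp, fn) == 0`.
#'
#' @inheritParams dice
#' @return Volumetric similarity (dimensionless).
#' @export
volumetric_similarity <- function(a, b) {
  cc <- metric_counts(a, b, "VS")
  1 - abs(cc$fp - cc$fn) / (2 * cc$tp + cc$fp + cc$fn)
}

#' Symmetric Hausdorff distance in millimetres
#'
#' The outlier-sensitive spatial distance between two voxel sets:
#' `max(h(A,B), h(B,A))` where `h(A,B)` is the largest distance from a
#' voxel centre of A to its nearest voxel centre of B, measured in
#' physical mm with anisotropic spacing. Computed via an exact Euclidean
#' distance transform of each mask; the maximum (100th percentile)
#' directed distance is used, not HD95.
#'
#' @param a,b [binary_mask()] objects on identical grids, both non-empty.
#' @return Hausdorff distance in mm; 0 iff identical voxel sets.
#' @export
hausdorff_mm <- function(a, b) {
  check_same_grid(a, b)
  if (!any(a$voxels) || !any(b$voxels))
    stop("Hausdorff distance is undefined for an empty mask")
  bb <- union_bbox(list(a, b))        # distances only involve set voxels
  ca <- crop_mask(a, bb); cb <- crop_mask(b, bb)
  sp <- ca$grid$spacing_mm
  dta <- edt_sq(ca$voxels, dim(ca$voxels), sp)
  dtb <- edt_sq(cb$voxels, dim(cb$voxels), sp)
  sqrt(max(max(dtb[ca$voxels]), max(dta[cb$voxels])))
}

#' Brute-force symmetric Hausdorff distance (verification oracle)
#'
#' Direct `O(|A|*|B|)` max-min computation over all pairs of set voxel
#' centres. Mathematically identical to [hausdorff_mm()]; intended as an
#' independent check on small masks (up to a few thousand voxels each).
#'
#' @inheritParams hausdorff_mm
#' @return Hausdorff distance in mm.
#' @export
hausdorff_bruteforce_mm <- function(a, b) {
  check_same_grid(a, b)
  if (!any(a$voxels) || !any(b$voxels))
    stop("Hausdorff distance is undefined for an empty mask")
  sp <- a$grid$spacing_mm
  pa <- which(a$voxels, arr.ind = TRUE) %*% diag(sp)
  pb <- which(b$voxels, arr.ind = TRUE) %*% diag(sp)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  sqrt(max(apply(d2, 1, min), apply(d2, 2, min)))
}

#' The four-metric agreement quartet for one observer pair
#'
#' Computes DSC, symmetric Hausdorff distance (mm), probabilistic distance
#' and volumetric similarity on one shared set of overlap counts. The four
#' metrics integrate complementary aspects of delineation agreement:
#' overlap, spatial outliers, alignment, and volume.
#'
#' If exactly one mask is empty, DSC and VS are still defined (both 0) and
#' PBD is `+Inf`, but the Hausdorff distance is not: the returned record
#' carries `hd_mm = NA` and an `undefined` field naming it. Two empty
#' masks are an error.
#'
#' @inheritParams dice
#' @return A list of class `metric_quartet` with fields `dsc`, `hd_mm`,
#'   `pbd`, `vs`, and `undefined` (character vector of metrics that could
#'   not be computed, usually empty).
#' @examples
#' g <- image_grid(c(1, 1, 8), c(1, 1, 1))
#' a <- binary_mask(array(seq_len(8) <= 4, g$shape), g)
#' b <- binary_mask(array(seq_len(8) >= 3 & seq_len(8) <= 6, g$shape), g)
#' metric_quartet(a, b)
#' @export
metric_quartet <- function(a, b) {
  cc <- metric_counts(a, b, "metric quartet")
  dsc <- 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
  vs <- 1 - abs(cc$fp - cc$fn) / (2 * cc$tp + cc$fp + cc$fn)
  pbd <- if (cc$tp == 0) Inf else (cc$fp + cc$fn) / (2 * cc$tp)
  undefined <- character()
  if (any(a$voxels) && any(b$voxels)) {
    hd <- hausdorff_mm(a, b)
  } else {
    hd <- NA_real_
    undefined <- "hd_mm"
  }
  structure(list(dsc = dsc, hd_mm = hd, pbd = pbd, vs = vs,
                 undefined = undefined),
            class = "metric_quartet")
}

#' @export
print.metric_quartet <- function(x, ...) {
  cat(sprintf("<metric_quartet> DSC %.4f | HD %.4f mm | PBD %s | VS %.4f\n",
              x$dsc, x$hd_mm,
              if (is.infinite(x$pbd)) "Inf" else sprintf("%.4f", x$pbd),
              x$vs))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
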