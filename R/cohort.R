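VOLUME_KINDS <- c("GTV", "ITV", "PTV")

#' One observer's delineation of one volume kind for one case
#'
#' @param case_id,observer_id character labels.
#' @param volume_kind one of `"GTV"`, `"ITV"`, `"PTV"`.
#' @param mask a [binary_mask()].
#' @return An object of class `delineation_record`.
#' @export
delineation_record <- function(case_id, observer_id, volume_kind, mask) {
  volume_kind <- match.arg(volume_kind, VOLUME_KINDS)
  stopifnot(inherits(mask, "binary_mask"))
  structure(list(case_id = as.character(case_id),
                 observer_id = as.character(observer_id),
                 volume_kind = volume_kind, mask = mask),
            class = "delineation_record")
}

#' Multi-observer structure-set cohort
#'
#' The case x observer x volume-kind collection of delineations that the
#' pairwise engine consumes. Validates that within each (case, kind) group
#' all masks share an identical grid (within [grids_equal()] tolerances)
#' and that no (case, observer, kind) combination appears twice. Ragged
#' participation -- observers who did not submit every volume -- is
#' allowed and handled downstream.
#'
#' @param records list of [delineation_record()] objects.
#' @return An object of class `cohort_structure_set`.
#' @export
cohort_structure_set <- function(records) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "delineation_record")))
  key <- vapply(records, function(r)
    paste(r$case_id, r$observer_id, r$volume_kind, sep = "\r"), character(1))
  if (anyDuplicated(key))
    stop("duplicate (case, observer, volume_kind) record: ",
         gsub("\r", "/", key[duplicated(key)][1]))
  grp <- vapply(records, function(r)
    paste(r$case_id, r$volume_kind, sep = "\r"), character(1))
  for (gname in unique(grp)) {
    rs <- records[grp == gname]
    for (i in seq_along(rs)[-1]) {
      if (!grids_equal(rs[[1]]$mask$grid, rs[[i]]$mask$grid))
        check_same_grid(rs[[1]]$mask, rs[[i]]$mask,
                        what = sprintf("observers %s and %s (%s)",
                                       rs[[1]]$observer_id,
                                       rs[[i]]$observer_id,
                                       gsub("\r", " ", gname)))
    }
  }
  structure(list(records = records), class = "cohort_structure_set")
}

#' @export
print.cohort_structure_set <- function(x, ...) {
  cases <- unique(vapply(x$records, `[[`, character(1), "case_id"))
  obs <- unique(vapply(x$records, `[[`, character(1), "observer_id"))
  cat(sprintf("<cohort_structure_set> %d records | %d cases | %d observers\n",
              length(x$records), length(cases), length(obs)))
  invisible(x)
}

# Records for one (case, kind) group, sorted by observer id.
cohort_group <- function(cohort, case_id, volume_kind) {
  rs <- Filter(function(r) r$case_id == case_id && r$volume_kind == volume_kind,
               cohort$records)
  rs[order(vapply(rs, `[[`, character(1), "observer_id"))]
}

cohort_cases <- function(cohort) {
  sort(unique(vapply(cohort$records, `[[`, character(1), "case_id")))
}
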