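#' All-pairs interobserver comparison for one case and volume kind
#'
#' Computes the four-metric quartet for every unordered pair of observers
#' who submitted the given volume kind for the given case -- all
#' comparisons between all experts, each pair once, `choose(n, 2)` rows
#' for `n` observers. Observers who did not submit this volume are
#' omitted; the omission is reported via a message with counts.
#'
#' Internally all masks of the group are cropped to their common bounding
#' box (plus one voxel) before the pairwise sweep; true negatives carry no
#' information for any of the metrics, so this is exact.
#'
#' @param cohort a [cohort_structure_set()].
#' @param case_id case label.
#' @param volume_kind `"GTV"`, `"ITV"` or `"PTV"`.
#' @return A `data.frame` of class `pairwise_results` with columns
#'   `case_id`, `volume_kind`, `observer_a`, `observer_b` (canonical sorted
#'   order), `dsc`, `hd_mm`, `pbd`, `vs`.
#' @export
all_pairs <- function(cohort, case_id, volume_kind) {
  stopifnot(inherits(cohort, "cohort_structure_set"))
  volume_kind <- match.arg(volume_kind, VOLUME_KINDS)
  rs <- cohort_group(cohort, case_id, volume_kind)
  if (length(rs) < 2)
    stop(sprintf("need >= 2 observers for case '%s' %s, found %d",
                 case_id, volume_kind, length(rs)))
  all_obs <- unique(vapply(cohort$records, `[[`, character(1), "observer_id"))
  if (length(rs) < length(all_obs))
    message(sprintf("case '%s' %s: %d of %d observers submitted; %d omitted",
                    case_id, volume_kind, length(rs), length(all_obs),
                    length(all_obs) - length(rs)))
  masks <- lapply(rs, `[[`, "mask")
  obs <- vapply(rs, `[[`, character(1), "observer_id")
  bb <- union_bbox(masks)
  if (!is.null(bb)) masks <- lapply(masks, crop_mask, bbox = bb)
  # cache the distance transform of each mask once per group
  dts <- vector("list", length(masks))
  need_dt <- vapply(masks, function(m) any(m$voxels), logical(1))
  for (i in seq_along(masks)) {
    if (need_dt[i])
      dts[[i]] <- edt_sq(masks[[i]]$voxels, dim(masks[[i]]$voxels),
                         masks[[i]]$grid$spacing_mm)
  }
  n <- length(masks)
  rows <- vector("list", n * (n - 1) / 2)
  r <- 0L
  for (i in seq_len(n - 1)) {
    vi <- masks[[i]]$voxels
    for (j in (i + 1):n) {
      vj <- masks[[j]]$voxels
      tp <- sum(vi & vj)
      fp <- sum(vi) - tp
      fn <- sum(vj) - tp
      if (tp + fp + fn == 0)
        stop(sprintf("both masks empty for observers %s and %s (case '%s' %s)",
                     obs[i], obs[j], case_id, volume_kind))
      dsc <- 2 * tp / (2 * tp + fp + fn)
      vs <- 1 - abs(fp - fn) / (2 * tp + fp + fn)
      pbd <- if (tp == 0) Inf else (fp + fn) / (2 * tp)
      hd <- if (need_dt[i] && need_dt[j])
        sqrt(max(max(dts[[j]][vi]), max(dts[[i]][vj]))) else NA_real_
      r <- r + 1L
      rows[[r]] <- data.frame(case_id = case_id, volume_kind = volume_kind,
                              observer_a = min(obs[i], obs[j]),
                              observer_b = max(obs[i], obs[j]),
                              dsc = dsc, hd_mm = hd, pbd = pbd, vs = vs,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$observer_a, out$observer_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pairwise_results", "data.frame")
  out
}

METRIC_COLS <- c("dsc", "hd_mm", "pbd", "vs")

#' Five-statistic agreement summary of pairwise results
#'
#' Aggregates a table of pairwise metric quartets into the
#' minimum / maximum / mean / median / std block reported per metric.
#' The median uses midpoint interpolation for even counts; the standard
#' deviation is the sample (`n - 1`) form, reported as 0 for a single
#' pair. Infinite probabilistic distances (disjoint pairs) are excluded
#' from mean and std with a warning, but participate in min, max and
#' median as the largest value.
#'
#' @param results a `pairwise_results` data frame from [all_pairs()] (or
#'   several, row-bound).
#' @return A `data.frame` of class `agreement_summary`: one row per metric,
#'   columns `metric`, `minimum`, `maximum`, `mean`, `median`, `std`,
#'   `n_pairs`.
#' @export
summarize_pairs <- function(results) {
  if (is.null(results) || nrow(results) == 0)
    stop("cannot summarize an empty set of pairwise results")
  out <- lapply(METRIC_COLS, function(mc) {
    v <- results[[mc]]
    fin <- v[is.finite(v)]
    if (length(fin) < length(v[!is.na(v)]))
      warning(sprintf(
        "%d infinite %s value(s) excluded from mean/std (kept for min/max/median)",
        sum(is.infinite(v)), mc), call. = FALSE)
    v <- v[!is.na(v)]
    data.frame(metric = mc,
               minimum = min(v), maximum = max(v),
               mean = mean(fin),
               median = stats::median(v),
               std = if (length(fin) > 1) stats::sd(fin) else 0,
               n_pairs = nrow(results),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("agreement_summary", "data.frame")
  out
}

#' Pooled agreement summary across all cases for one volume kind
#'
#' Concatenates the pairwise results of every eligible case (those with at
#' least two observers for the kind) and summarises the pooled values --
#' not a mean of per-case summaries.
#'
#' @param cohort a [cohort_structure_set()].
#' @param volume_kind `"GTV"`, `"ITV"` or `"PTV"`.
#' @return An `agreement_summary` data frame.
#' @export
pooled_summary <- function(cohort, volume_kind) {
  volume_kind <- match.arg(volume_kind, VOLUME_KINDS)
  parts <- list()
  for (cs in cohort_cases(cohort)) {
    if (length(cohort_group(cohort, cs, volume_kind)) >= 2)
      parts[[cs]] <- all_pairs(cohort, cs, volume_kind)
  }
  if (length(parts) == 0)
    stop(sprintf("no case with >= 2 observers for %s", volume_kind))
  summarize_pairs(do.call(rbind, parts))
}

#' Full interobserver-variability report
#'
#' The cohort-level report: for each volume kind (GTV, ITV, PTV) a pooled
#' all-patients block plus one block per case, each holding the
#' five-statistic summary of all pairwise comparisons, together with
#' per-case volume statistics (median and range in ml). Volume kinds with
#' fewer than two observers everywhere are reported as absent, not errors.
#' Row order is deterministic: cases in lexical order, kinds GTV < ITV <
#' PTV.
#'
#' @param cohort a [cohort_structure_set()].
#' @return A list of class `ioa_report`: per kind, `pooled` and `cases`
#'   summaries plus `volumes_ml` (per-case median/min/max/n); metadata
#'   records the median and std conventions.
#' @export
table1_report <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_structure_set"))
  kinds <- list()
  for (vk in VOLUME_KINDS) {
    per_case <- list()
    pooled_parts <- list()
    vols <- list()
    for (cs in cohort_cases(cohort)) {
      rs <- cohort_group(cohort, cs, vk)
      if (length(rs) >= 1) {
        v <- vapply(rs, function(r) mask_volume_ml(r$mask), numeric(1))
        vols[[cs]] <- list(median_ml = stats::median(v), min_ml = min(v),
                           max_ml = max(v), n_observers = length(rs))
      }
      if (length(rs) >= 2) {
        pr <- all_pairs(cohort, cs, vk)
        per_case[[cs]] <- summarize_pairs(pr)
        pooled_parts[[cs]] <- pr
      }
    }
    if (length(pooled_parts) == 0) next  # kind absent from the report
    kinds[[vk]] <- list(
      pooled = summarize_pairs(do.call(rbind, pooled_parts)),
      cases = per_case,
      volumes_ml = vols
    )
  }
  structure(list(
    kinds = kinds,
    metadata = list(
      median = "midpoint interpolation for even counts",
      std = "sample (n-1)",
      rounding = "half-even to 2 decimals at serialization only"
    )
  ), class = "ioa_report")
}

#' Flatten a report to the tabular serialization layout
#'
#' One row per (volume kind, scope, statistic); metric values rounded
#' half-even to `digits` decimals. `scope` is `"all"` for the pooled block
#' or the case id.
#'
#' @param report an `ioa_report` from [table1_report()].
#' @param digits rounding applied at this serialization step (default 2,
#'   matching the reporting convention; internal values are never rounded).
#' @return A `data.frame` with columns `volume_kind`, `scope`, `statistic`,
#'   `dsc`, `hd_mm`, `pbd`, `vs`, `n_pairs`.
#' @export
report_to_table <- function(report, digits = 2) {
  stopifnot(inherits(report, "ioa_report"))
  stats_names <- c("minimum", "maximum", "mean", "median", "std")
  rows <- list()
  for (vk in names(report$kinds)) {
    blk <- report$kinds[[vk]]
    scopes <- c(list(all = blk$pooled), blk$cases)
    for (sc in names(scopes)) {
      s <- scopes[[sc]]
      for (st in stats_names) {
        vals <- vapply(METRIC_COLS, function(mc)
          round(s[[st]][s$metric == mc], digits), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          volume_kind = vk, scope = sc, statistic = st,
          dsc = vals["dsc"], hd_mm = vals["hd_mm"], pbd = vals["pbd"],
          vs = vals["vs"], n_pairs = s$n_pairs[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report to CSV or JSON
#'
#' CSV uses the flat [report_to_table()] layout. JSON serialises the
#' nested structure (kinds, per-case volume statistics, metadata) with the
#' same 2-decimal rounding; infinite values become the string `"Inf"`.
#' Output is deterministic: identical cohorts yield byte-identical files.
#'
#' @param report an `ioa_report`.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param digits rounding at serialization (default 2).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, digits = 2) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rounded <- rapply(unclass(report), function(x) {
      if (is.numeric(x)) {
        x <- round(x, digits)
        if (any(is.infinite(x))) x <- ifelse(is.infinite(x), "Inf", x)
      }
      x
    }, how = "replace")
    jsonlite::write_json(rounded, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  } else {
    tab <- report_to_table(report, digits = digits)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a CSV report written by [write_report()]
#'
#' @param path a CSV written by [write_report()].
#' @return The flat report `data.frame`.
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
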