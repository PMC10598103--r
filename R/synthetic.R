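# Synthetic multi-observer cohort generator.
#
# The study this pipeline serves deposited no imaging data, so agreement
# computations are exercised on synthetic cohorts that emulate its scale:
# three cases, up to 19 observers, GTV volumes near the per-case medians
# (31.75 / 45.3 / 45.7 ml), ITVs as respiratory motion envelopes of the
# GTVs, PTVs as margin expansions of the ITVs, and tunable interobserver
# boundary noise. Tumours are star-convex: a radius field over directions
# from a fixed centre, r(d) = r0 + sum c_lm Y_lm(d) in mm, perturbed by
# low-order spherical harmonics. That keeps every construction seedable,
# supports exact containment logic, and has analytic sphere limits.

#' Template for one synthetic case
#'
#' @param case_id case label.
#' @param gtv_volume_ml target median GTV volume in ml.
#' @param shape,spacing_mm,origin_mm grid geometry (default 128^3 voxels
#'   at 2 mm isotropic).
#' @param motion_amplitude_mm respiratory motion amplitude per axis in the
#'   package's (slice, row, column) order; default `c(5, 0, 0)`,
#'   slice-axis (cranio-caudal) dominant.
#' @param n_phases number of respiratory phases for the ITV envelope
#'   (default 10, the usual 4D-CT binning).
#' @param ptv_margin_mm isotropic ITV-to-PTV margin (default 5 mm, a
#'   typical SBRT-scale setup margin).
#' @return An object of class `case_template`.
#' @export
case_template <- function(case_id, gtv_volume_ml,
                          shape = c(128L, 128L, 128L),
                          spacing_mm = c(2, 2, 2),
                          origin_mm = c(0, 0, 0),
                          motion_amplitude_mm = c(5, 0, 0),
                          n_phases = 10L,
                          ptv_margin_mm = 5) {
  stopifnot(gtv_volume_ml > 0, ptv_margin_mm >= 0, n_phases >= 1)
  structure(list(case_id = as.character(case_id),
                 gtv_volume_ml = gtv_volume_ml,
                 grid = image_grid(shape, spacing_mm, origin_mm),
                 motion_amplitude_mm = as.numeric(motion_amplitude_mm),
                 n_phases = as.integer(n_phases),
                 ptv_margin_mm = ptv_margin_mm),
            class = "case_template")
}

#' The three default study-scale case templates
#'
#' GTV volume targets are the per-case median GTV volumes the cohort
#' emulates: 31.75, 45.3 and 45.7 ml.
#'
#' @param shape,spacing_mm grid geometry shared by the three cases.
#' @return List of three [case_template()]s with case ids "1", "2", "3".
#' @export
default_case_templates <- function(shape = c(128L, 128L, 128L),
                                   spacing_mm = c(2, 2, 2)) {
  vols <- c("1" = 31.75, "2" = 45.3, "3" = 45.7)
  lapply(names(vols), function(id)
    case_template(id, vols[[id]], shape = shape, spacing_mm = spacing_mm))
}

#' Observer perturbation model
#'
#' One observer's deviation from the underlying true shape: a systematic
#' margin (`systematic_bias_mm`, a uniform radius offset -- positive for
#' over-contourers) plus a smooth zero-mean random radial field of
#' pointwise standard deviation `roughness_mm` (spherical harmonics of
#' degree at most 6).
#'
#' @param observer_id observer label.
#' @param systematic_bias_mm uniform radial offset in mm.
#' @param roughness_mm pointwise sd of the smooth perturbation field, mm.
#' @param seed integer seed for the field coefficients.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(observer_id, systematic_bias_mm = 0,
                           roughness_mm = 0, seed = 1L) {
  stopifnot(roughness_mm >= 0)
  structure(list(observer_id = as.character(observer_id),
                 systematic_bias_mm = systematic_bias_mm,
                 roughness_mm = roughness_mm,
                 seed = as.integer(seed)),
            class = "observer_model")
}

#' Cohort simulation configuration
#'
#' @param n_observers number of observers per case (default 19, the
#'   number of structure sets per case the emulated study evaluated).
#' @param templates list of [case_template()]s (default: the three
#'   study-scale cases).
#' @param sigma_bias_mm sd of the per-observer systematic bias (default
#'   1.5 mm).
#' @param roughness_mm pointwise sd of each observer's smooth boundary
#'   perturbation (default 2 mm). The (1.5, 2) defaults put median
#'   pairwise GTV Dice in the observed 0.70-0.90 band.
#' @param base_seed master seed; every per-observer seed derives from it
#'   as `base_seed * 10000 + case_index * 100 + observer_index` (keep
#'   `base_seed` below ~214000 so derived seeds stay in integer range).
#' @param participation probability that a non-first observer submits any
#'   given record (default 1: full participation). Values below 1 emulate
#'   the study's ragged participation.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_observers = 19L,
                              templates = default_case_templates(),
                              sigma_bias_mm = 1.5,
                              roughness_mm = 2,
                              base_seed = 42L,
                              participation = 1) {
  stopifnot(n_observers >= 2, sigma_bias_mm >= 0, roughness_mm >= 0,
            participation > 0, participation <= 1)
  if (base_seed * 10000 + (length(templates) + 1) * 100 + n_observers >
      .Machine$integer.max)
    stop("base_seed too large for the seed-derivation formula")
  structure(list(n_observers = as.integer(n_observers),
                 templates = templates,
                 sigma_bias_mm = sigma_bias_mm,
                 roughness_mm = roughness_mm,
                 base_seed = as.integer(base_seed),
                 participation = participation),
            class = "cohort_sim_config")
}

# Rasterise a star-convex shape: voxel set iff the distance of its centre
# from `center_mm` is at most r0 + B(direction) %*% coef_mm (absolute mm
# radius field, basis degrees 1..lmax). Only a bounding box of half-width
# max radius is visited; exceeding the grid is an error. Radii below
# `min_radius_mm` are clipped with a warning.
star_shape_mask <- function(grid, center_mm, r0_mm, lmax, coef_mm,
                            min_radius_mm = min(grid$spacing_mm)) {
  # |sum c Y(d)| <= sqrt(sum c^2) * sqrt(sum Y(d)^2) and the addition
  # theorem gives sum_{l,m} Y_lm(d)^2 = sum_l (2l+1)/(4 pi) exactly
  fbound <- sqrt(sum(coef_mm^2) * sph_field_var_unit(max(lmax, 1)))
  rmax <- r0_mm + fbound + max(grid$spacing_mm)
  lo <- hi <- integer(3)
  for (ax in 1:3) {
    c0 <- (center_mm[ax] - grid$origin_mm[ax]) / grid$spacing_mm[ax]
    w <- rmax / grid$spacing_mm[ax]
    lo[ax] <- floor(c0 - w); hi[ax] <- ceiling(c0 + w)
    if (lo[ax] < 0 || hi[ax] > grid$shape[ax] - 1)
      stop("target volume exceeds grid capacity; enlarge the grid or shrink the volume")
  }
  i1 <- axis_centers_mm(grid, 1)[(lo[1]:hi[1]) + 1L] - center_mm[1]
  i2 <- axis_centers_mm(grid, 2)[(lo[2]:hi[2]) + 1L] - center_mm[2]
  i3 <- axis_centers_mm(grid, 3)[(lo[3]:hi[3]) + 1L] - center_mm[3]
  n1 <- length(i1); n2 <- length(i2); n3 <- length(i3)
  dz <- array(i1, c(n1, n2, n3))
  dy <- aperm(array(i2, c(n2, n1, n3)), c(2, 1, 3))
  dx <- aperm(array(i3, c(n3, n1, n2)), c(2, 3, 1))
  d <- sqrt(dz^2 + dy^2 + dx^2)
  if (length(coef_mm) > 0 && any(coef_mm != 0)) {
    theta <- acos(pmin(1, pmax(-1, ifelse(d > 0, dz / d, 1))))
    phi <- atan2(dx, dy)
    B <- sph_basis(lmax, as.vector(theta), as.vector(phi))
    r <- r0_mm + as.vector(B %*% coef_mm)
  } else r <- rep(r0_mm, length(d))
  nclip <- sum(r < min_radius_mm)
  if (nclip > 0) {
    warning(sprintf(
      "perturbation drove the radius below %.3g mm in %d direction(s); clipped",
      min_radius_mm, nclip), call. = FALSE)
    r <- pmax(r, min_radius_mm)
  }
  inside <- array(as.vector(d) <= r, c(n1, n2, n3))
  out <- array(FALSE, grid$shape)
  out[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <- inside
  binary_mask(out, grid)
}

#' Generate the underlying true tumour for a case
#'
#' A star-convex mask with radius field
#' `r(d) = r0 * (1 + sum a_lm Y_lm(d))`, `a_lm ~ N(0, 0.05^2)` over
#' degrees `l = 1..4`, where `r0 = (3V / 4pi)^(1/3)` for the template's
#' target volume `V`. A voxel is set iff its centre lies within
#' `r(direction)` of the case centre (the grid's middle voxel centre).
#' The resulting volume is within 15% of the target (the l >= 1
#' perturbations are zero-mean over the sphere). Bit-reproducible for a
#' given seed.
#'
#' @param template a [case_template()].
#' @param seed integer seed for the shape coefficients.
#' @param perturb logical; `FALSE` gives an unperturbed sphere (analytic
#'   limit used in tests).
#' @return A [binary_mask()] carrying a `star_shape` attribute (centre,
#'   `r0`, absolute-mm coefficients) consumed by
#'   [simulate_observer_gtv()].
#' @export
make_base_tumor <- function(template, seed, perturb = TRUE) {
  stopifnot(inherits(template, "case_template"))
  g <- template$grid
  center <- g$origin_mm + (g$shape - 1) / 2 * g$spacing_mm
  r0 <- (3 * template$gtv_volume_ml * 1000 / (4 * pi))^(1 / 3)
  lmax <- 4L
  if (perturb) {
    set.seed(as.integer(seed))
    coef <- r0 * stats::rnorm(sph_nbasis(lmax), 0, 0.05)
  } else coef <- numeric(sph_nbasis(lmax))
  m <- star_shape_mask(g, center, r0, lmax, coef)
  attr(m, "star_shape") <- list(center_mm = center, r0 = r0, lmax = lmax,
                                coef_mm = coef)
  m
}

#' Simulate one observer's GTV delineation
#'
#' Perturbs the base tumour's radius field:
#' `r_obs(d) = r_base(d) + bias + g(d)` with `g` a smooth zero-mean
#' spherical-harmonic field (degree <= 6) of pointwise sd
#' `roughness_mm`. Deterministic given the observer's seed. A
#' perturbation driving the radius to zero or below anywhere is clipped
#' at one voxel (the smallest spacing component) with a warning.
#'
#' @param base a mask from [make_base_tumor()] (must carry its
#'   `star_shape` attribute).
#' @param obs an [observer_model()].
#' @return A [binary_mask()] on the base grid, carrying its own
#'   `star_shape` attribute.
#' @export
simulate_observer_gtv <- function(base, obs) {
  stopifnot(inherits(base, "binary_mask"), inherits(obs, "observer_model"))
  ss <- attr(base, "star_shape")
  if (is.null(ss))
    stop("'base' must be a star-convex mask from make_base_tumor()")
  lmax_o <- max(6L, ss$lmax)
  coef <- numeric(sph_nbasis(lmax_o))
  coef[seq_along(ss$coef_mm)] <- ss$coef_mm
  if (obs$roughness_mm > 0) {
    set.seed(obs$seed)
    s <- obs$roughness_mm / sqrt(sph_field_var_unit(6L))
    coef[seq_len(sph_nbasis(6L))] <- coef[seq_len(sph_nbasis(6L))] +
      stats::rnorm(sph_nbasis(6L), 0, s)
  }
  r0_obs <- ss$r0 + obs$systematic_bias_mm
  m <- star_shape_mask(base$grid, ss$center_mm, r0_obs, lmax_o, coef)
  attr(m, "star_shape") <- list(center_mm = ss$center_mm, r0 = r0_obs,
                                lmax = lmax_o, coef_mm = coef)
  m
}

#' Build an ITV as the respiratory motion envelope of a GTV
#'
#' Union over phases `p = 0..n_phases-1` of the GTV translated by
#' `amplitude * sin(2 pi p / n_phases)` along each axis, with each
#' translation rounded to the nearest whole voxel (halves away from
#' zero, keeping the envelope symmetric). Always contains the GTV.
#'
#' @param gtv a [binary_mask()].
#' @param template a [case_template()] supplying `motion_amplitude_mm`
#'   and `n_phases`.
#' @return A [binary_mask()]; errors if a translation would push set
#'   voxels off the grid.
#' @export
build_itv <- function(gtv, template) {
  stopifnot(inherits(gtv, "binary_mask"), inherits(template, "case_template"))
  g <- gtv$grid
  ph <- 0:(template$n_phases - 1)
  disp <- outer(sin(2 * pi * ph / template$n_phases),
                template$motion_amplitude_mm)      # n_phases x 3, mm
  vox <- sweep(disp, 2, g$spacing_mm, "/")
  vox <- sign(vox) * floor(abs(vox) + 0.5)         # halves away from zero
  offs <- unique(as.data.frame(vox))
  out <- array(FALSE, g$shape)
  w <- which(gtv$voxels, arr.ind = TRUE)
  if (nrow(w) == 0) return(binary_mask(out, g))
  for (r in seq_len(nrow(offs))) {
    o <- as.numeric(offs[r, ])
    ws <- sweep(w, 2, o, "+")
    if (any(ws < 1) || any(sweep(ws, 2, g$shape, ">")))
      stop("motion envelope leaves the grid; use a larger grid")
    out[ws] <- TRUE
  }
  binary_mask(out, g)
}

#' Build a PTV by isotropic margin expansion of an ITV
#'
#' A voxel belongs to the PTV iff its spacing-weighted Euclidean distance
#' to the nearest ITV voxel centre is at most `margin_mm`
#' (distance-transform thresholding). Margin 0 is the identity; the PTV
#' always contains the ITV.
#'
#' @param itv a [binary_mask()].
#' @param margin_mm non-negative margin in mm.
#' @return A [binary_mask()]; errors if the expansion would leave the
#'   grid.
#' @export
build_ptv <- function(itv, margin_mm) {
  stopifnot(inherits(itv, "binary_mask"), margin_mm >= 0)
  if (margin_mm == 0 || !any(itv$voxels)) return(itv)
  g <- itv$grid
  padv <- as.integer(floor(margin_mm / g$spacing_mm + 1e-9))
  bb0 <- union_bbox(list(itv), pad = 0L)
  if (any(bb0$lo - padv < 0) || any(bb0$hi + padv > g$shape - 1L))
    stop("margin expansion leaves the grid; use a larger grid")
  bb <- list(lo = bb0$lo - padv, hi = bb0$hi + padv)
  cm <- crop_mask(itv, bb)
  dt <- edt_sq(cm$voxels, dim(cm$voxels), g$spacing_mm)
  sub <- dt <= margin_mm^2 + 1e-9
  out <- array(FALSE, g$shape)
  out[(bb$lo[1]:bb$hi[1]) + 1L, (bb$lo[2]:bb$hi[2]) + 1L,
      (bb$lo[3]:bb$hi[3]) + 1L] <- sub
  binary_mask(out, g)
}

#' Generate a full synthetic multi-observer cohort
#'
#' For each case template: one base tumour; for each observer a perturbed
#' GTV, the ITV as the motion envelope of that observer's GTV, and the
#' PTV as the margin expansion of that observer's ITV. Fully
#' deterministic from `base_seed`: the base tumour of case `ci` uses seed
#' `base_seed * 10000 + ci * 100`, observer `oi` of case `ci` uses
#' `base_seed * 10000 + ci * 100 + oi`. With `participation < 1`, each
#' non-first observer's record set is kept with that probability
#' (decided once per observer-case from the observer seed).
#'
#' @param config a [cohort_sim_config()].
#' @return A [cohort_structure_set()] with a `manifest` attribute
#'   recording all template and observer parameters.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  records <- list()
  observers <- sprintf("%02d", seq_len(config$n_observers))
  manifest <- list(n_observers = config$n_observers,
                   sigma_bias_mm = config$sigma_bias_mm,
                   roughness_mm = config$roughness_mm,
                   base_seed = config$base_seed,
                   participation = config$participation,
                   cases = list())
  for (ci in seq_along(config$templates)) {
    tpl <- config$templates[[ci]]
    base <- make_base_tumor(tpl, seed = config$base_seed * 10000 + ci * 100)
    obs_entries <- list()
    for (oi in seq_len(config$n_observers)) {
      oseed <- config$base_seed * 10000 + ci * 100 + oi
      set.seed(oseed)
      bias <- stats::rnorm(1, 0, config$sigma_bias_mm)
      keep <- oi == 1 || config$participation >= 1 ||
        stats::runif(1) < config$participation
      om <- observer_model(observers[oi], systematic_bias_mm = bias,
                           roughness_mm = config$roughness_mm,
                           # field coefficients use their own derived seed
                           seed = oseed + 50L)
      obs_entries[[observers[oi]]] <- list(
        observer_id = observers[oi], seed = oseed,
        systematic_bias_mm = bias, roughness_mm = config$roughness_mm,
        participated = keep)
      if (!keep) next
      gtv <- simulate_observer_gtv(base, om)
      itv <- build_itv(gtv, tpl)
      ptv <- build_ptv(itv, tpl$ptv_margin_mm)
      records <- c(records, list(
        delineation_record(tpl$case_id, observers[oi], "GTV", gtv),
        delineation_record(tpl$case_id, observers[oi], "ITV", itv),
        delineation_record(tpl$case_id, observers[oi], "PTV", ptv)))
    }
    manifest$cases[[tpl$case_id]] <- list(
      gtv_volume_ml = tpl$gtv_volume_ml,
      grid = list(shape = tpl$grid$shape, spacing_mm = tpl$grid$spacing_mm,
                  origin_mm = tpl$grid$origin_mm),
      motion_amplitude_mm = tpl$motion_amplitude_mm,
      n_phases = tpl$n_phases, ptv_margin_mm = tpl$ptv_margin_mm,
      base_tumor_seed = config$base_seed * 10000 + ci * 100,
      observers = obs_entries)
  }
  cohort <- cohort_structure_set(records)
  attr(cohort, "manifest") <- manifest
  cohort
}
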