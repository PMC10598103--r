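# Smaller-than-default grids (64^3 at 2 mm) are used here to keep the
# unit suite fast; the acceptance suite exercises the default 128^3
# resolution.

small_tpl <- function(vol = 31.75, ...) {
  case_template("1", vol, shape = c(64L, 64L, 64L), spacing_mm = c(2, 2, 2), ...)
}

test_that("unperturbed base tumour is an analytic sphere", {
  # V = 33.51 ml at 1 mm spacing -> radius 20 mm, ~33510 voxels
  tpl <- case_template("s", 33.51, shape = c(56L, 56L, 56L),
                       spacing_mm = c(1, 1, 1))
  m <- make_base_tumor(tpl, seed = 1, perturb = FALSE)
  expect_equal(sum(m$voxels), 33510, tolerance = 0.01)
  # voxel set iff centre within r0 of the grid centre
  ss <- attr(m, "star_shape")
  expect_equal(ss$r0, 20, tolerance = 1e-3)
  oracle <- ball_mask(m$grid, ss$center_mm, ss$r0)
  expect_identical(m$voxels, oracle$voxels)
})

test_that("base tumour volume lands within 15% of target and is reproducible", {
  for (vol in c(31.75, 45.3)) {
    tpl <- small_tpl(vol)
    m1 <- make_base_tumor(tpl, seed = 11)
    m2 <- make_base_tumor(tpl, seed = 11)
    expect_identical(m1$voxels, m2$voxels)       # bit-reproducible
    expect_lt(abs(mask_volume_ml(m1) - vol) / vol, 0.15)
    m3 <- make_base_tumor(tpl, seed = 12)
    expect_false(identical(m1$voxels, m3$voxels))
  }
  expect_error(make_base_tumor(case_template("big", 400,
                                             shape = c(16L, 16L, 16L),
                                             spacing_mm = c(2, 2, 2)), 1),
               "grid capacity")
})

test_that("observer simulation: degenerate and biased limits", {
  tpl <- small_tpl()
  base <- make_base_tumor(tpl, seed = 3)
  id <- simulate_observer_gtv(base, observer_model("o", 0, 0, seed = 9))
  expect_identical(id$voxels, base$voxels)
  expect_equal(dice(base, id), 1)
  grown <- simulate_observer_gtv(base, observer_model("o", 3, 0, seed = 9))
  expect_gt(sum(grown$voxels), sum(base$voxels))
  expect_true(all(grown$voxels[base$voxels]))    # pure dilation contains base
  shrunk <- simulate_observer_gtv(base, observer_model("o", -3, 0, seed = 9))
  expect_lt(sum(shrunk$voxels), sum(base$voxels))
  expect_error(simulate_observer_gtv(random_mask(tpl$grid, 0.1, seed = 2),
                                     observer_model("o", 0, 1)),
               "star-convex")
})

test_that("observer fields are seed-deterministic and seed-sensitive", {
  tpl <- small_tpl()
  base <- make_base_tumor(tpl, seed = 3)
  a <- simulate_observer_gtv(base, observer_model("o", 1, 2, seed = 21))
  b <- simulate_observer_gtv(base, observer_model("o", 1, 2, seed = 21))
  c <- simulate_observer_gtv(base, observer_model("o", 1, 2, seed = 22))
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("ITV is the enumerated rounded-sine envelope of the GTV", {
  # single-voxel GTV, slice-axis amplitude 5 mm, 1 mm spacing, 10 phases
  tpl <- case_template("m", 1, shape = c(16L, 16L, 16L),
                       spacing_mm = c(1, 1, 1),
                       motion_amplitude_mm = c(5, 0, 0), n_phases = 10L)
  v <- array(FALSE, tpl$grid$shape); v[8, 8, 8] <- TRUE
  gtv <- binary_mask(v, tpl$grid)
  itv <- build_itv(gtv, tpl)
  # independent enumeration of the distinct rounded displacements
  offs <- sort(unique(sign(s <- 5 * sin(2 * pi * (0:9) / 10)) *
                        floor(abs(s) + 0.5)))
  got <- sort(which(itv$voxels, arr.ind = TRUE)[, 1]) - 8
  expect_equal(got, offs)
  # amplitude zero: identity; and ITV always contains the GTV
  tpl0 <- case_template("m", 1, shape = c(16L, 16L, 16L),
                        spacing_mm = c(1, 1, 1),
                        motion_amplitude_mm = c(0, 0, 0))
  expect_identical(build_itv(gtv, tpl0)$voxels, gtv$voxels)
  expect_true(all(itv$voxels[gtv$voxels]))
  expect_gte(mask_volume_ml(itv), mask_volume_ml(gtv))
  # motion pushing off-grid errors
  edge <- array(FALSE, tpl$grid$shape); edge[2, 8, 8] <- TRUE
  expect_error(build_itv(binary_mask(edge, tpl$grid), tpl), "larger grid")
})

test_that("PTV margin expansion: identity, lattice count, sphere ratio", {
  g <- image_grid(c(11, 11, 11), c(1, 1, 1))
  v <- array(FALSE, g$shape); v[6, 6, 6] <- TRUE
  single <- binary_mask(v, g)
  expect_identical(build_ptv(single, 0)$voxels, single$voxels)
  # margin 2 mm at 1 mm isotropic: lattice offsets with |o|^2 <= 4
  p2 <- build_ptv(single, 2)
  noff <- sum(outer(outer((-2:2)^2, (-2:2)^2, "+"), (-2:2)^2, "+") <= 4)
  expect_equal(noff, 33)
  expect_equal(sum(p2$voxels), 33)
  # sphere radius 15 + 5 mm margin ~ (20/15)^3 volume ratio
  g2 <- image_grid(c(46, 46, 46), c(1, 1, 1))
  ball <- ball_mask(g2, c(22.5, 22.5, 22.5), 15)
  grown <- build_ptv(ball, 5)
  expect_true(all(grown$voxels[ball$voxels]))
  expect_equal(mask_volume_ml(grown) / mask_volume_ml(ball), (20 / 15)^3,
               tolerance = 0.05)
  # off-grid expansion errors
  expect_error(build_ptv(ball, 10), "larger grid")
})

test_that("generate_cohort: record count, determinism, degenerate cohort", {
  tpls <- list(case_template("1", 8, shape = c(40L, 40L, 40L),
                             spacing_mm = c(2, 2, 2), ptv_margin_mm = 4),
               case_template("2", 10, shape = c(40L, 40L, 40L),
                             spacing_mm = c(2, 2, 2), ptv_margin_mm = 4))
  cfg <- cohort_sim_config(n_observers = 4, templates = tpls, base_seed = 5)
  ch1 <- generate_cohort(cfg)
  expect_length(ch1$records, 2 * 4 * 3)
  ch2 <- generate_cohort(cfg)
  expect_equal(ch1, ch2)
  # manifest records per-observer parameters
  man <- attr(ch1, "manifest")
  expect_named(man$cases, c("1", "2"))
  expect_length(man$cases[["1"]]$observers, 4)

  cfg0 <- cohort_sim_config(n_observers = 3, templates = tpls[1],
                            sigma_bias_mm = 0, roughness_mm = 0,
                            base_seed = 5)
  ch0 <- generate_cohort(cfg0)
  for (vk in c("GTV", "ITV", "PTV")) {
    pr <- all_pairs(ch0, "1", vk)
    expect_true(all(pr$dsc == 1))
    expect_true(all(pr$hd_mm == 0))
  }
})

test_that("GTV-ITV-PTV nesting holds for every generated record", {
  tpls <- list(case_template("1", 9, shape = c(40L, 40L, 40L),
                             spacing_mm = c(2, 2, 2), ptv_margin_mm = 4))
  ch <- generate_cohort(cohort_sim_config(n_observers = 4, templates = tpls,
                                          base_seed = 17))
  for (o in sprintf("%02d", 1:4)) {
    ms <- list()
    for (r in ch$records)
      if (r$observer_id == o) ms[[r$volume_kind]] <- r$mask
    expect_true(all(ms$ITV$voxels[ms$GTV$voxels]))
    expect_true(all(ms$PTV$voxels[ms$ITV$voxels]))
  }
})

test_that("participation < 1 drops some non-first observers' records", {
  tpls <- list(case_template("1", 8, shape = c(40L, 40L, 40L),
                             spacing_mm = c(2, 2, 2), ptv_margin_mm = 4))
  cfg <- cohort_sim_config(n_observers = 8, templates = tpls,
                           base_seed = 23, participation = 0.5)
  ch <- generate_cohort(cfg)
  obs <- unique(vapply(ch$records, `[[`, character(1), "observer_id"))
  expect_true("01" %in% obs)                  # first observer always kept
  expect_lt(length(ch$records), 8 * 3)
  expect_equal(length(ch$records) %% 3, 0)    # drop whole observer-cases
})

test_that("bias-only cohorts recover the bias sd from equivalent-sphere radii", {
  tpl <- small_tpl()
  base <- make_base_tumor(tpl, seed = 4, perturb = FALSE)
  sigma <- 2
  set.seed(31)
  radii <- vapply(1:19, function(o) {
    b <- rnorm(1, 0, sigma)
    m <- simulate_observer_gtv(base, observer_model("o", b, 0, seed = o))
    (3 * mask_volume_ml(m) * 1000 / (4 * pi))^(1 / 3)
  }, numeric(1))
  expect_lt(abs(sd(radii) - sigma) / sigma, 0.4)
})

test_that("median pairwise GTV dice decreases as roughness grows (small scale)", {
  tpl <- small_tpl()
  med_dice <- function(rough, seed) {
    base <- make_base_tumor(tpl, seed = seed)
    gtvs <- lapply(1:8, function(o) {
      set.seed(seed * 100 + o)
      b <- rnorm(1, 0, 1.5)
      simulate_observer_gtv(base, observer_model(sprintf("%02d", o), b, rough,
                                                 seed = seed * 100 + o + 50))
    })
    d <- c()
    for (i in 1:7) for (j in (i + 1):8)
      d <- c(d, dice(gtvs[[i]], gtvs[[j]]))
    median(d)
  }
  meds <- vapply(c(0.5, 2, 4), med_dice, numeric(1), seed = 6)
  expect_true(all(diff(meds) < 0))
})
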