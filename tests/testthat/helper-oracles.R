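# Shared fixtures and independent oracles. Everything here deliberately
# avoids the code paths it is used to check.

random_mask <- function(grid, p = 0.2, seed = NULL, nonempty = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    v <- array(runif(prod(grid$shape)) < p, grid$shape)
    if (!nonempty || any(v)) return(binary_mask(v, grid))
  }
}

# Solid ball mask: voxel centres within radius_mm of center_mm.
ball_mask <- function(grid, center_mm, radius_mm) {
  d2 <- array(0, grid$shape)
  for (ax in 1:3) {
    c1 <- grid$origin_mm[ax] + (seq_len(grid$shape[ax]) - 1) *
      grid$spacing_mm[ax] - center_mm[ax]
    perm <- order(c(ax, setdiff(1:3, ax)))
    d2 <- d2 + aperm(array(c1^2, grid$shape[c(ax, setdiff(1:3, ax))]), perm)
  }
  binary_mask(d2 <= radius_mm^2, grid)
}

# Independent point-in-convex-polygon test: the point is inside iff it is
# on the inner side of every edge (half-plane signs), on-edge counting as
# inside. Valid for convex vertex lists in either orientation.
convex_pip_oracle <- function(verts, py, px) {
  n <- nrow(verts)
  cx <- mean(verts[, 2]); cy <- mean(verts[, 1])
  for (e in seq_len(n)) {
    f <- if (e == n) 1L else e + 1L
    dy <- verts[f, 1] - verts[e, 1]; dx <- verts[f, 2] - verts[e, 2]
    s_c <- (cx - verts[e, 2]) * dy - (cy - verts[e, 1]) * dx
    s_p <- (px - verts[e, 2]) * dy - (py - verts[e, 1]) * dx
    if (s_c > 0) { if (s_p < 0) return(FALSE) } else if (s_p > 0) return(FALSE)
  }
  TRUE
}

# Random convex polygon: points on an ellipse at sorted random angles.
random_convex_polygon <- function(n, cy, cx, ry, rx) {
  ang <- sort(runif(n, 0, 2 * pi))
  cbind(cy + ry * sin(ang), cx + rx * cos(ang))
}

# Brute-force nearest-neighbour resampling: per target voxel, argmin of
# |target centre - source centre| along each axis (which.min ties to the
# first = lowest index), background outside the source extent.
resample_oracle <- function(m, target) {
  src <- m$grid
  out <- array(FALSE, target$shape)
  sc <- lapply(1:3, function(ax)
    src$origin_mm[ax] + (seq_len(src$shape[ax]) - 1) * src$spacing_mm[ax])
  for (i in seq_len(target$shape[1]))
    for (j in seq_len(target$shape[2]))
      for (k in seq_len(target$shape[3])) {
        pos <- target$origin_mm + (c(i, j, k) - 1) * target$spacing_mm
        idx <- integer(3); ok <- TRUE
        for (ax in 1:3) {
          dd <- abs(pos[ax] - sc[[ax]])
          idx[ax] <- which.min(dd)
          if (min(dd) > src$spacing_mm[ax] / 2 + 1e-12) ok <- FALSE
        }
        if (ok) out[i, j, k] <- m$voxels[idx[1], idx[2], idx[3]]
      }
  binary_mask(out, target)
}

# Direct five-statistic computation by sorting / closed formulas.
stats_oracle <- function(v) {
  fin <- v[is.finite(v)]
  n <- length(v)
  srt <- sort(v)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  list(minimum = srt[1], maximum = srt[n],
       mean = sum(fin) / length(fin), median = med,
       std = if (length(fin) > 1)
         sqrt(sum((fin - mean(fin))^2) / (length(fin) - 1)) else 0)
}

# Tiny distinct masks for engine tests: one ball per observer, jittered.
toy_cohort <- function(n_obs, case_ids = "c1", seed = 1, shape = c(12, 12, 12)) {
  set.seed(seed)
  g <- image_grid(shape, c(2, 2, 2))
  recs <- list()
  for (cs in case_ids) {
    for (o in seq_len(n_obs)) {
      ctr <- (shape - 1) * g$spacing_mm / 2 + runif(3, -1.5, 1.5)
      m <- ball_mask(g, ctr, 6 + runif(1, -1, 1))
      for (vk in c("GTV", "ITV", "PTV")) {
        mk <- if (vk == "GTV") m else build_ptv(m, if (vk == "ITV") 2 else 4)
        recs[[length(recs) + 1L]] <-
          delineation_record(cs, sprintf("o%02d", o), vk, mk)
      }
    }
  }
  cohort_structure_set(recs)
}
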