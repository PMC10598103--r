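test_that("mask volumes round-trip through NRRD in both encodings", {
  g <- image_grid(c(9, 7, 11), c(0.98, 0.98, 3), origin_mm = c(-12, 4.5, 0.25))
  m <- random_mask(g, 0.3, seed = 101)
  for (enc in c("raw", "ascii")) {
    f <- tempfile(fileext = ".nrrd")
    write_mask_volume(m, f, encoding = enc)
    back <- read_mask_volume(f)
    expect_identical(back$voxels, m$voxels)
    expect_true(grids_equal(back$grid, m$grid))
    expect_equal(back$grid$spacing_mm, g$spacing_mm, tolerance = 1e-6)
    unlink(f)
  }
  # empty mask round-trip
  e <- binary_mask(array(FALSE, g$shape), g)
  f <- tempfile(fileext = ".nrrd")
  write_mask_volume(e, f)
  expect_equal(mask_volume_ml(read_mask_volume(f)), 0)
  unlink(f)
})

test_that("a 200x200x100 mask round-trips quickly", {
  g <- image_grid(c(200, 200, 100), c(1, 1, 2))
  m <- binary_mask(array(seq_len(prod(g$shape)) %% 7 == 0, g$shape), g)
  f <- tempfile(fileext = ".nrrd")
  t0 <- Sys.time()
  write_mask_volume(m, f)
  back <- read_mask_volume(f)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_identical(back$voxels, m$voxels)
  unlink(f)
})

test_that("volume reader rejects malformed files with the path in the message", {
  f <- tempfile(fileext = ".nrrd")
  writeLines(c("not a volume", ""), f)
  expect_error(read_mask_volume(f), "NRRD")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 2", "sizes: 4 4",
               "encoding: ascii", "", "0 0 0 0"), f)
  expect_error(read_mask_volume(f), "3-D")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "space directions: (-1,0,0) (0,1,0) (0,0,1)",
               "encoding: ascii", "", paste(rep(0, 8), collapse = " ")), f)
  expect_error(read_mask_volume(f), "spacing")
  expect_error(read_mask_volume(tempfile()), "no such")
  unlink(f)
})

test_that("metrics are preserved exactly through a write/read round-trip", {
  g <- image_grid(c(8, 8, 8), c(1.5, 1, 1))
  a <- random_mask(g, 0.3, seed = 7, nonempty = TRUE)
  b <- random_mask(g, 0.3, nonempty = TRUE)
  fa <- tempfile(fileext = ".nrrd"); fb <- tempfile(fileext = ".nrrd")
  write_mask_volume(a, fa); write_mask_volume(b, fb)
  a2 <- read_mask_volume(fa); b2 <- read_mask_volume(fb)
  expect_identical(metric_quartet(a2, b2)[c("dsc", "hd_mm", "pbd", "vs")],
                   metric_quartet(a, b)[c("dsc", "hd_mm", "pbd", "vs")])
  unlink(c(fa, fb))
})

test_that("rasterization follows the centre-inside even-odd rule", {
  g <- image_grid(c(1, 4, 4), c(3, 1, 1))
  # square through the centres of the 2x2 patch at rows/cols 1..2 (mm)
  sq <- contour_polygon(0, rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1)))
  m <- rasterize_contours(list(sq), g)
  expect_equal(sum(m$voxels), 4)             # edge centres count as inside
  expect_true(all(m$voxels[1, 2:3, 2:3]))

  # polygon entirely between voxel centres: nothing set, warning
  tiny <- contour_polygon(0, rbind(c(0.2, 0.2), c(0.2, 0.8), c(0.8, 0.8),
                                   c(0.8, 0.2)) + 0.1)
  expect_warning(m0 <- rasterize_contours(list(tiny), g), "no voxel centre")
  expect_equal(sum(m0$voxels), 0)

  # nested squares: even-odd carves a hole (ring)
  g2 <- image_grid(c(1, 9, 9), c(3, 1, 1))
  outer_sq <- contour_polygon(0, rbind(c(0.5, 0.5), c(0.5, 7.5),
                                       c(7.5, 7.5), c(7.5, 0.5)))
  inner_sq <- contour_polygon(0, rbind(c(2.5, 2.5), c(2.5, 5.5),
                                       c(5.5, 5.5), c(5.5, 2.5)))
  ring <- rasterize_contours(list(outer_sq, inner_sq), g2)
  expect_equal(sum(ring$voxels), 49 - 9)
  expect_false(any(ring$voxels[1, 4:6, 4:6]))
})

test_that("contours off any slice plane are dropped with a warning", {
  g <- image_grid(c(4, 6, 6), c(3, 1, 1))
  onplane <- contour_polygon(3, rbind(c(0.5, 0.5), c(0.5, 3.5), c(3.5, 3.5),
                                      c(3.5, 0.5)))
  off <- contour_polygon(20, rbind(c(0.5, 0.5), c(0.5, 3.5), c(3.5, 3.5),
                                   c(3.5, 0.5)))
  expect_warning(m <- rasterize_contours(list(onplane, off), g),
                 "half a slice spacing")
  expect_true(any(m$voxels[2, , ]))
  expect_equal(sum(m$voxels), sum(m$voxels[2, , ]))
})

test_that("rasterizer agrees with an independent convex point-in-polygon oracle", {
  g <- image_grid(c(1, 64, 64), c(3, 1, 1))   # voxel centres at 0..63 mm
  for (s in 1:25) {
    set.seed(7000 + s)
    verts <- random_convex_polygon(sample(3:9, 1), cy = runif(1, 20, 43),
                                   cx = runif(1, 20, 43),
                                   ry = runif(1, 3, 18), rx = runif(1, 3, 18))
    m <- rasterize_contours(list(contour_polygon(0, verts)), g)
    oracle <- matrix(FALSE, 64, 64)
    for (j in 1:64) for (k in 1:64)
      oracle[j, k] <- convex_pip_oracle(verts, j - 1, k - 1)
    expect_identical(m$voxels[1, , ], oracle)
  }
})

test_that("rasterization is translation-consistent and orientation-independent", {
  base_verts <- rbind(c(2.25, 1.5), c(2.5, 9.75), c(8.75, 11.25),
                      c(10.5, 4.25), c(6.25, 0.75))
  g <- image_grid(c(1, 14, 14), c(3, 1, 1))
  m0 <- rasterize_contours(list(contour_polygon(0, base_verts)), g)
  shift <- c(5.25, -2.5)                     # exactly representable
  gs <- image_grid(g$shape, g$spacing_mm,
                   g$origin_mm + c(0, shift[1], shift[2]))
  ms <- rasterize_contours(list(contour_polygon(0, sweep(base_verts, 2, shift, "+"))), gs)
  expect_identical(ms$voxels, m0$voxels)
  mr <- rasterize_contours(list(contour_polygon(0, base_verts[nrow(base_verts):1, ])), g)
  expect_identical(mr$voxels, m0$voxels)
})

test_that("structure sets round-trip and validate", {
  d <- tempfile(); dir.create(d)
  f <- file.path(d, "ss.json")
  sq <- contour_polygon(6, rbind(c(1, 1), c(1, 4), c(4, 4), c(4, 1)))
  write_structure_set(list(GTV = list(sq)), f, frame_of_reference = "FOR-1")
  ss <- parse_structure_set(f)
  expect_named(ss$rois, "GTV")
  expect_length(ss$rois$GTV, 1)
  p <- ss$rois$GTV[[1]]
  expect_equal(p$slice_position_mm, 6)
  expect_equal(nrow(p$vertices), 4)
  expect_equal(p$vertices, sq$vertices)
  expect_equal(ss$frame_of_reference, "FOR-1")

  # non-planar contour is a format error naming the ROI
  bad <- list(frame_of_reference = "x", rois = list(list(
    name = "ITV", contours = list(list(points = list(
      c(0, 0, 0), c(1, 0, 0.5), c(1, 1, 0)))))))
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(parse_structure_set(f), "ITV.*non-planar")

  # fewer than 3 points is an error
  bad2 <- list(rois = list(list(name = "PTV", contours = list(list(
    points = list(c(0, 0, 0), c(1, 1, 0)))))))
  jsonlite::write_json(bad2, f, auto_unbox = TRUE)
  expect_error(parse_structure_set(f), "fewer than 3")
  unlink(d, recursive = TRUE)
})

test_that("synthesize-parse-rasterize recovers the analytic polygon volume", {
  # regular 20-gon of radius 10 mm on 3 slices, thickness 2.5 mm
  ang <- seq(0, 2 * pi, length.out = 21)[-21]
  verts <- cbind(31.5 + 10 * sin(ang), 31.5 + 10 * cos(ang))
  area <- 0.5 * 20 * 10^2 * sin(2 * pi / 20)          # regular polygon area
  g <- image_grid(c(6, 64, 64), c(2.5, 1, 1))
  polys <- lapply(c(2.5, 5, 7.5), contour_polygon, vertices = verts)
  f <- tempfile(fileext = ".json")
  write_structure_set(list(GTV = polys), f)
  ss <- parse_structure_set(f)
  m <- rasterize_contours(ss$rois$GTV, g)
  expect_equal(mask_volume_ml(m), 3 * area * 2.5 / 1000, tolerance = 0.05)
  unlink(f)
})
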