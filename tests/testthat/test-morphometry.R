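test_that("mean diameter and circularity follow the printed formulas", {
  expect_identical(mean_diameter(pi), 1)
  expect_equal(mean_diameter(45.6), sqrt(45.6 / pi), tolerance = 1e-12)
  expect_equal(mean_diameter(45.6), 3.80985, tolerance = 1e-5)
  expect_error(mean_diameter(0), "positive")

  for (r in c(1, 5, 10))
    expect_identical(circularity(pi * r^2, 2 * pi * r), 1)
  s <- 3.2
  expect_equal(circularity(s^2, 4 * s), pi / 4, tolerance = 1e-12)
  expect_error(circularity(-1, 5), "positive")
  expect_error(circularity(5, 0), "positive")
})

test_that("rasterized discs converge to circularity 1 under the Crofton estimator", {
  for (rad in c(30, 50)) {
    m <- disc_mask(rad)
    r <- label_regions(m)
    expect_equal(circularity(r$area_px, r$perimeter_px), 1, tolerance = 0.03)
  }
})

test_that("feret extremes: degenerate conventions and anisotropy direction", {
  expect_equal(feret_extremes(cbind(3L, 5L), pixel_scale = 0.25),
               c(max_feret = 0.25, min_feret = 0.25))

  bar <- cbind(rep(1L, 10), 1:10)
  f <- feret_extremes(bar, pixel_scale = 1)
  expect_equal(unname(f[1]), sqrt(10^2 + 1^2), tolerance = 1e-9)
  expect_equal(unname(f[2]), 1, tolerance = 1e-9)
  expect_gt(f[1] / f[2], 1)
})

test_that("rasterized disc calipers are nearly isotropic", {
  px <- which(disc_mask(50), arr.ind = TRUE)
  f <- feret_extremes(px, pixel_scale = 1)
  expect_lt(f[1] / f[2], 1.02)
})

test_that("calipers agree with an exhaustive angular sweep", {
  sweep_oracle <- function(px) {
    r <- px[, 1]; cc <- px[, 2]
    pts <- cbind(c(r - .5, r - .5, r + .5, r + .5),
                 c(cc - .5, cc + .5, cc - .5, cc + .5))
    th <- seq(0, pi, length.out = 3600)
    w <- vapply(th, function(t) {
      pr <- pts[, 2] * cos(t) + pts[, 1] * sin(t)
      max(pr) - min(pr)
    }, numeric(1))
    c(max(w), min(w))
  }
  set.seed(11)
  for (i in 1:4) {
    px <- raster_ellipse(6 + 2 * runif(1), 1 + runif(1) / 2, runif(1, 0, pi),
                         pixel_scale = 0.5)
    f <- feret_extremes(px, pixel_scale = 1)
    o <- sweep_oracle(px)
    expect_equal(unname(f[1]), o[1], tolerance = 0.005)
    expect_equal(unname(f[2]), o[2], tolerance = 0.005)
  }
})

test_that("population summary implements the CV% distribution width", {
  cells <- tibble::tibble(
    cell_id = 1:3, area = pi * (c(6, 8, 10) / 2)^2, perimeter = pi * c(6, 8, 10),
    mean_diameter = c(6, 8, 10), max_feret = c(6, 8, 10),
    min_feret = c(6, 8, 10), axis_ratio = 1, circularity = 1,
    centroid_x = 0, centroid_y = 0, area_px = 1L
  )
  s <- summarize_population(cells)
  expect_equal(s$diameter_mean, 8)
  expect_equal(s$diameter_dw, 25)            # sample SD (n-1): 100 * 2 / 8
  expect_equal(s$axis_ratio_dw, 0)
  expect_equal(summarize_population(cells, width = "sd")$diameter_dw, 2)

  perm <- cells[c(3, 1, 2), ]
  expect_equal(summarize_population(perm), s)

  same <- cells; same$mean_diameter <- 8; same$area <- pi * 16
  expect_true(all(summarize_population(same)[, c("diameter_dw")] == 0))

  expect_error(summarize_population(cells[0, ]), "empty")

  v <- population_vector(summarize_population(cells, dr = c(1.1, 1.2, 1.3)))
  expect_identical(names(v), c("diameter_mean", "diameter_dw",
                               "circularity_mean", "circularity_dw",
                               "axis_ratio_mean", "axis_ratio_dw",
                               "dr_mean", "dr_dw"))
  expect_equal(unname(v["dr_mean"]), 1.2)

  s2 <- summarize_population(cells, volume_ml = chamber_volume_ml(100, 100))
  expect_equal(s2$concentration, 3 / (100 * 100 * 20 * 1e-12))
})

test_that("measurements are scale-equivariant in the pixel scale", {
  m <- disc_mask(12, pixel_scale = 0.25)
  r <- label_regions(m)
  c1 <- measure_cells(r, pixel_scale = 0.25)
  c2 <- measure_cells(r, pixel_scale = 0.5)
  expect_equal(c2$mean_diameter, 2 * c1$mean_diameter)
  expect_equal(c2$max_feret, 2 * c1$max_feret)
  expect_equal(c2$area, 4 * c1$area)
  expect_equal(c2$circularity, c1$circularity)
  expect_equal(c2$axis_ratio, c1$axis_ratio)
})

test_that("clean scenes recover the generator's morphology within 3%", {
  # near-circular cells are the hard case for Max/MinFeret: run at fine
  # pixel sampling (0.125 um/px) where the caliper bias is small
  for (spec in list(list(p = class_profile("healthy"), seeds = c(21, 22)),
                    list(p = class_profile("MF"), seeds = c(23, 24)))) {
    cells <- dplyr::bind_rows(lapply(spec$seeds, function(s) {
      sc <- clean_scene(profile = spec$p, n_cells = 105, field = 200,
                        pixel_scale = 0.125, stress = "none", seed = s)
      measure_cells(segment_frame(sc$pre))
    }))
    expect_gte(nrow(cells), 200)
    truth_diam <- sqrt(pi * (spec$p$diameter_mean / 2)^2 / pi)  # device convention
    expect_lt(abs(mean(cells$mean_diameter) / truth_diam - 1), 0.03)
    expect_lt(abs(mean(cells$axis_ratio) / spec$p$axis_ratio_mean - 1), 0.03)
  }
})

test_that("segmenting a clean scene recovers true per-cell areas within 5%", {
  sc <- clean_scene(n_cells = 20, field = 100, stress = "none", seed = 31)
  cells <- measure_cells(segment_frame(sc$pre))
  expect_identical(nrow(cells), 20L)
  ti <- vapply(seq_len(nrow(cells)), function(i) {
    which.min((sc$truth$centroid_x - cells$centroid_x[i])^2 +
                (sc$truth$centroid_y - cells$centroid_y[i])^2)
  }, integer(1))
  rel <- cells$area / sc$truth$true_area_pre[ti] - 1
  expect_true(all(abs(rel) < 0.05))
})
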