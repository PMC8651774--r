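test_that("to_grayscale collapses RGB with ITU-R 601 weights and is idempotent", {
  rgb <- array(0L, dim = c(4, 4, 3))
  rgb[, , 1] <- 100L; rgb[, , 2] <- 100L; rgb[, , 3] <- 100L
  f <- image_frame(rgb, 0.25)
  expect_true(all(to_grayscale(f)$pixels == 100L))

  red <- array(0L, dim = c(2, 2, 3)); red[, , 1] <- 255L
  expect_true(all(to_grayscale(image_frame(red, 1))$pixels == 76L))

  g <- image_frame(matrix(7L, 3, 3), 0.25)
  expect_identical(to_grayscale(g), g)
})

test_that("adjust_intensity maps the rescale percentiles to the 8-bit endpoints", {
  px <- matrix(rep(50:150, length.out = 400), 20, 20)
  f <- image_frame(px, 1)
  out <- adjust_intensity(f, p_low = 0, p_high = 1)
  expect_identical(min(out$pixels), 0L)
  expect_identical(max(out$pixels), 255L)

  full <- image_frame(matrix(as.integer(seq(0, 255, length.out = 256)), 16, 16), 1)
  expect_lte(max(abs(adjust_intensity(full, 0, 1)$pixels - full$pixels)), 1L)

  expect_warning(adjust_intensity(image_frame(matrix(9L, 4, 4), 1)), "constant")
})

test_that("adjust_intensity preserves intensity ordering", {
  set.seed(42)
  for (i in 1:5) {
    px <- matrix(sample.int(256, 100, replace = TRUE) - 1L, 10, 10)
    out <- adjust_intensity(image_frame(px, 1))$pixels
    o <- order(px)
    expect_true(all(diff(out[o]) >= 0))
  }
})

test_that("binarize separates a bimodal image and matches exhaustive Otsu", {
  px <- matrix(200L, 20, 20)
  px[5:10, 5:10] <- 40L
  mask <- binarize(image_frame(px, 1))
  expect_identical(unname(which(mask)), unname(which(px == 40L)))

  # brute-force between-class variance maximizer as the oracle
  set.seed(1)
  px2 <- matrix(as.integer(pmin(255, pmax(0, round(c(rnorm(300, 70, 12),
                                                     rnorm(700, 190, 18)))))),
                25, 40)
  h <- tabulate(as.vector(px2) + 1L, 256)
  p <- h / sum(h); lv <- 0:255
  bcv <- vapply(0:254, function(t) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    m0 <- sum(lv[1:(t + 1)] * p[1:(t + 1)]) / w0
    m1 <- sum(lv[(t + 2):256] * p[(t + 2):256]) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
  t_star <- which.max(bcv) - 1L
  got <- attr(binarize(image_frame(px2, 1)), "threshold")
  expect_lt(abs(got - t_star), 1.5)

  expect_warning(m0 <- binarize(image_frame(matrix(c(200L, 201L), 4, 4), 1),
                                method = "fixed", threshold = 10), "empty")
  expect_false(any(m0))
})

test_that("fill_holes turns an annulus into a solid disc and is idempotent", {
  outer_d <- disc_mask(8)
  inner <- disc_mask(3, side = ncol(outer_d))
  ann <- outer_d & !inner
  attr(ann, "pixel_scale") <- 1
  filled <- fill_holes(ann)
  expect_identical(which(filled), which(outer_d))
  expect_identical(fill_holes(filled), filled)

  no_hole <- disc_mask(5)
  expect_identical(which(fill_holes(no_hole)), which(no_hole))
})

test_that("label_regions finds 8-connected components with correct geometry", {
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE
  m[8:10, 8:10] <- TRUE
  attr(m, "pixel_scale") <- 1
  r <- label_regions(m)
  expect_identical(nrow(r), 2L)
  expect_equal(r$area_px, c(9L, 9L))
  expect_equal(r$centroid_row, c(3, 9))

  # diagonal contact joins regions (8-connectivity)
  m2 <- matrix(FALSE, 6, 6); m2[2, 2] <- TRUE; m2[3, 3] <- TRUE
  attr(m2, "pixel_scale") <- 1
  expect_identical(nrow(label_regions(m2)), 1L)

  # 10x10 square: Crofton perimeter within the documented 10% of 40
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  attr(sq, "pixel_scale") <- 1
  expect_equal(label_regions(sq)$perimeter_px, 40, tolerance = 0.10)

  empty <- matrix(FALSE, 5, 5); attr(empty, "pixel_scale") <- 1
  expect_identical(nrow(label_regions(empty)), 0L)

  edge <- matrix(FALSE, 5, 5); edge[1, 2:3] <- TRUE
  attr(edge, "pixel_scale") <- 1
  expect_true(label_regions(edge)$touches_border)
})

test_that("remove_stacked rejects a merged doublet but keeps identical singles", {
  side <- 60L
  m <- matrix(FALSE, side, side)
  put_disc <- function(m, centre, r)
    m | disc_mask(r, side = nrow(m), centre = centre)
  for (cen in list(c(10, 10), c(10, 30), c(10, 50), c(30, 10), c(50, 10),
                   c(30, 50), c(50, 30)))
    m <- put_disc(m, cen, 5)
  # strongly-overlapped doublet: centres 0.9 * (r1 + r2) apart
  m <- put_disc(m, c(40, 35), 5)
  m <- put_disc(m, c(40, 44), 5)
  attr(m, "pixel_scale") <- 1
  parts <- remove_stacked(label_regions(m))
  expect_identical(nrow(parts$rejected), 1L)
  expect_identical(nrow(parts$kept), 7L)
  expect_true(all(parts$rejected$area_px > max(parts$kept$area_px)))

  # identical discs only: nothing rejected; idempotent on the kept set
  singles <- label_regions(structure(
    put_disc(put_disc(matrix(FALSE, 40, 40), c(10, 10), 5), c(28, 28), 5),
    pixel_scale = 1))
  p2 <- remove_stacked(singles)
  expect_identical(nrow(p2$rejected), 0L)
  p3 <- remove_stacked(p2$kept)
  expect_identical(nrow(p3$rejected), 0L)

  empty <- singles[0, ]
  pe <- remove_stacked(empty)
  expect_identical(nrow(pe$kept), 0L)
  expect_identical(nrow(pe$rejected), 0L)
})

test_that("segmentation of clean scenes conserves the cell count and rotates", {
  sc <- clean_scene(n_cells = 25, field = 110, seed = 9)
  regs <- segment_frame(sc$pre)
  kept <- sum(!regs$rejected_stacked & !regs$touches_border)
  expect_identical(kept, 25L)

  # 90 degree rotation: same count, same multiset of areas
  rot <- image_frame(t(sc$pre$pixels)[ncol(sc$pre$pixels):1, ],
                     sc$pre$pixel_scale)
  regs_rot <- segment_frame(rot)
  expect_identical(nrow(regs_rot), nrow(regs))
  expect_identical(sort(regs_rot$area_px), sort(regs$area_px))
  expect_equal(sort(regs_rot$perimeter_px), sort(regs$perimeter_px),
               tolerance = 1e-12)
})
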