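test_that("Bland-Altman bias, SD and LOA identities", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  g <- glance(bland_altman(d, x, y))
  expect_equal(c(g$bias, g$sd_diff, g$loa_low, g$loa_high), c(0, 0, 0, 0))

  d2 <- data.frame(x = c(1, 2, 3), y = c(6, 7, 8))
  g2 <- glance(bland_altman(d2, x, y))
  expect_equal(g2$bias, 5); expect_equal(g2$sd_diff, 0)

  d3 <- data.frame(x = c(0, 0, 0) + 10, y = 10 + c(-1, 0, 1))
  g3 <- glance(bland_altman(d3, x, y))
  expect_equal(g3$bias, 0)
  expect_equal(g3$sd_diff, 1)
  expect_equal(c(g3$loa_low, g3$loa_high), c(-1.96, 1.96))

  expect_error(bland_altman(d3[1:2, ], x, y), "at least 3")

  set.seed(8)
  d4 <- data.frame(x = rnorm(40, 100, 10), y = rnorm(40, 100, 10))
  g4 <- glance(bland_altman(d4, x, y))
  expect_equal(g4$loa_low, g4$bias - 1.96 * g4$sd_diff, tolerance = 1e-12)
  expect_equal(g4$loa_high, g4$bias + 1.96 * g4$sd_diff, tolerance = 1e-12)

  # direction and percent-mode conventions
  g5 <- glance(bland_altman(d2, x, y, direction = "x_minus_y"))
  expect_equal(g5$bias, -5)
  d6 <- data.frame(x = c(100, 200, 300), y = c(110, 220, 330))
  g6 <- glance(bland_altman(d6, x, y, mode = "percent"))
  expect_equal(g6$bias, 100 * 10 / 105, tolerance = 1e-9)
})

test_that("Passing-Bablok recovers exact affine relations", {
  d <- data.frame(x = 1:12, y = 1:12)
  f <- passing_bablok(d, x, y)
  expect_equal(f$slope, 1); expect_equal(f$intercept, 0)

  d2 <- data.frame(x = 1:15, y = 2 * (1:15) + 3)
  f2 <- passing_bablok(d2, x, y)
  expect_equal(f2$slope, 2); expect_equal(f2$intercept, 3)

  expect_error(passing_bablok(d[1:5, ], x, y), "at least 10")
  expect_error(passing_bablok(data.frame(x = rep(1, 12), y = 1:12), x, y),
               "not all be equal")
})

pb_slope_oracle <- function(x, y) {
  # direct O(n^2) enumeration of the shifted-median slope
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- c(s, if (dx == 0) sign(dy) * Inf else dy / dx)
  }
  s <- sort(s[s != -1])
  N <- length(s); K <- sum(s < -1)
  if (N %% 2 == 1) s[(N + 1) %/% 2 + K] else
    mean(c(s[N %/% 2 + K], s[N %/% 2 + 1 + K]))
}

test_that("Passing-Bablok slope equals the brute-force enumeration oracle", {
  set.seed(12)
  for (trial in 1:4) {
    x <- round(runif(12, 1, 30), 1)
    y <- round(1.3 * x + 2 + rnorm(12, 0, 1.5), 1)
    f <- passing_bablok(data.frame(x, y), x, y)
    expect_equal(f$slope, pb_slope_oracle(x, y), tolerance = 1e-12)
    expect_equal(f$intercept, median(y - f$slope * x), tolerance = 1e-12)
    expect_true(f$slope_ci[1] <= f$slope && f$slope <= f$slope_ci[2])
  }
})

test_that("Passing-Bablok is scale-equivariant", {
  # equivariance is exact while no pairwise slope crosses the -1 handling
  # boundary; strictly increasing data keeps every slope positive
  set.seed(13)
  x <- cumsum(runif(20, 1, 3))
  y <- 0.9 * x + runif(20, 0, 0.4)
  stopifnot(all(diff(y) > 0))
  f1 <- passing_bablok(data.frame(x, y), x, y)
  f2 <- passing_bablok(data.frame(x, y = 3 * y), x, y)
  expect_equal(f2$slope, 3 * f1$slope, tolerance = 1e-12)
})

test_that("ROC handles separable and uninformative scores", {
  d <- data.frame(s = c(1:10, 21:30), lab = rep(c("neg", "pos"), each = 10))
  r <- roc_analysis(d, s, lab, pos_class = "pos")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  d2 <- data.frame(s = rep(5, 20), lab = rep(c("neg", "pos"), each = 10))
  expect_equal(roc_analysis(d2, s, lab, pos_class = "pos")$auc, 0.5)

  expect_error(roc_analysis(d[d$lab == "pos", ], s, lab), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney pair count", {
  set.seed(14)
  for (trial in 1:4) {
    s <- round(rnorm(20), 1)                      # ties likely
    lab <- sample(rep(c("a", "b"), each = 10))
    r <- roc_analysis(data.frame(s, lab), s, lab, pos_class = "b")
    pos <- s[lab == "b"]; neg <- s[lab == "a"]
    mw <- mean(outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`))
    expect_equal(r$auc, mw, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(15)
  s <- rnorm(30); lab <- sample(rep(c("a", "b"), 15))
  a1 <- roc_analysis(data.frame(s, lab), s, lab)$auc
  a2 <- roc_analysis(data.frame(s = exp(2 * s), lab), s, lab)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  set.seed(16)
  s <- c(rnorm(25, 0), rnorm(25, 1.2))
  lab <- rep(c(0, 1), each = 25)
  r <- roc_analysis(data.frame(s, lab), s, lab, pos_class = 1)
  pr <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$auc_ci[1], ci[1], tolerance = 1e-6)
  expect_equal(r$auc_ci[2], ci[3], tolerance = 1e-6)
})

test_that("mountain plot folds percentiles and centers on the median", {
  d <- data.frame(x = rep(0, 9), y = c(-4, -3, -2, -1, 0, 1, 2, 3, 4))
  m <- mountain_plot(d, x, y)
  expect_equal(m$center, 0)
  expect_true(all(m$curve$folded <= 50))

  d2 <- data.frame(x = rep(0, 100), y = 1:100)
  m2 <- mountain_plot(d2, x, y)
  expect_equal(m2$p5, 5)
  expect_equal(m2$p95, 95)
  expect_equal(m2$center, 50.5)

  set.seed(17)
  d3 <- data.frame(x = rnorm(37), y = rnorm(37))
  m3 <- mountain_plot(d3, x, y)
  expect_true(all(m3$curve$folded <= 50))
  expect_equal(m3$center, median(d3$y - d3$x))
})

test_that("result objects expose tidy/glance/autoplot surfaces", {
  set.seed(18)
  d <- data.frame(x = rnorm(20, 10), y = rnorm(20, 10))
  ba <- bland_altman(d, x, y)
  expect_s3_class(tidy(ba), "tbl_df")
  expect_s3_class(autoplot(ba), "ggplot")
  mp <- mountain_plot(d, x, y)
  expect_s3_class(autoplot(mp), "ggplot")
  lab <- rep(c(0, 1), 10)
  rc <- roc_analysis(data.frame(s = d$x, lab), s, lab)
  expect_s3_class(autoplot(rc), "ggplot")
  pb <- passing_bablok(d, x, y)
  expect_s3_class(autoplot(pb), "ggplot")
  expect_identical(nrow(tidy(pb)), 2L)
})
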