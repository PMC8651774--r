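#' Bland-Altman agreement analysis
#'
#' Per-pair differences between a device and a comparator, their mean
#' (bias), sample SD, and the 95% limits of agreement `bias +/- 1.96 * SD`.
#' The difference convention is explicit: `direction = "y_minus_x"`
#' (default) or `"x_minus_y"`; `mode = "percent"` expresses each difference
#' as percent of the pairwise mean (used for morphology comparisons),
#' `"absolute"` keeps raw units (used for counts).
#'
#' @param data data frame of paired measurements.
#' @param x,y unquoted column names: comparator and device values.
#' @param mode `"absolute"` or `"percent"`.
#' @param direction difference convention.
#' @return object of class `rbc_bland_altman`; see [tidy()]/[glance()].
#' @examples
#' d <- data.frame(a = 1:10, b = 1:10 + c(-1, 1))
#' glance(bland_altman(d, a, b))
#' @export
bland_altman <- function(data, x, y, mode = c("absolute", "percent"),
                         direction = c("y_minus_x", "x_minus_y")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3L) abort("Bland-Altman needs at least 3 pairs")
  d <- if (direction == "y_minus_x") yv - xv else xv - yv
  m <- (xv + yv) / 2
  if (mode == "percent") {
    if (any(m == 0)) abort("percent mode undefined when a pairwise mean is 0")
    d <- 100 * d / m
  }
  bias <- mean(d)
  s <- sd(d)
  structure(list(
    data = tibble(x = xv, y = yv, mean = m, diff = d),
    bias = bias, sd_diff = s,
    loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = n, mode = mode, direction = direction
  ), class = "rbc_bland_altman")
}

#' Passing-Bablok method-comparison regression
#'
#' Non-parametric regression for method comparison: the slope is the
#' shifted median of all pairwise slopes (slopes equal to -1 discarded,
#' the median offset by the number of slopes below -1, per the original
#' procedure), the intercept is `median(y - slope * x)`. Confidence bounds
#' use the classical rank-based intervals (normal approximation of the
#' Kendall statistic).
#'
#' @param data data frame of paired measurements.
#' @param x,y unquoted column names: comparator and device values.
#' @param conf confidence level (default 0.95).
#' @return object of class `rbc_passing_bablok` with `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`.
#' @export
passing_bablok <- function(data, x, y, conf = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 10L) abort("Passing-Bablok needs at least 10 pairs")
  if (length(unique(xv)) < 2L) abort("x values must not all be equal")
  ij <- utils::combn(n, 2L)
  dx <- xv[ij[2, ]] - xv[ij[1, ]]
  dy <- yv[ij[2, ]] - yv[ij[1, ]]
  keep <- !(dx == 0 & dy == 0)               # identical points carry no slope
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[s != -1]                            # per the original method
  s <- sort(s)
  N <- length(s)
  if (N == 0L) abort("no usable pairwise slopes")
  K <- sum(s < -1)
  med_at <- function(pos) {
    pos <- pmin(pmax(pos, 1L), N)
    s[pos]
  }
  b <- if (N %% 2L == 1L) med_at((N + 1L) %/% 2L + K) else
    mean(c(med_at(N %/% 2L + K), med_at(N %/% 2L + 1L + K)))
  z <- qnorm(1 - (1 - conf) / 2)
  w <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- as.integer(round((N - w) / 2))
  M2 <- N - M1 + 1L
  b_lo <- med_at(M1 + K)
  b_hi <- med_at(M2 + K)
  a <- median(yv - b * xv)
  a_lo <- median(yv - b_hi * xv)
  a_hi <- median(yv - b_lo * xv)
  structure(list(
    data = tibble(x = xv, y = yv),
    slope = b, slope_ci = c(b_lo, b_hi),
    intercept = a, intercept_ci = c(a_lo, a_hi),
    n = n, conf = conf
  ), class = "rbc_passing_bablok")
}

#' ROC analysis with Youden-optimal threshold
#'
#' Empirical ROC curve (higher score means more likely positive), trapezoid
#' AUC (equal to the Mann-Whitney probability with ties counted half), the
#' threshold maximizing Youden's J, and confidence intervals: DeLong for
#' the AUC, Clopper-Pearson (exact binomial) for sensitivity and
#' specificity at the chosen threshold.
#'
#' @param data data frame.
#' @param score,label unquoted columns: numeric score, and class label.
#' @param pos_class value of `label` treated as positive (default: the
#'   larger of the two sorted unique values).
#' @param conf confidence level.
#' @return object of class `rbc_roc` with `auc`, `auc_ci`, `threshold`
#'   (score cutoff, predict positive at `score >= threshold`),
#'   `sensitivity`, `sensitivity_ci`, `specificity`, `specificity_ci`, and
#'   the full `curve` tibble.
#' @export
roc_analysis <- function(data, score, label, pos_class = NULL, conf = 0.95) {
  sc <- dplyr::pull(data, {{ score }})
  lb <- dplyr::pull(data, {{ label }})
  u <- sort(unique(lb))
  if (length(u) < 2L) abort("both classes must be present")
  if (length(u) > 2L) abort("ROC analysis needs exactly two classes")
  if (is.null(pos_class)) pos_class <- u[2]
  pos <- sc[lb == pos_class]
  neg <- sc[lb != pos_class]
  ths <- sort(unique(sc), decreasing = TRUE)
  sens <- vapply(ths, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(neg >= t), numeric(1))
  curve <- tibble(threshold = c(Inf, ths, -Inf),
                  sensitivity = c(0, sens, 1),
                  specificity = 1 - c(0, fpr, 1))
  o <- order(1 - curve$specificity, curve$sensitivity)
  xs <- (1 - curve$specificity)[o]; ys <- curve$sensitivity[o]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  # DeLong variance from placement values
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  var_auc <- stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
  if (!is.finite(var_auc)) var_auc <- 0
  z <- qnorm(1 - (1 - conf) / 2)
  auc_ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(var_auc)))
  j <- sens + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]          # tie-break: favor sensitivity
  thr <- ths[best]
  tp <- sum(pos >= thr); fn <- length(pos) - tp
  tn <- sum(neg < thr); fp <- length(neg) - tn
  sens_ci <- binom.test(tp, tp + fn, conf.level = conf)$conf.int
  spec_ci <- binom.test(tn, tn + fp, conf.level = conf)$conf.int
  structure(list(
    curve = curve, auc = auc, auc_ci = auc_ci,
    threshold = thr,
    sensitivity = tp / (tp + fn), sensitivity_ci = as.numeric(sens_ci),
    specificity = tn / (tn + fp), specificity_ci = as.numeric(spec_ci),
    n_pos = length(pos), n_neg = length(neg),
    pos_class = pos_class, conf = conf
  ), class = "rbc_roc")
}

#' Mountain (folded empirical percentile) plot of paired differences
#'
#' Ranks the differences `y - x`, assigns Hazen percentiles
#' `100 * (i - 0.5) / n`, and folds every percentile above 50 to
#' `100 - percentile`. The mountain's center is the median difference; the
#' reported 5th/95th percentile differences use the inverse empirical CDF.
#'
#' @param data data frame of paired measurements.
#' @param x,y unquoted column names: comparator and device values.
#' @return object of class `rbc_mountain` with `curve` (tibble: `diff`,
#'   `percentile`, `folded`), `center`, `p5`, `p95`.
#' @export
mountain_plot <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 3L) abort("mountain plot needs at least 3 pairs")
  d <- sort(yv - xv)
  pct <- 100 * (seq_len(n) - 0.5) / n
  folded <- ifelse(pct > 50, 100 - pct, pct)
  structure(list(
    curve = tibble(diff = d, percentile = pct, folded = folded),
    center = median(d),
    p5 = quantile(d, 0.05, type = 1, names = FALSE),
    p95 = quantile(d, 0.95, type = 1, names = FALSE),
    n = n
  ), class = "rbc_mountain")
}
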