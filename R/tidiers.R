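# broom-style tidiers for the result objects.

#' @export
tidy.rbc_bland_altman <- function(x, ...) x$data

#' @export
glance.rbc_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
         loa_high = x$loa_high, n = x$n, mode = x$mode,
         direction = x$direction)
}

#' @export
tidy.rbc_passing_bablok <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf.high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' @export
glance.rbc_passing_bablok <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, n = x$n, conf = x$conf)
}

#' @export
tidy.rbc_roc <- function(x, ...) x$curve

#' @export
glance.rbc_roc <- function(x, ...) {
  tibble(
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
    threshold = x$threshold,
    sensitivity = x$sensitivity,
    sensitivity_low = x$sensitivity_ci[1],
    sensitivity_high = x$sensitivity_ci[2],
    specificity = x$specificity,
    specificity_low = x$specificity_ci[1],
    specificity_high = x$specificity_ci[2],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
tidy.rbc_mountain <- function(x, ...) x$curve

#' @export
glance.rbc_mountain <- function(x, ...) {
  tibble(center = x$center, p5 = x$p5, p95 = x$p95, n = x$n)
}

#' @export
tidy.rbc_classifier <- function(x, ...) x$metrics

#' @export
glance.rbc_classifier <- function(x, ...) {
  tibble(n_classes = length(x$classes),
         n_cycles = nrow(x$metrics),
         mean_val_accuracy = mean(x$metrics$val_accuracy),
         features = paste(x$config$features, collapse = "+"))
}

#' @export
tidy.rbc_match <- function(x, ...) x$pairs

#' @export
glance.rbc_match <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         n_unmatched_pre = nrow(x$unmatched_pre),
         n_unmatched_post = nrow(x$unmatched_post),
         dr_mean = if (nrow(x$pairs)) mean(x$pairs$dr) else NA_real_)
}
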