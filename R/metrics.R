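# Agreement and error statistics for paired diameter measurements:
# MAPE, MAE, RMSE, the residual-based R^2, Lin's concordance correlation,
# the Wilcoxon signed-rank comparison and box-plot summary statistics.
#
# All functions take a data frame first, with columns `measured_mm` (the
# method under evaluation, w) and `true_mm` (the manual caliper reference,
# k), so calls chain with the pipe.

check_pairs <- function(pairs, require_positive = TRUE) {
  stopifnot(is.data.frame(pairs),
            all(c("measured_mm", "true_mm") %in% names(pairs)))
  w <- pairs$measured_mm; k <- pairs$true_mm
  if (length(w) != length(k) || length(w) < 2) {
    rlang::abort("need at least 2 complete pairs",
                 class = "stemdepth_parameter_error")
  }
  if (require_positive && (any(w <= 0) || any(k <= 0))) {
    rlang::abort("diameters must be positive",
                 class = "stemdepth_parameter_error")
  }
  list(w = w, k = k)
}

#' Mean absolute percentage error
#'
#' `mean(|w - k| / k) * 100`, in percent.
#'
#' @param pairs Data frame with columns `measured_mm` (w) and `true_mm` (k).
#' @return A single number.
#' @export
mape <- function(pairs) {
  p <- check_pairs(pairs)
  if (any(p$k == 0)) {
    rlang::abort("true values must be nonzero", class = "stemdepth_parameter_error")
  }
  mean(abs(p$w - p$k) / p$k) * 100
}

#' Mean absolute error (mm)
#' @inheritParams mape
#' @return A single number in mm.
#' @export
mae <- function(pairs) {
  p <- check_pairs(pairs)
  mean(abs(p$w - p$k))
}

#' Root mean square error (mm)
#' @inheritParams mape
#' @return A single number in mm; always `>= mae`.
#' @export
rmse <- function(pairs) {
  p <- check_pairs(pairs)
  sqrt(mean((p$w - p$k)^2))
}

#' Residual-based coefficient of determination
#'
#' `1 - sum((k - w)^2) / sum((k - mean(k))^2)`: the variance in the manual
#' measurements explained by taking the method's values at face value.
#' Note this is not the R-squared of a fitted regression; no line is fitted.
#'
#' @inheritParams mape
#' @return A single number `<= 1` (negative when the method is worse than
#'   predicting the mean).
#' @export
r2 <- function(pairs) {
  p <- check_pairs(pairs)
  ss_tot <- sum((p$k - mean(p$k))^2)
  if (ss_tot == 0) {
    rlang::abort("true values are constant; R^2 undefined",
                 class = "stemdepth_degenerate_error")
  }
  1 - sum((p$k - p$w)^2) / ss_tot
}

#' Lin's concordance correlation coefficient
#'
#' `2 * rho * sx * sy / (sx^2 + sy^2 + (mx - my)^2)` with Pearson's rho and
#' population (1/n) standard deviations, penalising both correlation loss
#' and location/scale shift between the two measurement sets.
#'
#' @inheritParams mape
#' @return A single number in `[-1, 1]`.
#' @export
ccc <- function(pairs) {
  p <- check_pairs(pairs)
  n <- length(p$w)
  vx <- sum((p$w - mean(p$w))^2) / n
  vy <- sum((p$k - mean(p$k))^2) / n
  if (vx == 0 || vy == 0) {
    rlang::abort("a measurement vector is constant; CCC undefined",
                 class = "stemdepth_degenerate_error")
  }
  rho <- stats::cor(p$w, p$k)
  2 * rho * sqrt(vx * vy) / (vx + vy + (mean(p$w) - mean(p$k))^2)
}

#' Wilcoxon signed-rank test on paired measurements
#'
#' Two-sided test of a systematic difference between the method and the
#' manual measurements. Zero differences are dropped (Wilcoxon's rule). The
#' default mode is the normal approximation with tie-corrected variance and
#' continuity correction; `mode = "exact"` uses the exact signed-rank
#' distribution (tie-free data, n <= 25) or, with ties, full enumeration of
#' the 2^n sign assignments for n <= 20.
#'
#' @inheritParams mape
#' @param mode `"approx"` (default) or `"exact"`.
#' @return The two-sided p-value. All differences zero gives the degenerate
#'   p = 1.
#' @export
wilcoxon_signed_rank <- function(pairs, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  p <- check_pairs(pairs, require_positive = FALSE)
  d <- p$w - p$k
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  if (mode == "approx") {
    return(suppressWarnings(
      stats::wilcox.test(p$w, p$k, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value))
  }
  r <- rank(abs(d))
  if (!any(duplicated(r)) && length(d) <= 25) {
    return(stats::wilcox.test(p$w, p$k, paired = TRUE, exact = TRUE)$p.value)
  }
  if (length(d) > 20) {
    rlang::abort("exact mode with ties supports n <= 20",
                 class = "stemdepth_parameter_error")
  }
  wilcoxon_exact_enumeration(d)
}

# two-sided p by enumerating all 2^n sign assignments of |d| (handles ties)
wilcoxon_exact_enumeration <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

#' Box-plot summary statistics
#'
#' @param values Nonempty numeric vector.
#' @param quartile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A one-row tibble with `median`, `q1`, `q3`, `iqr` (= q3 - q1)
#'   and `width` (= max - min).
#' @export
summary_stats <- function(values, quartile_type = 7) {
  stopifnot(length(values) >= 1, is.numeric(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = quartile_type,
                       names = FALSE)
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
                 width = max(values) - min(values))
}

#' Full evaluation report for paired measurements
#'
#' Computes every agreement statistic at once and carries the data for
#' plotting. `glance()` returns the one-row statistics tibble, `tidy()` a
#' long `(metric, value)` form, and `autoplot()` a measured-vs-true scatter
#' with the identity line.
#'
#' @inheritParams mape
#' @param quartile_type Quantile convention for the box-plot statistics.
#' @return An object of class `metrics_report`.
#' @examples
#' tb <- stem_tables()$table1
#' rep <- stem_metrics(tb)
#' glance(rep)
#' @export
stem_metrics <- function(pairs, quartile_type = 7) {
  check_pairs(pairs)
  sm <- summary_stats(pairs$measured_mm, quartile_type)
  sk <- summary_stats(pairs$true_mm, quartile_type)
  stats <- tibble::tibble(
    n = nrow(pairs),
    mape = mape(pairs), mae = mae(pairs), rmse = rmse(pairs),
    r2 = r2(pairs), ccc = ccc(pairs),
    wilcoxon_p = wilcoxon_signed_rank(pairs),
    median_measured = sm$median, median_true = sk$median,
    q1_measured = sm$q1, q3_measured = sm$q3, iqr_measured = sm$iqr,
    width_measured = sm$width,
    q1_true = sk$q1, q3_true = sk$q3, iqr_true = sk$iqr,
    width_true = sk$width)
  structure(list(stats = stats, pairs = tibble::as_tibble(pairs),
                 quartile_type = quartile_type),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf(paste0("<metrics_report> n = %d\n",
                     "  MAPE %.2f%%  MAE %.2f mm  RMSE %.2f mm\n",
                     "  R^2 %.2f  CCC %.3f  Wilcoxon p %.4f\n",
                     "  median measured %.2f mm / true %.2f mm\n"),
              s$n, s$mape, s$mae, s$rmse, s$r2, s$ccc, s$wilcoxon_p,
              s$median_measured, s$median_true))
  invisible(x)
}

#' @export
#' @rdname metrics_report_tidiers
#' @method glance metrics_report
glance.metrics_report <- function(x, ...) x$stats

#' Tidiers for metrics reports
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @name metrics_report_tidiers
#' @export
#' @method tidy metrics_report
tidy.metrics_report <- function(x, ...) {
  tidyr::pivot_longer(x$stats, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
#' @method autoplot metrics_report
autoplot.metrics_report <- function(object, ...) {
  s <- object$stats
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$true_mm, y = .data$measured_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "manual diameter (mm)", y = "measured diameter (mm)",
      title = sprintf("MAPE %.2f%%, MAE %.2f mm, RMSE %.2f mm, R² %.2f, CCC %.3f",
                      s$mape, s$mae, s$rmse, s$r2, s$ccc))
}

#' Packaged field measurement tables
#'
#' Two tables of 60 paired stem diameters transcribed from the published
#' field study: `table1` compares the depth-information method with manual
#' caliper measurements, `table2` the checkerboard pinhole-imaging baseline
#' with the same manual measurements.
#'
#' @return A named list of two tibbles with columns `id`, `measured_mm`,
#'   `true_mm`.
#' @export
stem_tables <- function() {
  rd <- function(f) {
    tibble::as_tibble(utils::read.csv(
      system.file("extdata", f, package = "stemdepth", mustWork = TRUE)))
  }
  list(table1 = rd("table1.csv"), table2 = rd("table2.csv"))
}
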