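## Method-comparison statistics: Bland-Altman limits of agreement, Pearson
## correlation with Fisher-transform confidence interval, ICC(2,1)
## (two-way random effects, single measurement, absolute agreement), and
## Fisher r-to-Z comparison of correlations from independent groups.

#' Bland-Altman agreement analysis
#'
#' Differences are `test - reference`; the limits of agreement are the
#' mean difference minus and plus 1.96 times the sample standard deviation
#' (n-1 denominator) of the differences, and the confidence interval of
#' the mean difference is `mean +/- 1.96 * SD / sqrt(n)`.
#'
#' @param pairs a [paired_measurements()] with n >= 2.
#' @return object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `ci_mean_lower`, `ci_mean_upper`, `n`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$test - pairs$reference
  n <- length(d)
  if (n < 2L) stopf("Bland-Altman analysis needs n >= 2")
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 ci_mean_lower = m - 1.96 * s / sqrt(n),
                 ci_mean_upper = m + 1.96 * s / sqrt(n),
                 n = n, label = pairs$label),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman%s: bias %.3f (SD %.3f), LoA [%.3f, %.3f], 95%% CI of bias [%.3f, %.3f], n=%d\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper,
              x$ci_mean_lower, x$ci_mean_upper, x$n))
  invisible(x)
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Sample Pearson r; two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))`;
#' confidence interval by back-transforming `atanh(r) +/- z / sqrt(n-3)`.
#'
#' @param pairs a [paired_measurements()] with n >= 4 and non-degenerate
#'   variance in both vectors.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `correlation_result`: `r`, `ci_lower`,
#'   `ci_upper`, `p_value`, `n`.
#' @export
pearson_with_ci <- function(pairs, conf_level = 0.95) {
  x <- pairs$test; y <- pairs$reference
  n <- length(x)
  if (n < 4L) stopf("Pearson correlation with CI needs n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in one of the vectors")
  r <- stats::cor(x, y)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-1, 1) * z * se)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  structure(list(r = r, ci_lower = ci[1L], ci_upper = ci[2L],
                 p_value = p, n = n, label = pairs$label),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r%s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$r, x$ci_lower, x$ci_upper, x$p_value, x$n))
  invisible(x)
}

## two-way (subjects x raters) mean squares for an n x k table
twoway_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  list(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
       mse = ss_err / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Intraclass correlation ICC(2,1): two-way random, single measurement,
#' absolute agreement
#'
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` from the
#' two-way subjects-by-raters ANOVA decomposition; the confidence interval
#' follows the F-based absolute-agreement procedure (McGraw-Wong style,
#' with the Satterthwaite degrees of freedom), and the p-value comes from
#' `F = MSR / MSE` against `F(n-1, (n-1)(k-1))`.
#'
#' @param pairs a [paired_measurements()] (k = 2 raters) with n >= 5, or an
#'   n x k numeric matrix (subjects in rows, raters in columns).
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`, `k`, `model_tag`.
#' @export
icc_2_1 <- function(pairs, conf_level = 0.95) {
  m <- if (inherits(pairs, "paired_measurements"))
    cbind(pairs$test, pairs$reference) else as.matrix(pairs)
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stopf("ICC(2,1) needs at least 5 subjects")
  if (k < 2L) stopf("ICC(2,1) needs at least 2 raters")
  if (stats::var(as.vector(m)) == 0) stopf("degenerate table: zero total variance")
  ms <- twoway_mean_squares(m)
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  ## F-based CI for ICC(A,1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
       ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
           (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
           (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  ## perfect agreement (zero residual and rater variance) degenerates the
  ## F-based interval; collapse it onto the point estimate
  if (!is.finite(lower)) lower <- icc
  if (!is.finite(upper)) upper <- icc
  fstat <- msr / mse
  p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, ci_lower = lower, ci_upper = upper,
                 p_value = p, n = n, k = k,
                 model_tag = "two-way random, single measurement, absolute agreement",
                 label = if (inherits(pairs, "paired_measurements")) pairs$label else ""),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1)%s = %.3f (95%% CI %.3f-%.3f), p = %.3g, n = %d [%s]\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$icc, x$ci_lower, x$ci_upper, x$p_value, x$n, x$model_tag))
  invisible(x)
}

#' Fisher r-to-Z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 group sizes, >= 4.
#' @return object of class `fisher_comparison`: `z_stat`, `p_value`, and
#'   the inputs.
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stopf("|r| must be < 1 (Fisher transform diverges)")
  if (n1 < 4L || n2 < 4L) stopf("group sizes must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z_stat = z, p_value = 2 * stats::pnorm(-abs(z)),
                 r1 = r1, n1 = n1, r2 = r2, n2 = n2),
            class = "fisher_comparison")
}

#' @export
print.fisher_comparison <- function(x, ...) {
  cat(sprintf("Fisher r-to-Z: z = %.3f, p = %.3g (r1 = %.3f, n1 = %d; r2 = %.3f, n2 = %d)\n",
              x$z_stat, x$p_value, x$r1, x$n1, x$r2, x$n2))
  invisible(x)
}

agreement_block <- function(pairs) {
  out <- list(n = pairs$n)
  out$bland_altman <- if (pairs$n >= 2L) unclass_keep(bland_altman(pairs)) else NULL
  out$pearson <- if (pairs$n >= 4L &&
                     stats::sd(pairs$test) > 0 && stats::sd(pairs$reference) > 0)
    unclass_keep(pearson_with_ci(pairs)) else NULL
  out$icc <- if (pairs$n >= 5L && stats::var(c(pairs$test, pairs$reference)) > 0)
    unclass_keep(icc_2_1(pairs)) else NULL
  out
}

unclass_keep <- function(x) { attributes(x) <- list(names = names(x)); x }

#' Evaluate a platform against a reference
#'
#' Runs the full agreement battery mirroring a clinical method-comparison
#' layout: for each tissue (lumen, plaque) at three levels -- per-segment
#' volumes, per-plane areas, and per-plane areas restricted to the stenotic
#' (reference plaque burden > threshold) subgroup -- Bland-Altman, Pearson
#' and ICC(2,1) statistics are computed. Per-segment volume agreement
#' requires several segments; pass lists of profiles for a multi-segment
#' cohort (single profiles are treated as a one-segment cohort, whose
#' volume block carries NA statistics).
#'
#' @param test an `area_profile` or list of them (one per segment).
#' @param reference matching `area_profile`(s), e.g. fine-interval
#'   reference profiles.
#' @param offset arclength shift applied to each reference, mm (scalar or
#'   per segment).
#' @param burden_threshold stenotic-subgroup burden threshold (default 0.6).
#' @return nested list of class `latm_report`: `analysis` (volume / area /
#'   stenotic_area) -> tissue (lumen / plaque) -> statistics. ICC-vs-ICC
#'   platform comparisons, when made, reuse [fisher_compare()] on the ICC
#'   values (method tag `"fisher-z-on-icc"`).
#' @export
evaluate_platform <- function(test, reference, offset = 0,
                              burden_threshold = 0.6) {
  if (inherits(test, "area_profile")) test <- list(test)
  if (inherits(reference, "area_profile")) reference <- list(reference)
  if (length(test) != length(reference))
    stopf("test and reference cohorts must have the same number of segments")
  nseg <- length(test)
  offset <- rep_len(offset, nseg)

  pool <- function(which) {
    ps <- lapply(seq_len(nseg), function(i)
      align_and_pair(test[[i]], reference[[i]], offset[i], which))
    list(test = unlist(lapply(ps, `[[`, "test")),
         reference = unlist(lapply(ps, `[[`, "reference")),
         burden = unlist(lapply(ps, attr, "reference_burden")))
  }
  report <- list()
  for (tissue in c("lumen", "plaque")) {
    pl <- pool(tissue)
    pairs_area <- paired_measurements(pl$test, pl$reference,
                                      label = paste0(tissue, "_area"))
    sten <- stenotic_subset(pairs_area, pl$burden, burden_threshold)
    vols_t <- vapply(test, volume_sum, numeric(1), which = tissue)
    vols_r <- vapply(reference, volume_simpson, numeric(1), which = tissue)
    pairs_vol <- paired_measurements(vols_t, vols_r,
                                     label = paste0(tissue, "_volume"))
    report$volume[[tissue]] <- agreement_block(pairs_vol)
    report$area[[tissue]] <- agreement_block(pairs_area)
    report$stenotic_area[[tissue]] <- agreement_block(sten)
  }
  structure(list(analyses = report, n_segments = nseg,
                 burden_threshold = burden_threshold,
                 icc_comparison_method = "fisher-z-on-icc"),
            class = "latm_report")
}

#' @export
print.latm_report <- function(x, ...) {
  cat(sprintf("<latm_report> %d segment(s), stenotic threshold %.2f\n",
              x$n_segments, x$burden_threshold))
  for (an in names(x$analyses)) for (ti in names(x$analyses[[an]])) {
    b <- x$analyses[[an]][[ti]]
    icc <- if (!is.null(b$icc)) sprintf("%.3f", b$icc$icc) else "NA"
    r <- if (!is.null(b$pearson)) sprintf("%.3f", b$pearson$r) else "NA"
    bias <- if (!is.null(b$bland_altman)) sprintf("%.3f", b$bland_altman$mean_diff) else "NA"
    cat(sprintf("  %-14s %-7s n=%-6d bias=%-8s r=%-6s ICC=%s\n",
                an, ti, b$n, bias, r, icc))
  }
  invisible(x)
}
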