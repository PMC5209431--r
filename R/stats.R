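# Group comparison (unpaired t-tests) and repeatability (single-measure ICC).

#' Unpaired two-sample t-test from summary statistics
#'
#' Pooled-variance (default) or Welch form, computed directly from group
#' means, SDs and sizes so the printed summaries of a study can be
#' re-analysed without raw data. `t = (m2 - m1) / se`, two-sided p.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return a `group_comparison` list: `t`, `df`, `p`, the inputs and the
#'   variant. Both variances zero with equal means gives `t = 0, p = 1`;
#'   zero variances with unequal means leaves `t`/`p` as `NA`
#'   (`degenerate = TRUE`).
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  degenerate <- FALSE
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      tval <- 0; df <- if (variant == "pooled") n1 + n2 - 2 else NA_real_; p <- 1
    } else {
      tval <- NA_real_; df <- NA_real_; p <- NA_real_; degenerate <- TRUE
    }
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    tval <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * pt(-abs(tval), df)
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    tval <- (m2 - m1) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * pt(-abs(tval), df)
  }
  structure(list(mean1 = m1, sd1 = s1, n1 = n1, mean2 = m2, sd2 = s2, n2 = n2,
                 t = tval, df = df, p = p, variant = variant,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' Unpaired two-sample t-test on raw values
#'
#' Drops non-finite values (with a message) and delegates to
#' [t_test_summary()] on the sample means and SDs, so the two forms agree
#' by construction.
#'
#' @param values1,values2 numeric vectors (>= 2 finite values each).
#' @inheritParams t_test_summary
#' @export
t_test_raw <- function(values1, values2, variant = c("pooled", "welch")) {
  v1 <- values1[is.finite(values1)]
  v2 <- values2[is.finite(values2)]
  dropped <- length(values1) + length(values2) - length(v1) - length(v2)
  if (dropped > 0)
    message(sprintf("t_test_raw: dropped %d missing value(s)", dropped))
  if (length(v1) < 2 || length(v2) < 2)
    stop("each group needs at least 2 finite values")
  t_test_summary(mean(v1), sd(v1), length(v1), mean(v2), sd(v2), length(v2),
                 variant)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Unpaired t-test (%s): %.2f (%.2f), n=%d vs %.2f (%.2f), n=%d\n",
              x$variant, x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Single-measure intraclass correlation coefficient
#'
#' ICC from the two-way ANOVA mean squares of a subjects x raters matrix
#' (between-subjects MSR, between-raters MSC, residual MSE; for the
#' one-way form, within-subjects MSW):
#' \itemize{
#'   \item `ICC1` — one-way random: `(MSR - MSW) / (MSR + (k-1) MSW)`
#'   \item `ICC2` — two-way random, absolute agreement (default):
#'     `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#'   \item `ICC3` — two-way mixed, consistency:
#'     `(MSR - MSE) / (MSR + (k-1) MSE)`
#' }
#' 95% confidence intervals use the standard F-based formulas
#' (McGraw & Wong single-rater forms). Rows containing missing values are
#' dropped with a message.
#'
#' @param ratings numeric matrix or data.frame, subjects in rows, raters
#'   (or repeated sessions) in columns; >= 3 complete subjects, >= 2 raters.
#' @param form `"ICC2"`, `"ICC3"` or `"ICC1"`.
#' @param conf confidence level (default 0.95).
#' @return an `icc_result` list: `estimate`, `ci_low`, `ci_high`, `form`,
#'   `band` (interpretation label), `n`, `k`.
#' @export
icc <- function(ratings, form = c("ICC2", "ICC3", "ICC1"), conf = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(ratings)
  keep <- complete.cases(x)
  if (any(!keep))
    message(sprintf("icc: dropped %d subject row(s) with missing ratings",
                    sum(!keep)))
  x <- x[keep, , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  stopifnot(n >= 3, k >= 2)

  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - grand)^2)           # between subjects
  ssc <- n * sum((cm - grand)^2)            # between raters
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc                    # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  msw <- (ssc + sse) / (n * (k - 1))

  out <- structure(list(estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, form = form, band = NA_character_,
                        n = n, k = k,
                        ms = c(msr = msr, msc = msc, mse = mse, msw = msw)),
                   class = "icc_result")
  # no between-subject variance: reliability undefined
  if (sst <= 0 || ssr <= 1e-12 * sst) return(out)

  alpha <- 1 - conf
  trans <- function(f) (f - 1) / (f + k - 1)
  if (form == "ICC1") {
    est <- (msr - msw) / (msr + (k - 1) * msw)
    fo <- msr / msw
    lo <- trans(fo / qf(1 - alpha / 2, n - 1, n * (k - 1)))
    hi <- trans(fo * qf(1 - alpha / 2, n * (k - 1), n - 1))
  } else if (form == "ICC3") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) { lo <- hi <- est <- 1 } else {
      fo <- msr / mse
      lo <- trans(fo / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1)))
      hi <- trans(fo * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1))
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse <= 0 && msc <= 0) { lo <- hi <- est } else {
      a <- k * est / (n * (1 - est))
      b <- 1 + k * est * (n - 1) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      if (!is.finite(v)) { lo <- hi <- NA_real_ } else {
        fl <- qf(1 - alpha / 2, n - 1, v)
        fu <- qf(1 - alpha / 2, v, n - 1)
        lo <- n * (msr - fl * mse) /
          (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
        hi <- n * (fu * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * fu * msr)
      }
    }
  }
  out$estimate <- est
  out$ci_low <- min(lo, est)
  out$ci_high <- max(hi, est)
  out$band <- icc_band(est)
  out
}

#' Interpretation band for an ICC estimate
#'
#' Almost perfect for 0.81-1.00, substantial for 0.61-0.80, moderate for
#' 0.40-0.60, below-moderate otherwise; the estimate is rounded to two
#' decimals first so the printed value and its label always agree.
#'
#' @param estimate an ICC value.
#' @return character label.
#' @export
icc_band <- function(estimate) {
  if (!is.finite(estimate)) return(NA_character_)
  r <- round(estimate, 2)
  if (r >= 0.81) "almost perfect"
  else if (r >= 0.61) "substantial"
  else if (r >= 0.40) "moderate"
  else "below-moderate"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.2f (%.2f, %.2f) [%s], n = %d subjects x %d raters\n",
              x$form, x$estimate, x$ci_low, x$ci_high, x$band, x$n, x$k))
  invisible(x)
}
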