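#' Bland-Altman limits of agreement
#'
#' Mean difference of paired measurements and the 1.96-SD limits of
#' agreement, the standard presentation of agreement between two measurement
#' methods. SD uses the n-1 denominator.
#'
#' @param a,b numeric vectors of paired measurements (e.g. manual vs
#'   automated SI), equal length, no missing values.
#' @param ids optional labels for the pairs.
#' @return an object of class `agreement_report` with `mean_diff`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, `n`, and the per-pair `differences`
#'   and `means` (for plotting).
#' @export
bland_altman <- function(a, b, ids = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired series must have equal length")
  if (anyNA(a) || anyNA(b)) stop("paired series must not contain missing values")
  n <- length(a)
  if (n < 2L) stop("sample-size error: need at least 2 pairs")
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa_lower = md - 1.96 * sdd, loa_upper = md + 1.96 * sdd,
                 n = n, differences = d, means = (a + b) / 2, ids = ids),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d, mean diff %.4f, LoA [%.4f, %.4f]\n",
    x$n, x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference against mean with horizontal lines at the mean difference and
#' the two limits of agreement.
#'
#' @param x an `agreement_report` from [bland_altman()].
#' @param ... passed to [plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of methods",
       ylab = "difference (a - b)", ...)
  graphics::abline(h = c(x$loa_lower, x$mean_diff, x$loa_upper),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Two-way random-effects ICC, single measure, absolute agreement
#'
#' ICC(2,1) in the Shrout-Fleiss nomenclature, from the two-way ANOVA mean
#' squares (subjects x raters):
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% CI follows the standard F-distribution construction of McGraw &
#' Wong. The paper states only "two-way random"; the single-measure
#' absolute-agreement form is the conventional reading for single-rater
#' reliability, and the form is recorded in the result so the choice is
#' auditable.
#'
#' @param ratings numeric matrix, `n` subjects x `k` raters/methods.
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci` (lower, upper), `form` (`"ICC(2,1)"`),
#'   `ms` (the mean squares), `n`, `k`. If the between-subject variance is
#'   zero the ICC is 0 with a degenerate-variance warning.
#' @export
icc_two_way_random <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must not contain missing values")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= mse && msr <= .Machine$double.eps^0.5) {
    warning("degenerate variance: no between-subject variability; ICC set to 0")
    return(list(icc = 0, ci = c(NA_real_, NA_real_), form = "ICC(2,1)",
                ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k))
  }
  icc <- (msr - mse) / denom
  if (mse <= .Machine$double.eps^0.5 * msr) {
    # error-free ratings: the interval degenerates at the point estimate
    return(list(icc = icc, ci = c(lower = icc, upper = icc), form = "ICC(2,1)",
                ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k))
  }
  # McGraw & Wong (1996) F-based CI for ICC(A,1) with Satterthwaite df
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fu <- stats::qf(1 - alpha / 2, n - 1, v)
  fl <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fu * mse) /
    (fu * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fl * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fl * msr)
  list(icc = icc, ci = c(lower = lower, upper = upper), form = "ICC(2,1)",
       ms = c(MSR = msr, MSC = msc, MSE = mse), n = n, k = k)
}

#' Absolute inter-eye difference summary
#'
#' Per-subject absolute difference |SI_right - SI_left| with mean, SD, median
#' and range — the statistic contrasting unilateral disease against controls.
#' Subjects missing a fellow-eye value are skipped with a warning.
#'
#' @param right,left numeric vectors of per-subject SI for the right (OD) and
#'   left (OS) eye.
#' @param ids optional subject labels.
#' @return list with `differences`, `mean`, `sd`, `median`, `range`, `n`,
#'   `skipped`.
#' @export
inter_eye_difference <- function(right, left, ids = NULL) {
  right <- as.numeric(right); left <- as.numeric(left)
  if (length(right) != length(left))
    stop("right and left series must have equal length")
  ok <- !is.na(right) & !is.na(left)
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) skipped: missing fellow-eye value")
    if (!is.null(ids)) ids <- ids[ok]
  }
  d <- abs(right[ok] - left[ok])
  if (length(d) == 0L) stop("no complete eye pairs")
  list(differences = d, mean = mean(d), sd = stats::sd(d),
       median = stats::median(d), range = range(d), n = length(d),
       skipped = sum(!ok), ids = ids)
}
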