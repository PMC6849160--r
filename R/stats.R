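# Half-up rounding at the reported precision (base round() is banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Binomial proportion with confidence interval
#'
#' Wilson score interval (default) or Clopper-Pearson exact interval for a
#' binomial proportion. The Wilson interval is used for all reported
#' proportions because of its stability at small counts and near 0/1.
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @param method "wilson" or "clopper_pearson".
#' @return A tibble with columns `k`, `n`, `point`, `ci_low`, `ci_high`,
#'   `method` (fractions in \[0, 1\]).
#' @examples
#' wilson_ci(41, 315)
#' @export
wilson_ci <- function(k, n, level = 0.95, method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  if (any(n <= 0)) stop("n must be positive")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
  } else {
    lo <- ifelse(k == 0, 0, stats::qbeta((1 - level) / 2, k, n - k + 1))
    hi <- ifelse(k == n, 1, stats::qbeta(1 - (1 - level) / 2, k + 1, n - k))
  }
  tibble::tibble(k = k, n = n, point = k / n, ci_low = lo, ci_high = hi,
                 method = method)
}

#' Confusion-derived binary metrics
#'
#' Sensitivity, specificity and positive predictive value from 2x2 counts,
#' each with a binomial confidence interval. Metrics with a zero denominator
#' are reported as undefined (NA) rather than propagated as NaN.
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @param level Confidence level.
#' @param method CI method, see [wilson_ci()].
#' @return A tibble with one row per metric: `metric`, `k`, `n`, `point`,
#'   `ci_low`, `ci_high` (fractions; NA when undefined).
#' @examples
#' binary_metrics(tp = 41, fp = 6, fn = 274, tn = 287)
#' @export
binary_metrics <- function(tp, fp, fn, tn, level = 0.95,
                           method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  one <- function(name, k, n) {
    if (n == 0) {
      tibble::tibble(metric = name, k = NA_integer_, n = 0L,
                     point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    } else {
      ci <- wilson_ci(k, n, level = level, method = method)
      tibble::tibble(metric = name, k = k, n = n, point = ci$point,
                     ci_low = ci$ci_low, ci_high = ci$ci_high)
    }
  }
  dplyr::bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp)
  )
}

# Format a proportion the way the tables print them: "13.0 (9.5, 17.2)".
format_pct_ci <- function(point, lo, hi, digits = 1) {
  ifelse(is.na(point), "-",
         sprintf("%s (%s, %s)",
                 formatC(round_half_up(100 * point, digits), format = "f", digits = digits),
                 formatC(round_half_up(100 * lo, digits), format = "f", digits = digits),
                 formatC(round_half_up(100 * hi, digits), format = "f", digits = digits)))
}
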