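#' LOESS-smoothed daily trend
#'
#' Locally weighted linear regression (degree 1, tricube kernel, no
#' robustness iterations) over the `floor(span * n)` nearest neighbours of
#' each observed day, evaluated at the observed days. Missing values are
#' excluded from fitting and returned as `NA`.
#'
#' @param day numeric vector of days.
#' @param value numeric vector of daily totals (may contain `NA`).
#' @param span neighbourhood fraction in (0, 1\].
#' @return tibble with `day`, `value`, `smoothed`.
#' @export
loess_smooth <- function(day, value, span = 0.3) {
  stopifnot(length(day) == length(value), span > 0, span <= 1)
  ok <- !is.na(value) & !is.na(day)
  if (sum(ok) < 3) stop("need at least 3 non-missing points")
  if (floor(span * sum(ok)) < 2)
    stop("span too small: local windows contain fewer than 2 points")
  fit <- stats::loess(value[ok] ~ day[ok], span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  smoothed <- rep(NA_real_, length(day))
  smoothed[ok] <- stats::predict(fit)
  tibble::tibble(day = day, value = value, smoothed = smoothed)
}

#' Detection-uncertainty ribbon around a smoothed trend
#'
#' Scales the smoothed counts by the detector error rates: false positives
#' could have inflated observed counts (lower bound `smoothed * (1 - fpr)`)
#' while false negatives could have hidden calls (upper bound
#' `smoothed * (1 + fnr)`). Bands are clipped at zero.
#'
#' @param smoothed non-negative smoothed values.
#' @param fpr detector false positive rate.
#' @param fnr detector false negative rate.
#' @return tibble with `lower`, `upper`.
#' @export
uncertainty_ribbon <- function(smoothed, fpr = 0.158, fnr = 0.132) {
  stopifnot(fpr >= 0, fpr <= 1, fnr >= 0, fnr <= 1)
  tibble::tibble(lower = pmax(smoothed * (1 - fpr), 0),
                 upper = pmax(smoothed * (1 + fnr), 0))
}

#' Per-instrument, per-period box summaries of hourly counts
#'
#' Five-number summaries with type-7 (linear interpolation) quartiles;
#' whiskers extend to the most extreme observation within 1.5 x IQR of the
#' box, and points beyond are listed as outliers. Empty cells are omitted
#' with a warning.
#'
#' @param counts hourly count table.
#' @param periods period table as from [survey_periods()].
#' @return tibble with `instrument`, `period`, `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, and a list column `outliers`.
#' @export
period_boxes <- function(counts, periods = survey_periods()) {
  ok <- counts[counts$valid & !is.na(counts$count), , drop = FALSE]
  grid <- expand.grid(instrument = sort(unique(ok$instrument)),
                      period = periods$name, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    x <- ok$count[ok$instrument == grid$instrument[k] &
                  ok$period == grid$period[k]]
    if (length(x) == 0) {
      warning(sprintf("no data for %s / %s; cell omitted",
                      grid$instrument[k], grid$period[k]), call. = FALSE)
      return(NULL)
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    tibble::tibble(instrument = grid$instrument[k], period = grid$period[k],
                   n = length(x), median = q[2], q1 = q[1], q3 = q[3],
                   whisker_low = min(inside), whisker_high = max(inside),
                   outliers = list(sort(x[x < lo_fence | x > hi_fence])))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
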