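#' Assign a Julian day to a survey period
#'
#' @param jd integer Julian day(s) (day of year).
#' @param periods period table as from [survey_periods()].
#' @return character vector of period names; days outside every range are
#'   an error.
#' @export
assign_period <- function(jd, periods = survey_periods()) {
  out <- rep(NA_character_, length(jd))
  for (k in seq_len(nrow(periods)))
    out[jd >= periods$jd_start[k] & jd <= periods$jd_end[k]] <-
      periods$name[k]
  if (anyNA(out))
    stop("Julian day(s) outside all survey periods: ",
         paste(unique(jd[is.na(out)]), collapse = ", "))
  out
}

#' Roll per-frame detections into hourly counts
#'
#' Counts positive 30-s frames per instrument-hour. The frame grid is
#' anchored at each instrument's recording start; hours are clock hours
#' from that origin. Hours with no frames, and hours overlapping a corrupt
#' Julian day, are flagged invalid and carry `NA` counts.
#'
#' @param detections tibble/data.frame with columns `instrument`,
#'   `time_s` (frame start, seconds since the instrument's recording
#'   start), and binary `label`; duplicate frame times within an instrument
#'   are an error.
#' @param start_jd Julian day on which each recording starts (recycled
#'   across instruments or a named vector by instrument).
#' @param periods period table as from [survey_periods()].
#' @param corrupt_jd integer vector of Julian days to blank as corrupt.
#' @return tibble with `instrument`, `jd`, `period`, `hour` (0-23),
#'   `count`, `valid`.
#' @export
hourly_counts <- function(detections, start_jd = survey_periods()$jd_start[1],
                          periods = survey_periods(),
                          corrupt_jd = integer(0)) {
  stopifnot(all(c("instrument", "time_s", "label") %in% names(detections)))
  if (!all(detections$label %in% c(0, 1))) stop("labels must be binary")
  out <- lapply(split(detections, detections$instrument), function(d) {
    if (anyDuplicated(d$time_s))
      stop("duplicate frame timestamps within instrument ", d$instrument[1])
    sjd <- if (!is.null(names(start_jd))) start_jd[[d$instrument[1]]]
           else start_jd
    hour_abs <- floor(d$time_s / 3600)
    agg <- stats::aggregate(list(count = d$label),
                            by = list(hour_abs = hour_abs), FUN = sum)
    # hours inside the recorded span with no frames at all become invalid
    grid <- seq(min(agg$hour_abs), max(agg$hour_abs))
    count <- rep(NA_integer_, length(grid))
    count[match(agg$hour_abs, grid)] <- as.integer(agg$count)
    jd <- sjd + grid %/% 24L
    tibble::tibble(instrument = d$instrument[1],
                   jd = as.integer(jd),
                   period = assign_period(jd, periods),
                   hour = as.integer(grid %% 24L),
                   count = count,
                   valid = !is.na(count))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  bad <- out$jd %in% corrupt_jd
  out$valid[bad] <- FALSE
  out$count[bad] <- NA_integer_
  out[order(out$instrument, out$jd, out$hour), ]
}

#' Per-instrument, per-period count summaries
#'
#' Means and ranges of hourly counts over valid hours only, plus pooled
#' quiet and shooting means per instrument. Pooling is hour-weighted by
#' default (the mean over all valid hours of the pooled periods);
#' `pooling = "simple"` averages the two period means instead.
#'
#' @param counts hourly count table ([hourly_counts()] or
#'   [simulate_counts()]).
#' @param periods period table as from [survey_periods()].
#' @param pooling `"hours"` (default) or `"simple"`.
#' @return list with `by_period` (tibble: instrument, period, n_hours,
#'   mean, min, max) and `pooled` (tibble: instrument, regime, mean).
#' @export
summarize_counts <- function(counts, periods = survey_periods(),
                             pooling = c("hours", "simple")) {
  pooling <- match.arg(pooling)
  ok <- counts[counts$valid & !is.na(counts$count), , drop = FALSE]
  cell_stats <- function(d) {
    if (nrow(d) == 0) {
      warning("empty instrument-period cell; reported as NA", call. = FALSE)
      return(tibble::tibble(n_hours = 0L, mean = NA_real_,
                            min = NA_integer_, max = NA_integer_))
    }
    tibble::tibble(n_hours = nrow(d), mean = mean(d$count),
                   min = min(d$count), max = max(d$count))
  }
  grid <- expand.grid(instrument = sort(unique(ok$instrument)),
                      period = periods$name, stringsAsFactors = FALSE)
  by_period <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    d <- ok[ok$instrument == grid$instrument[k] &
            ok$period == grid$period[k], , drop = FALSE]
    cbind(grid[k, , drop = FALSE], cell_stats(d))
  }))
  by_period <- tibble::as_tibble(by_period)

  regime_of <- stats::setNames(ifelse(periods$shooting, "shooting", "quiet"),
                               periods$name)
  pooled <- do.call(rbind, lapply(sort(unique(ok$instrument)), function(ins) {
    do.call(rbind, lapply(c("quiet", "shooting"), function(reg) {
      pers <- names(regime_of)[regime_of == reg]
      m <- if (pooling == "hours") {
        d <- ok[ok$instrument == ins & ok$period %in% pers, , drop = FALSE]
        if (nrow(d)) mean(d$count) else NA_real_
      } else {
        pm <- by_period$mean[by_period$instrument == ins &
                             by_period$period %in% pers]
        mean(pm)
      }
      tibble::tibble(instrument = ins, regime = reg, mean = m)
    }))
  }))
  list(by_period = by_period, pooled = tibble::as_tibble(pooled))
}

#' Daily total positive-frame counts
#'
#' Sums hourly counts per instrument-day over valid hours; days listed as
#' corrupt (or with no valid hours) are `NA`.
#'
#' @param counts hourly count table.
#' @param corrupt_jd Julian days to blank.
#' @return tibble with `instrument`, `jd`, `period`, `total`.
#' @export
daily_totals <- function(counts, corrupt_jd = integer(0)) {
  out <- do.call(rbind, lapply(split(counts, list(counts$instrument,
                                                  counts$jd), drop = TRUE),
    function(d) {
      ok <- d$valid & !is.na(d$count)
      tibble::tibble(instrument = d$instrument[1], jd = d$jd[1],
                     period = d$period[1],
                     total = if (any(ok) && !(d$jd[1] %in% corrupt_jd))
                       sum(d$count[ok]) else NA_real_)
    }))
  out <- out[order(out$instrument, out$jd), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
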