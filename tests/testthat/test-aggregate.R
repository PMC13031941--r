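test_that("Julian days map to the published period boundaries", {
  expect_equal(assign_period(156), "Shooting 1")
  expect_equal(assign_period(173), "Shooting 1")
  expect_equal(assign_period(174), "Quiet 1")
  expect_equal(assign_period(197), "Shooting 2")
  expect_equal(assign_period(213), "Quiet 2")
  expect_equal(assign_period(218), "Quiet 2")
  expect_error(assign_period(155), "outside")
  expect_error(assign_period(219), "outside")
})

test_that("hourly aggregation matches a naive group-and-sum oracle", {
  # one full hour of positive frames
  det <- tibble::tibble(instrument = "A", time_s = seq(0, 3570, by = 30),
                        label = 1)
  hc <- hourly_counts(det)
  expect_equal(hc$count, 120L)
  expect_equal(hc$jd, 156L)
  expect_equal(hc$period, "Shooting 1")

  # data present but no detections
  det0 <- det
  det0$label <- 0
  hc0 <- hourly_counts(det0)
  expect_equal(hc0$count, 0L)
  expect_true(hc0$valid)

  # random detections over 3 days x 2 instruments vs brute force
  set.seed(31)
  det <- tibble::tibble(
    instrument = rep(c("A", "B"), each = 3 * 24 * 120),
    time_s = rep(seq(0, 3 * 86400 - 30, by = 30), 2),
    label = rbinom(2 * 3 * 24 * 120, 1, 0.3))
  hc <- hourly_counts(det)
  for (r in sample(nrow(hc), 25)) {
    h0 <- ((hc$jd[r] - 156) * 24 + hc$hour[r]) * 3600
    ref <- sum(det$label[det$instrument == hc$instrument[r] &
                         det$time_s >= h0 & det$time_s < h0 + 3600])
    expect_equal(hc$count[r], ref)
  }
  expect_equal(sum(hc$count), sum(det$label))

  dup <- tibble::tibble(instrument = "A", time_s = c(0, 0), label = c(1, 0))
  expect_error(hourly_counts(dup), "duplicate")

  # an hour with no frames inside the recorded span is an invalid row
  gap <- tibble::tibble(instrument = "A",
                        time_s = c(seq(0, 3570, 30), seq(7200, 10770, 30)),
                        label = 1)
  hg <- hourly_counts(gap)
  expect_equal(nrow(hg), 3)
  expect_false(hg$valid[2])
  expect_true(is.na(hg$count[2]))
})

test_that("corrupt days are blanked as missing", {
  det <- tibble::tibble(instrument = "A",
                        time_s = seq(0, 2 * 86400 - 30, by = 30),
                        label = 1)
  hc <- hourly_counts(det, corrupt_jd = 157L)
  expect_true(all(is.na(hc$count[hc$jd == 157])))
  expect_true(all(!hc$valid[hc$jd == 157]))
  expect_true(all(hc$valid[hc$jd == 156]))
})

test_that("summaries pool by hours by default and by period mean on request", {
  # Quiet 1: 23 days at constant 74.4-like counts; Quiet 2: 6 days at 83
  mk <- function(jd, val) tibble::tibble(
    instrument = "OBS18", jd = jd, period = assign_period(jd),
    hour = 0L, count = val, valid = TRUE)
  d <- rbind(do.call(rbind, lapply(174:196, mk, val = 74L)),
             do.call(rbind, lapply(213:218, mk, val = 83L)),
             do.call(rbind, lapply(156:173, mk, val = 18L)),
             do.call(rbind, lapply(197:212, mk, val = 14L)))
  s_hours <- summarize_counts(d, pooling = "hours")
  s_simple <- summarize_counts(d, pooling = "simple")
  qh <- s_hours$pooled$mean[s_hours$pooled$regime == "quiet"]
  qs <- s_simple$pooled$mean[s_simple$pooled$regime == "quiet"]
  expect_equal(qh, (74 * 23 + 83 * 6) / 29)   # hour-weighted
  expect_equal(qs, (74 + 83) / 2)             # simple average of period means

  # partition property: per-period hours sum to total valid hours
  expect_equal(sum(s_hours$by_period$n_hours), nrow(d))

  # invariance to row order
  perm <- sample(nrow(d))
  s_perm <- summarize_counts(d[perm, ], pooling = "hours")
  expect_equal(s_perm$by_period[order(s_perm$by_period$period), ],
               s_hours$by_period[order(s_hours$by_period$period), ])
})

test_that("summaries skip missing hours and warn on empty cells", {
  d <- tibble::tibble(instrument = "A", jd = c(156L, 156L, 156L),
                      period = "Shooting 1", hour = 0:2,
                      count = c(10L, NA, 20L), valid = c(TRUE, FALSE, TRUE))
  expect_warning(summarize_counts(d, periods = survey_periods()[1:2, ]),
                 "empty")
  s <- suppressWarnings(summarize_counts(d))
  row <- s$by_period[s$by_period$period == "Shooting 1", ]
  expect_equal(row$mean, 15)
  expect_equal(row$n_hours, 2L)
  expect_equal(c(row$min, row$max), c(10L, 20L))
})

test_that("daily totals sum valid hours and blank corrupt days", {
  d <- simulate_counts(count_sim_config(seed = 2, n_instruments = 1))
  dt <- daily_totals(d, corrupt_jd = c(160L, 200L))
  expect_true(all(is.na(dt$total[dt$jd %in% c(160, 200)])))
  one <- d[d$jd == 175, ]
  expect_equal(dt$total[dt$jd == 175], sum(one$count))
  expect_equal(nrow(dt), 63)
})
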