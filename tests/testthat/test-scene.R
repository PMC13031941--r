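test_that("whale pulse is a downsweep with energy in its frequency band", {
  pp <- list(f_start_hz = 23, f_end_hz = 18, duration_s = 1.0, snr_db = Inf)
  x <- synth_whale_pulse(pp, 200)
  expect_length(x, 200)
  expect_equal(mean(x^2), 1, tolerance = 1e-10)

  # STFT ridge must descend monotonically in frequency
  nfft <- 64L
  hop <- 16L
  cols <- seq(1, length(x) - nfft, by = hop)
  ridge <- vapply(cols, function(i) {
    s <- Mod(stats::fft(x[i:(i + nfft - 1)] *
                          (0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft))))
    which.max(s[1:(nfft / 2)])
  }, numeric(1))
  expect_true(all(diff(ridge) <= 0))

  # >= 90% of periodogram energy inside [f_end, f_start]
  per <- Mod(stats::fft(x))^2
  f <- (seq_along(per) - 1) * 200 / length(per)
  half <- f <= 100
  in_band <- half & f >= 17 & f <= 24
  expect_gte(sum(per[in_band]) / sum(per[half]), 0.9)
})

test_that("degenerate and invalid pulse parameters are handled", {
  expect_length(synth_whale_pulse(list(f_start_hz = 23, f_end_hz = 18,
                                       duration_s = 0), 200), 0)
  expect_error(synth_whale_pulse(list(f_start_hz = 120, f_end_hz = 18,
                                      duration_s = 1), 200), "Nyquist")
  expect_error(synth_whale_pulse(list(f_start_hz = 18, f_end_hz = 23,
                                      duration_s = 1), 200), "f_start")
})

test_that("scene scheduling follows the configuration", {
  cfg <- scene_config(duration_s = 3600, pulse_rate_per_min = 0,
                      airgun_active = TRUE, seed = 4)
  sc <- simulate_scene(cfg)
  expect_false(any(sc$events$kind == "whale_pulse"))
  shots <- sc$events[sc$events$kind == "airgun_shot", ]
  expect_equal(nrow(shots), 225)   # shots at t = 0, 16, ..., 3584
  expect_equal(shots$onset_s, seq(0, 3584, by = 16))
  expect_true(all(shots$duration_s >= 2.7 & shots$duration_s <= 7.7))
  # events complete, sorted, inside the scene
  expect_true(!is.unsorted(sc$events$onset_s))
  expect_true(all(sc$events$onset_s >= 0))
  expect_true(all(sc$events$onset_s + sc$events$duration_s <= 3600 + 1e-9))
})

test_that("identical seeds give bit-identical scenes", {
  cfg <- scene_config(duration_s = 300, pulse_rate_per_min = 3,
                      airgun_active = TRUE, seed = 77)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$waveform, s2$waveform)
  expect_identical(s1$events, s2$events)
})

test_that("mask durations have the configured mean and range", {
  durs <- finpulse:::draw_mask_durations(10000, c(2.7, 7.7), 5.5)
  expect_true(all(durs >= 2.7 & durs <= 7.7))
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 5.5), 3 * se)
  # plain uniform variant keeps the midpoint mean
  u <- finpulse:::draw_mask_durations(10000, c(2.7, 7.7), NULL)
  expect_lt(abs(mean(u) - 5.2), 3 * stats::sd(u) / sqrt(length(u)))
})

test_that("frame labels agree with a brute-force overlap oracle", {
  expect_equal(frame_labels(tibble::tibble(kind = character(),
                                           onset_s = numeric(),
                                           duration_s = numeric()),
                            300)$label, rep(0L, 10))

  # one pulse straddling a frame boundary labels both frames
  ev <- tibble::tibble(kind = "whale_pulse", onset_s = 29.5, duration_s = 1)
  expect_equal(frame_labels(ev, 90)$label, c(1L, 1L, 0L))

  # one pulse per frame in a 1-h scene: 120 positive frames
  ev <- tibble::tibble(kind = "whale_pulse",
                       onset_s = seq(10, 3590, by = 30), duration_s = 1)
  expect_equal(sum(frame_labels(ev, 3600)$label), 120)

  # randomized cases against the naive oracle; airgun shots never label
  set.seed(42)
  for (rep in 1:5) {
    ev <- tibble::tibble(
      kind = sample(c("whale_pulse", "airgun_shot"), 40, replace = TRUE),
      onset_s = runif(40, 0, 590),
      duration_s = runif(40, 0.5, 8))
    ev <- ev[order(ev$onset_s), ]
    expect_equal(frame_labels(ev, 600)$label, naive_frame_labels(ev, 600))
  }
})

test_that("label count is conserved against pulse count", {
  cfg <- scene_config(duration_s = 1800, pulse_rate_per_min = 2, seed = 12)
  sc <- simulate_scene(cfg)
  labs <- frame_labels(sc$events, 1800)
  n_pulse <- sum(sc$events$kind == "whale_pulse")
  expect_lte(sum(labs$label), 2 * n_pulse)  # a pulse spans at most 2 frames
  expect_gte(n_pulse, sum(labs$label) / 2)
})

test_that("WAV round-trips in both encodings", {
  x <- sin(2 * pi * 20 * (0:999) / 200) * 0.8
  for (fmt in c("float32", "pcm16")) {
    path <- tempfile(fileext = ".wav")
    write_wav(x, path, 200, format = fmt)
    back <- read_wav(path)
    expect_equal(back$sample_rate_hz, 200)
    tol <- if (fmt == "pcm16") 1e-4 else 1e-6
    expect_equal(back$samples, x, tolerance = tol)
    unlink(path)
  }
})

test_that("scene configs round-trip through YAML and ground truth CSV", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(duration_s = 120, pulse_rate_per_min = 2,
                        airgun_active = TRUE, seed = 9), path)
  cfg <- read_scene_config(path)
  expect_s3_class(cfg, "scene_config")
  expect_equal(cfg$duration_s, 120)
  sc <- simulate_scene(cfg)
  csv <- tempfile(fileext = ".csv")
  write_ground_truth(sc$events, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(sc$events))
  expect_equal(back$onset_s, sc$events$onset_s)
  unlink(c(path, csv))
})
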