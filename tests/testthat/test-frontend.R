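test_that("resampling preserves duration and tone frequency", {
  x <- sin(2 * pi * 20 * (0:7499) / 250)
  y <- resample_audio(x, 250)
  expect_length(y, 6000)
  # dominant periodogram bin still nearest 20 Hz
  per <- Mod(stats::fft(y))^2
  f <- (seq_along(per) - 1) * 200 / length(per)
  peak <- f[which.max(per[f <= 100])]
  expect_lt(abs(peak - 20), 0.1)

  same <- resample_audio(x, 200)
  expect_identical(same, x)
  expect_error(resample_audio(x, 150), "upsampling")
})

test_that("band-limited STFT honours the declared arithmetic", {
  expect_equal(unname(stft_bandlimit(numeric(6000))[1, 1]), 0)
  expect_true(all(stft_bandlimit(numeric(6000)) == 0))

  sp <- stft_bandlimit(tone_frame(20))
  expect_equal(nrow(sp), 90)    # floor((6000 - 256)/64) + 1
  freqs <- attr(sp, "freq_hz")
  expect_true(all(freqs >= 4 & freqs <= 80))
  # per-column argmax at the full-spectrum FFT bin nearest 20 Hz (bin 26)
  argmax_bins <- attr(sp, "bin_index")[apply(sp, 1, which.max)]
  expect_true(all(argmax_bins == 26))

  expect_error(stft_bandlimit(numeric(5000)), "6000 samples")
})

test_that("PCEN matches its closed form and suppresses gain differences", {
  p <- frontend_config()$pcen_params
  expect_true(all(pcen(matrix(0, 10, 5), p) == 0))

  # constant input: M equals the constant, so every cell takes the scalar
  # closed form ((c/(eps+c)^alpha) + delta)^r - delta^r
  cc <- 3.7
  out <- pcen(matrix(cc, 8, 4), p)
  expected <- (cc / (p$eps + cc)^p$alpha + p$delta)^p$r - p$delta^p$r
  expect_equal(max(abs(out - expected)), 0, tolerance = 1e-12)

  expect_error(pcen(matrix(-1, 2, 2), p), "non-negative")

  # loud vs quiet stationary tones end up with more similar dynamic ranges
  loud <- stft_bandlimit(tone_frame(20) * 100 +
                           tone_frame(40) * 10)
  quiet <- stft_bandlimit(tone_frame(20) + tone_frame(40) * 0.1)
  raw_ratio <- max(loud) / max(quiet)
  pcen_ratio <- max(pcen(loud, p)) / max(pcen(quiet, p))
  expect_lt(abs(log(pcen_ratio)), abs(log(raw_ratio)))
})

test_that("detector input tensor has the pinned shape and channel layout", {
  set.seed(1)
  frame <- stats::rnorm(6000)
  x <- to_input(pcen(stft_bandlimit(frame)))
  expect_equal(dim(x), c(97, 90, 3))
  expect_true(all(x >= 0 & x <= 1))
  expect_identical(x[, , 1], x[, , 2])
  expect_identical(x[, , 1], x[, , 3])

  const <- to_input(matrix(5, 90, 97))
  expect_true(all(const == 0))      # min-max of a constant pins to zero
  expect_error(to_input(matrix(numeric(0), 0, 0)), "empty")
})

test_that("bilinear resize matches a per-pixel oracle", {
  set.seed(7)
  x <- matrix(rnorm(30), 5, 6)
  z <- finpulse:::bilinear_resize(x, 9, 4)
  ri <- seq(1, 5, length.out = 9)
  ci <- seq(1, 6, length.out = 4)
  for (i in seq_len(9)) for (j in seq_len(4)) {
    r0 <- min(floor(ri[i]), 4); c0 <- min(floor(ci[j]), 5)
    fr <- ri[i] - r0; fc <- ci[j] - c0
    val <- x[r0, c0] * (1 - fr) * (1 - fc) + x[r0 + 1, c0] * fr * (1 - fc) +
      x[r0, c0 + 1] * (1 - fr) * fc + x[r0 + 1, c0 + 1] * fr * fc
    expect_equal(z[i, j], val, tolerance = 1e-12)
  }
})

test_that("the frontend is deterministic and localizes pulse energy", {
  cfg <- scene_config(duration_s = 30, pulse_rate_per_min = 0, seed = 21,
                      noise_params = list(slope = -1, level = 0.2))
  sc <- simulate_scene(cfg)
  pulse <- synth_whale_pulse(list(f_start_hz = 23, f_end_hz = 18,
                                  duration_s = 1.0), 200) * 3
  wav <- sc$waveform
  at <- 2001:2200   # pulse support 10-11 s
  wav[at] <- wav[at] + pulse

  t1 <- to_input(pcen(stft_bandlimit(wav)))
  t2 <- to_input(pcen(stft_bandlimit(wav)))
  expect_identical(t1, t2)

  sp <- pcen(stft_bandlimit(wav))
  peak <- arrayInd(which.max(sp), dim(sp))
  peak_time_s <- (peak[1] - 1) * 64 / 200
  peak_freq <- attr(sp, "freq_hz")[peak[2]]
  expect_true(peak_freq >= 15 && peak_freq <= 30)
  expect_true(peak_time_s >= 9 && peak_time_s <= 12)
})

test_that("frontend_frames splits a scene into tensors with start times", {
  cfg <- scene_config(duration_s = 95, pulse_rate_per_min = 1, seed = 2)
  sc <- simulate_scene(cfg)
  fr <- frontend_frames(sc$waveform, sc$sample_rate_hz)
  expect_equal(ncol(fr$x), 3)    # trailing 5 s dropped
  expect_equal(fr$start_s, c(0, 30, 60))
  expect_equal(nrow(fr$x), prod(c(97, 90, 3)))
})
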