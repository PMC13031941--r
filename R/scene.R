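#' Configuration for a synthetic acoustic scene
#'
#' Describes a single-channel low-frequency ocean soundscape containing
#' fin-whale 20-Hz pulses (1-s linear downsweeps), optionally overlaid with
#' impulsive airgun shots fired at a fixed interval, over pink ambient noise.
#' Defaults follow the survey conditions the pipeline is designed around:
#' shots every 16 s, each masking 5.5 s of recording on average
#' (range 2.7-7.7 s).
#'
#' @param duration_s scene length in seconds (> 0).
#' @param sample_rate_hz sampling rate, Hz.
#' @param pulse_rate_per_min expected whale-pulse rate (homogeneous Poisson
#'   scheduling); 0 disables pulses.
#' @param pulse_params list with `f_start_hz`, `f_end_hz`, `duration_s`,
#'   `snr_db` (pulse RMS over broadband noise RMS, in dB; `Inf` means the
#'   pulse is mixed at unit RMS into a noiseless scene).
#' @param airgun_active logical; schedule airgun shots?
#' @param airgun_interval_s shot interval, seconds.
#' @param airgun_mask_mean_s target mean masking duration per shot, seconds;
#'   `NULL` draws plain uniform durations on `airgun_mask_range_s`.
#' @param airgun_mask_range_s length-2 range of masking durations, seconds.
#' @param airgun_snr_db shot RMS (over its masked duration) relative to
#'   noise RMS, dB.
#' @param noise_params list with `slope` (power spectral density exponent;
#'   -1 is pink) and `level` (broadband RMS).
#' @param seed integer RNG seed; identical configs give bit-identical scenes.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(duration_s = 3600,
                         sample_rate_hz = 200,
                         pulse_rate_per_min = 1,
                         pulse_params = list(f_start_hz = 23, f_end_hz = 18,
                                             duration_s = 1.0, snr_db = 10),
                         airgun_active = FALSE,
                         airgun_interval_s = 16,
                         airgun_mask_mean_s = 5.5,
                         airgun_mask_range_s = c(2.7, 7.7),
                         airgun_snr_db = 20,
                         noise_params = list(slope = -1, level = 1),
                         seed = 1L) {
  stopifnot_scalar(duration_s)
  if (duration_s <= 0) stop("duration_s must be > 0")
  stopifnot_scalar(sample_rate_hz)
  stopifnot(pulse_rate_per_min >= 0, airgun_interval_s > 0,
            length(airgun_mask_range_s) == 2,
            airgun_mask_range_s[1] > 0,
            diff(airgun_mask_range_s) >= 0)
  if (!is.null(airgun_mask_mean_s) &&
      (airgun_mask_mean_s <= airgun_mask_range_s[1] ||
       airgun_mask_mean_s >= airgun_mask_range_s[2]))
    stop("airgun_mask_mean_s must lie strictly inside airgun_mask_range_s")
  structure(list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    pulse_rate_per_min = pulse_rate_per_min, pulse_params = pulse_params,
    airgun_active = airgun_active, airgun_interval_s = airgun_interval_s,
    airgun_mask_mean_s = airgun_mask_mean_s,
    airgun_mask_range_s = airgun_mask_range_s,
    airgun_snr_db = airgun_snr_db,
    noise_params = noise_params, seed = as.integer(seed)
  ), class = "scene_config")
}

#' Synthesize a fin-whale 20-Hz pulse
#'
#' A linear downsweep chirp with a Hann amplitude taper, normalized to unit
#' RMS. The instantaneous frequency falls linearly from `f_start_hz` to
#' `f_end_hz` over `duration_s`, emulating the stereotyped downsweep
#' structure of the fin-whale 20-Hz pulse.
#'
#' @param pulse_params list with `f_start_hz`, `f_end_hz`, `duration_s`
#'   (see [scene_config()]).
#' @param sample_rate_hz sampling rate, Hz.
#' @return numeric waveform segment (possibly length 0 for zero duration).
#' @export
synth_whale_pulse <- function(pulse_params, sample_rate_hz = 200) {
  f0 <- pulse_params$f_start_hz
  f1 <- pulse_params$f_end_hz
  dur <- pulse_params$duration_s
  nyq <- sample_rate_hz / 2
  if (!(f0 > f1 && f1 > 0)) stop("need f_start_hz > f_end_hz > 0")
  if (f0 >= nyq || f1 >= nyq)
    stop("pulse frequencies must lie below the Nyquist frequency")
  n <- round(dur * sample_rate_hz)
  if (n <= 0) return(numeric(0))
  t <- (seq_len(n) - 1) / sample_rate_hz
  # linear chirp: phase(t) = 2*pi*(f0*t + (f1-f0)/(2*dur)*t^2)
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)
  env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
  x <- sin(phase) * env
  x / sqrt(mean(x^2))
}

#' Synthesize an impulsive airgun shot
#'
#' An exponentially decaying broadband transient, low-pass shaped below
#' 100 Hz, whose effective (masking) duration is `mask_duration_s`: the
#' envelope decays to about 5% of its onset value at that point and the
#' segment is truncated there. Unit RMS over the masked duration.
#'
#' @param mask_duration_s effective duration of the transient, seconds.
#' @param sample_rate_hz sampling rate, Hz.
#' @return numeric waveform segment.
#' @export
synth_airgun_shot <- function(mask_duration_s, sample_rate_hz = 200) {
  n <- round(mask_duration_s * sample_rate_hz)
  if (n <= 0) return(numeric(0))
  t <- (seq_len(n) - 1) / sample_rate_hz
  env <- exp(-3 * t / mask_duration_s)
  x <- stats::rnorm(n) * env
  # one-pole lowpass to push energy below ~100 Hz at any sample rate
  fc <- min(100, 0.45 * sample_rate_hz)
  a <- exp(-2 * pi * fc / sample_rate_hz)
  x <- stats::filter(x * (1 - a), filter = a, method = "recursive")
  x <- as.numeric(x)
  x / sqrt(mean(x^2))
}

# Two-piece uniform on (lo, mean) and (mean, hi) with piece probability
# chosen so the expectation equals `mean` exactly; NULL mean = plain uniform.
draw_mask_durations <- function(n, range, mean = NULL) {
  lo <- range[1]; hi <- range[2]
  if (is.null(mean)) return(stats::runif(n, lo, hi))
  p_low <- (hi - mean) / (hi - lo)
  low <- stats::runif(n, lo, mean)
  high <- stats::runif(n, mean, hi)
  ifelse(stats::runif(n) < p_low, low, high)
}

# FFT-shaped Gaussian noise with power spectral density ~ f^slope,
# normalized to the requested broadband RMS.
synth_colored_noise <- function(n, slope = -1, level = 1) {
  if (n <= 0) return(numeric(0))
  if (level <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))           # guard DC
  f <- pmin(f, n - f + 1)             # mirror for negative frequencies
  shape <- f^(slope / 2)
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x * level / sqrt(mean(x^2))
}

#' Simulate an annotated acoustic scene
#'
#' Builds the scene waveform (ambient noise + whale pulses + optional airgun
#' shots) together with a complete, onset-sorted ground-truth event table.
#' Whale pulses are scheduled as a homogeneous Poisson process truncated so
#' every pulse fits inside the scene; airgun shots fire at
#' `t = 0, interval, 2*interval, ...` with masking durations drawn by the
#' configured rule.
#'
#' @param config a [scene_config()].
#' @return list with `waveform` (numeric), `sample_rate_hz`, and `events`,
#'   a tibble with columns `kind` (`"whale_pulse"` or `"airgun_shot"`),
#'   `onset_s`, `duration_s`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    fs <- config$sample_rate_hz
    n <- round(config$duration_s * fs)
    wav <- synth_colored_noise(n, config$noise_params$slope,
                               config$noise_params$level)
    noise_rms <- if (config$noise_params$level > 0) config$noise_params$level else 1
    events <- list()

    pdur <- config$pulse_params$duration_s
    if (config$pulse_rate_per_min > 0 && pdur < config$duration_s) {
      n_pulse <- stats::rpois(1, config$pulse_rate_per_min *
                                   config$duration_s / 60)
      onsets <- sort(stats::runif(n_pulse, 0, config$duration_s - pdur))
      if (n_pulse > 0) {
        snr <- config$pulse_params$snr_db
        amp <- if (is.infinite(snr)) 1 else noise_rms * 10^(snr / 20)
        seg <- synth_whale_pulse(config$pulse_params, fs) * amp
        for (on in onsets) {
          i0 <- round(on * fs) + 1L
          idx <- i0:(i0 + length(seg) - 1L)
          keep <- idx <= n
          wav[idx[keep]] <- wav[idx[keep]] + seg[keep]
        }
        events$pulse <- tibble::tibble(kind = "whale_pulse", onset_s = onsets,
                                       duration_s = pdur)
      }
    }

    if (config$airgun_active) {
      n_shots <- floor((config$duration_s - 1e-9) /
                         config$airgun_interval_s) + 1L
      onsets <- (seq_len(n_shots) - 1) * config$airgun_interval_s
      durs <- draw_mask_durations(length(onsets), config$airgun_mask_range_s,
                                  config$airgun_mask_mean_s)
      durs <- pmin(durs, config$duration_s - onsets)
      amp <- noise_rms * 10^(config$airgun_snr_db / 20)
      for (k in seq_along(onsets)) {
        seg <- synth_airgun_shot(durs[k], fs) * amp
        i0 <- round(onsets[k] * fs) + 1L
        idx <- i0:(i0 + length(seg) - 1L)
        keep <- idx <= n
        wav[idx[keep]] <- wav[idx[keep]] + seg[keep]
      }
      events$shot <- tibble::tibble(kind = "airgun_shot", onset_s = onsets,
                                    duration_s = durs)
    }

    ev <- if (length(events)) do.call(rbind, events) else
      tibble::tibble(kind = character(), onset_s = numeric(),
                     duration_s = numeric())
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    rownames(ev) <- NULL
    list(waveform = wav, sample_rate_hz = fs, events = tibble::as_tibble(ev))
  })
}

#' Label 30-s frames by whale-pulse presence
#'
#' Partitions a scene into consecutive non-overlapping frames anchored at
#' the scene start and labels a frame 1 if at least one whale pulse overlaps
#' it. Airgun shots never contribute to the label.
#'
#' @param events ground-truth event tibble from [simulate_scene()].
#' @param duration_s scene duration, seconds.
#' @param frame_len_s frame length, seconds (default 30).
#' @return tibble with `frame`, `start_s`, and binary `label`.
#' @export
frame_labels <- function(events, duration_s, frame_len_s = 30) {
  n_frames <- floor(duration_s / frame_len_s)
  starts <- (seq_len(n_frames) - 1) * frame_len_s
  pulses <- events[events$kind == "whale_pulse", , drop = FALSE]
  label <- integer(n_frames)
  if (nrow(pulses)) {
    for (k in seq_len(n_frames)) {
      f0 <- starts[k]; f1 <- f0 + frame_len_s
      label[k] <- as.integer(any(pulses$onset_s < f1 &
                                 pulses$onset_s + pulses$duration_s > f0))
    }
  }
  tibble::tibble(frame = seq_len(n_frames), start_s = starts, label = label)
}

#' Write scene ground truth to CSV
#'
#' @param events event tibble from [simulate_scene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(events, path) {
  utils::write.csv(events[, c("kind", "onset_s", "duration_s")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a scene configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [scene_config()].
#' @return a `scene_config` object.
#' @export
read_scene_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$airgun_mask_range_s))
    vals$airgun_mask_range_s <- as.numeric(vals$airgun_mask_range_s)
  do.call(scene_config, vals)
}
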