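#' Spectrogram frontend configuration
#'
#' Fixes every knob of the detector input representation: 30-s frames at
#' 200 Hz, a 256-point Hann STFT with 75% overlap, band-limiting to
#' 4-80 Hz, per-channel energy normalisation (PCEN), and a bilinear resize
#' to the detector tensor shape 97 (time) x 90 (frequency) x 3 (identical
#' channels).
#'
#' @param target_rate_hz working sample rate, Hz.
#' @param frame_len_s frame length, seconds.
#' @param nfft FFT size, samples.
#' @param overlap_frac window overlap fraction in \[0, 1).
#' @param band_hz length-2 retained frequency band, Hz.
#' @param pcen_params list with `alpha` (gain), `delta` (bias), `r`
#'   (compression exponent), `s` (IIR smoothing coefficient), `eps` (floor).
#' @param out_shape integer length-3 output tensor shape
#'   (time, frequency, channels).
#' @return an object of class `frontend_config`.
#' @export
frontend_config <- function(target_rate_hz = 200, frame_len_s = 30,
                            nfft = 256, overlap_frac = 0.75,
                            band_hz = c(4, 80),
                            pcen_params = list(alpha = 0.98, delta = 2,
                                               r = 0.5, s = 0.025,
                                               eps = 1e-6),
                            out_shape = c(97L, 90L, 3L)) {
  stopifnot(overlap_frac >= 0, overlap_frac < 1,
            band_hz[1] > 0, band_hz[2] <= target_rate_hz / 2,
            length(out_shape) == 3)
  structure(list(target_rate_hz = target_rate_hz, frame_len_s = frame_len_s,
                 nfft = as.integer(nfft), overlap_frac = overlap_frac,
                 band_hz = band_hz, pcen_params = pcen_params,
                 out_shape = as.integer(out_shape)),
            class = "frontend_config")
}

#' Resample a waveform to the working rate
#'
#' Anti-aliased polyphase resampling to `target_rate_hz`. Instruments
#' already at the working rate pass through unchanged; upsampling is
#' refused because the band of interest must be covered by the input.
#'
#' @param waveform numeric samples.
#' @param in_rate input sampling rate, Hz (>= `target_rate_hz`).
#' @param target_rate_hz output rate, Hz.
#' @return numeric waveform at `target_rate_hz`.
#' @export
resample_audio <- function(waveform, in_rate, target_rate_hz = 200) {
  if (in_rate < target_rate_hz)
    stop("upsampling not supported: in_rate must be >= target rate")
  if (in_rate == target_rate_hz) return(waveform)
  g <- gcd_int(round(target_rate_hz), round(in_rate))
  p <- round(target_rate_hz) / g
  q <- round(in_rate) / g
  as.numeric(signal::resample(waveform, p, q))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Band-limited STFT magnitude of a 30-s frame
#'
#' Hann-windowed short-time Fourier transform magnitude with hop
#' `nfft * (1 - overlap_frac)`, rows outside `band_hz` dropped. For the
#' default configuration a 6000-sample frame gives 90 time columns and 97
#' retained frequency bins (bin width 200/256 Hz).
#'
#' @param frame numeric vector of exactly
#'   `frame_len_s * target_rate_hz` samples.
#' @param config a [frontend_config()].
#' @return matrix (time x frequency) with attributes `freq_hz` (bin centre
#'   frequencies) and `bin_index` (0-based full-spectrum FFT bin indices).
#' @export
stft_bandlimit <- function(frame, config = frontend_config()) {
  n_expect <- round(config$frame_len_s * config$target_rate_hz)
  if (length(frame) != n_expect)
    stop(sprintf("frame must be %d samples (%g s at %g Hz)", n_expect,
                 config$frame_len_s, config$target_rate_hz))
  nfft <- config$nfft
  hop <- round(nfft * (1 - config$overlap_frac))
  n_cols <- floor((length(frame) - nfft) / hop) + 1L
  win <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))  # periodic Hann
  starts <- (seq_len(n_cols) - 1L) * hop
  seg <- matrix(frame[outer(seq_len(nfft), starts, `+`)], nrow = nfft)
  spec <- Mod(stats::mvfft(seg * win))[seq_len(nfft %/% 2 + 1L), ,
                                       drop = FALSE]
  freq <- (0:(nfft %/% 2)) * config$target_rate_hz / nfft
  keep <- which(freq >= config$band_hz[1] & freq <= config$band_hz[2])
  out <- t(spec[keep, , drop = FALSE])   # time x frequency, ascending freq
  attr(out, "freq_hz") <- freq[keep]
  attr(out, "bin_index") <- keep - 1L
  out
}

#' Per-channel energy normalisation
#'
#' Adaptive gain control of a spectrogram:
#' `out = (E / (eps + M)^alpha + delta)^r - delta^r`, where `M` is a
#' per-frequency first-order IIR smoothing of `E` along time
#' (`M_t = (1 - s) M_{t-1} + s E_t`, initialized at the first frame).
#' Stationary background is divided out while transient energy such as a
#' whale pulse is preserved, so loud and quiet recordings map to comparable
#' dynamic ranges.
#'
#' @param spectrogram non-negative matrix (time x frequency).
#' @param pcen_params list as in [frontend_config()].
#' @return matrix of the same shape, all values >= 0; keeps the frequency
#'   attributes of the input.
#' @export
pcen <- function(spectrogram, pcen_params = frontend_config()$pcen_params) {
  if (any(spectrogram < 0)) stop("PCEN input must be non-negative")
  p <- pcen_params
  M <- matrix(0, nrow(spectrogram), ncol(spectrogram))
  M[1, ] <- spectrogram[1, ]
  if (nrow(spectrogram) > 1) {
    for (t in 2:nrow(spectrogram))
      M[t, ] <- (1 - p$s) * M[t - 1, ] + p$s * spectrogram[t, ]
  }
  out <- (spectrogram / (p$eps + M)^p$alpha + p$delta)^p$r - p$delta^p$r
  out <- pmax(out, 0)
  attr(out, "freq_hz") <- attr(spectrogram, "freq_hz")
  attr(out, "bin_index") <- attr(spectrogram, "bin_index")
  out
}

# bilinear resize of a matrix to n_out rows x m_out cols, aligned so the
# first/last samples map to the first/last output positions
bilinear_resize <- function(x, n_out, m_out) {
  n <- nrow(x); m <- ncol(x)
  ri <- if (n_out == 1) 1 else seq(1, n, length.out = n_out)
  ci <- if (m_out == 1) 1 else seq(1, m, length.out = m_out)
  r0 <- pmin(floor(ri), n - 1L); r0[n == 1] <- 1
  c0 <- pmin(floor(ci), m - 1L); c0[m == 1] <- 1
  if (n == 1) { r0 <- rep(1, n_out); fr <- rep(0, n_out) } else fr <- ri - r0
  if (m == 1) { c0 <- rep(1, m_out); fc <- rep(0, m_out) } else fc <- ci - c0
  r1 <- pmin(r0 + 1L, n); c1 <- pmin(c0 + 1L, m)
  a <- x[r0, c0, drop = FALSE]; b <- x[r1, c0, drop = FALSE]
  cc <- x[r0, c1, drop = FALSE]; d <- x[r1, c1, drop = FALSE]
  wr <- matrix(fr, n_out, m_out); wc <- matrix(fc, n_out, m_out, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc +
    d * wr * wc
}

#' Convert a PCEN spectrogram to the detector input tensor
#'
#' Bilinear resize to the configured (time x frequency) shape, min-max
#' scaling to \[0, 1\] (a constant spectrogram maps to all zeros), and
#' replication into three identical channels.
#'
#' @param spectrogram PCEN spectrogram matrix (time x frequency).
#' @param config a [frontend_config()].
#' @return array of shape `config$out_shape`.
#' @export
to_input <- function(spectrogram, config = frontend_config()) {
  if (length(spectrogram) == 0) stop("empty spectrogram")
  shp <- config$out_shape
  z <- bilinear_resize(unclass(spectrogram), shp[1], shp[2])
  rng <- range(z)
  z <- if (rng[2] - rng[1] > 1e-12 * max(abs(rng), 1))
    (z - rng[1]) / (rng[2] - rng[1]) else z * 0
  array(rep(z, shp[3]), dim = shp)
}

#' Run the full frontend over a scene
#'
#' Splits a waveform into consecutive 30-s frames (dropping a trailing
#' partial frame), applies STFT band-limiting, PCEN and tensor conversion,
#' and returns the stacked detector inputs.
#'
#' @param waveform numeric samples at `in_rate`.
#' @param in_rate input sampling rate, Hz.
#' @param config a [frontend_config()].
#' @return list with `x` (matrix, one flattened input tensor per column),
#'   `start_s` (frame start times), and `shape` (tensor dimensions).
#' @export
frontend_frames <- function(waveform, in_rate, config = frontend_config()) {
  wav <- resample_audio(waveform, in_rate, config$target_rate_hz)
  flen <- round(config$frame_len_s * config$target_rate_hz)
  n_frames <- floor(length(wav) / flen)
  if (n_frames < 1) stop("waveform shorter than one frame")
  shp <- config$out_shape
  x <- matrix(0, prod(shp), n_frames)
  for (k in seq_len(n_frames)) {
    seg <- wav[((k - 1) * flen + 1):(k * flen)]
    x[, k] <- as.vector(to_input(pcen(stft_bandlimit(seg, config),
                                      config$pcen_params), config))
  }
  list(x = x, start_s = (seq_len(n_frames) - 1) * config$frame_len_s,
       shape = shp)
}
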