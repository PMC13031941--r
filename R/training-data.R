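#' Build a labelled synthetic frame dataset
#'
#' Generates annotated acoustic scenes (alternating airgun-on and
#' airgun-off), runs the spectrogram frontend over consecutive 30-s frames
#' and labels each frame by ground-truth whale-pulse presence. The default
#' pulse rate gives roughly balanced classes (P(pulse in 30 s) =
#' 1 - exp(-rate/2) ~ 0.55 at 1.6 pulses/min).
#'
#' @param n_frames number of labelled frames to return.
#' @param snr_db pulse signal-to-noise ratio, dB.
#' @param pulse_rate_per_min whale-pulse rate.
#' @param airgun_frac fraction of scenes with airgun shooting active.
#' @param scene_duration_s duration of each generated scene.
#' @param seed integer seed; scenes are seeded deterministically from it.
#' @param config frontend configuration.
#' @return list with `x` (matrix, one flattened input tensor per column),
#'   `labels` (binary vector), `shape`.
#' @export
synthetic_frame_dataset <- function(n_frames, snr_db = 10,
                                    pulse_rate_per_min = 1.6,
                                    airgun_frac = 0.5,
                                    scene_duration_s = 1200,
                                    seed = 1L,
                                    config = frontend_config()) {
  per_scene <- floor(scene_duration_s / config$frame_len_s)
  n_scenes <- ceiling(n_frames / per_scene)
  xs <- vector("list", n_scenes)
  labs <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    cfg <- scene_config(
      duration_s = scene_duration_s,
      pulse_rate_per_min = pulse_rate_per_min,
      pulse_params = list(f_start_hz = 23, f_end_hz = 18, duration_s = 1.0,
                          snr_db = snr_db),
      airgun_active = (i %% max(1, round(1 / max(airgun_frac, 1e-9)))) == 0,
      seed = seed * 1000L + i)
    sc <- simulate_scene(cfg)
    fr <- frontend_frames(sc$waveform, sc$sample_rate_hz, config)
    xs[[i]] <- fr$x
    labs[[i]] <- frame_labels(sc$events, cfg$duration_s,
                              config$frame_len_s)$label
  }
  x <- do.call(cbind, xs)[, seq_len(n_frames), drop = FALSE]
  labels <- unlist(labs)[seq_len(n_frames)]
  list(x = x, labels = labels, shape = config$out_shape)
}
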