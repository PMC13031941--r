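# shared small fixtures built in code

tone_frame <- function(freq_hz = 20, n = 6000, fs = 200)
  sin(2 * pi * freq_hz * (seq_len(n) - 1) / fs)

# brute-force interval-overlap frame labelling oracle
naive_frame_labels <- function(events, duration_s, frame_len_s = 30) {
  n_frames <- floor(duration_s / frame_len_s)
  vapply(seq_len(n_frames), function(k) {
    f0 <- (k - 1) * frame_len_s
    f1 <- f0 + frame_len_s
    hit <- FALSE
    for (r in seq_len(nrow(events))) {
      if (events$kind[r] != "whale_pulse") next
      a <- events$onset_s[r]
      b <- a + events$duration_s[r]
      if (a < f1 && b > f0) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

# exhaustive pairwise AUC oracle: P(score+ > score-) + 0.5 P(tie)
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# per-point tricube local-linear regression oracle
naive_loess <- function(x, y, span) {
  n <- length(x)
  k <- floor(span * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    dmax <- sort(d)[k]
    w <- pmax(1 - (d / dmax)^3, 0)^3
    stats::lm.wfit(cbind(1, x - x[i]), y, w)$coefficients[1]
  }, numeric(1))
}
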