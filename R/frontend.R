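#' Log mel-filterbank energies
#'
#' Converts a mono waveform into the acoustic features the transcriber
#' consumes: framing with a 25 ms window and 10 ms hop, Hann windowing, FFT
#' power spectrum, a mel-spaced triangular filterbank (80 bins by default),
#' and a floored log. Frame count follows
#' `floor((n_samples - win_samples) / hop_samples) + 1`.
#'
#' @param waveform numeric vector of audio samples.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param n_bins number of mel bins (default 80).
#' @param win_s analysis window length in seconds (default 0.025).
#' @param hop_s hop between frames in seconds (default 0.010).
#' @param log_floor energy floor applied before the log so silent frames map
#'   to `log(log_floor)` instead of `-Inf` (default 1e-10).
#' @return a `feature_matrix`: numeric matrix (frames x `n_bins`) with
#'   attributes `frame_hop_s`, `frame_len_s`, `n_bins`, `sample_rate`.
#' @export
log_filterbank <- function(waveform, sample_rate, n_bins = 80,
                           win_s = 0.025, hop_s = 0.010, log_floor = 1e-10) {
  if (sample_rate <= 0) stop("sample_rate must be positive")
  win <- round(win_s * sample_rate)
  hop <- round(hop_s * sample_rate)
  n <- length(waveform)
  if (n < win) {
    stop("audio too short for one analysis window: ", n, " samples < ", win)
  }
  n_frames <- floor((n - win) / hop) + 1
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  idx <- outer(seq_len(win) - 1L, starts, `+`)
  frames <- matrix(waveform[idx], nrow = win)  # win x n_frames
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)
  frames <- frames * hann
  n_fft <- 2^ceiling(log2(win))
  padded <- matrix(0, nrow = n_fft, ncol = n_frames)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)
  n_half <- n_fft %/% 2 + 1
  power <- Mod(spec[seq_len(n_half), , drop = FALSE])^2
  fb <- mel_filterbank(n_bins, n_fft, sample_rate)
  energies <- t(fb %*% power)  # frames x bins
  out <- log(pmax(energies, log_floor))
  structure(out, class = c("feature_matrix", "matrix"),
            frame_hop_s = hop_s, frame_len_s = win_s,
            n_bins = n_bins, sample_rate = sample_rate)
}

# Triangular mel filterbank matrix (n_bins x n_fft/2+1), HTK mel scale.
mel_filterbank <- function(n_bins, n_fft, sample_rate) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  n_half <- n_fft %/% 2 + 1
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                 length.out = n_bins + 2)
  bin_pts <- floor((n_fft + 1) * mel_to_hz(mel_pts) / sample_rate)
  fb <- matrix(0, nrow = n_bins, ncol = n_half)
  for (b in seq_len(n_bins)) {
    l <- bin_pts[b]; c <- bin_pts[b + 1]; r <- bin_pts[b + 2]
    if (c > l) {
      k <- l:(c - 1)
      fb[b, k + 1] <- (k - l) / (c - l)
    }
    if (r > c) {
      k <- c:(r - 1)
      fb[b, k + 1] <- (r - k) / (r - c)
    }
  }
  fb
}

#' Per-utterance cepstral mean and variance normalization
#'
#' Normalizes each filterbank bin to zero mean and unit variance over the
#' frames of one utterance (population variance). Bins whose variance falls
#' below `var_floor` are treated as constant and set to zero, so degenerate
#' inputs cannot produce infinities. Per-utterance statistics keep
#' single-utterance inference self-contained.
#'
#' @param feat a `feature_matrix` (or plain matrix), frames x bins, with at
#'   least 2 frames.
#' @param var_floor variance below which a bin counts as constant.
#' @return the normalized matrix, attributes preserved.
#' @export
cmvn <- function(feat, var_floor = 1e-8) {
  if (nrow(feat) < 2) stop("cmvn requires at least 2 frames, got ", nrow(feat))
  mu <- colMeans(feat)
  centered <- sweep(unclass(feat), 2, mu)
  v <- colMeans(centered^2)
  scale <- ifelse(v < var_floor, 0, 1 / sqrt(v))
  out <- sweep(centered, 2, scale, `*`)
  attributes(out) <- attributes(feat)
  out
}
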