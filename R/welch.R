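#' Welch estimator configuration
#'
#' The acquisition-protocol defaults: Hamming window of 2500 samples, 90%
#' overlap, `nfft = 2500` and a 250 MHz sampling rate, which yield exactly
#' the protocol's 0.1 MHz spectral resolution (`fs / nfft`).
#'
#' @param window_length Segment length in samples.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param nfft FFT length; defaults to the window length.
#' @param fs Sampling rate in Hz.
#' @return A `pa_welch_config`.
#' @export
welch_config <- function(window_length = 2500L, overlap = 0.90,
                         nfft = window_length, fs = 250e6) {
  stopifnot(window_length >= 2L, overlap >= 0, overlap < 1,
            nfft >= window_length, fs > 0)
  structure(list(window_length = as.integer(window_length),
                 overlap = overlap, nfft = as.integer(nfft), fs = fs),
            class = "pa_welch_config")
}

#' Welch power spectral density of a raw record
#'
#' Averaged modified periodogram over overlapping Hamming-windowed segments
#' (one-sided, density scaling), the standard Welch estimator. With the
#' default configuration the frequency axis is spaced at exactly 0.1 MHz.
#'
#' @param record A `pa_raw_record` from [synthesize_waveform()], or a bare
#'   numeric waveform.
#' @param cfg A [welch_config()].
#' @return List with `freq` (Hz) and `psd` (power per Hz, nonnegative).
#' @export
welch_power_spectrum <- function(record, cfg = welch_config()) {
  x <- if (inherits(record, "pa_raw_record")) record$waveform else as.numeric(record)
  fs <- if (inherits(record, "pa_raw_record")) record$fs else cfg$fs
  L <- cfg$window_length
  if (length(x) < L) {
    stop(sprintf("waveform has %d samples; the Welch window requires at least %d",
                 length(x), L), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("waveform must be finite", call. = FALSE)
  step <- max(1L, as.integer(round(L * (1 - cfg$overlap))))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- as.numeric(signal::hamming(L))
  U <- sum(w^2)
  # all segments as one matrix, one FFT call
  seg <- matrix(x[outer(0:(L - 1L), starts, `+`)], nrow = L)
  seg <- seg * w
  if (cfg$nfft > L) seg <- rbind(seg, matrix(0, cfg$nfft - L, ncol(seg)))
  X <- stats::mvfft(seg)
  nh <- cfg$nfft %/% 2L + 1L
  p <- rowMeans(Mod(X[seq_len(nh), , drop = FALSE])^2) / (fs * U)
  scale <- rep(2, nh); scale[1] <- 1
  if (cfg$nfft %% 2L == 0L) scale[nh] <- 1
  list(freq = (seq_len(nh) - 1L) * fs / cfg$nfft, psd = p * scale)
}
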