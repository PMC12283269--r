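#' Synthesise a raw A-line waveform with a prescribed band spectrum
#'
#' Spectrally shapes white Gaussian noise so that the Welch power spectral
#' density of the output, after band selection, matches a prescribed 90-bin
#' dB target. The target is interpolated onto the full one-sided FFT grid,
#' rolled off smoothly outside the 1--9.9 MHz analysis band, and imposed in
#' the frequency domain with Hermitian symmetry before an inverse FFT.
#'
#' @param target_log_spectrum Numeric vector of 90 dB values on the band
#'   grid ([pa_frequency_grid()]).
#' @param n_samples Waveform length; must be at least the Welch window
#'   length (2500 samples).
#' @param fs Sampling rate in Hz (default 250 MHz).
#' @param seed Integer seed.
#' @param wavelength,patient_id,system_id,label Optional metadata carried on
#'   the record.
#' @return A `pa_raw_record`: list with `waveform`, `fs`, and the metadata.
#' @export
synthesize_waveform <- function(target_log_spectrum, n_samples, fs = 250e6,
                                seed = 1L, wavelength = NA_real_,
                                patient_id = NA_character_,
                                system_id = NA_integer_, label = NA_integer_) {
  if (!all(is.finite(target_log_spectrum)) || length(target_log_spectrum) != 90L) {
    stop("target_log_spectrum must be 90 finite dB values", call. = FALSE)
  }
  if (n_samples < 2500L) {
    stop("n_samples must be >= the Welch window length of 2500 samples",
         call. = FALSE)
  }
  n <- as.integer(n_samples)
  band_f <- pa_frequency_grid() * 1e6
  # one-sided FFT frequency grid
  freqs <- (0:(n %/% 2)) * fs / n
  target_lin <- 10^(target_log_spectrum / 10)
  # interpolate inside the band; smooth exponential roll-off to a -40 dB
  # floor outside it, so the band content dominates the signal energy
  s <- stats::approx(band_f, target_lin, xout = freqs, rule = 2)$y
  floor_lin <- max(target_lin) * 1e-4
  lo <- band_f[1]; hi <- band_f[90]
  below <- freqs < lo
  above <- freqs > hi
  s[below] <- floor_lin + (target_lin[1] - floor_lin) *
    exp(-((lo - freqs[below]) / 2e5)^2)
  s[above] <- floor_lin + (target_lin[90] - floor_lin) *
    exp(-((freqs[above] - hi) / 2e5)^2)

  with_seed(seed, {
    nh <- length(freqs)
    # E|X_k|^2 = S(f_k) * fs * n / 2 gives a one-sided density of S
    amp <- sqrt(s * fs * n / 2)
    re <- stats::rnorm(nh); im <- stats::rnorm(nh)
    X <- complex(real = amp * re / sqrt(2), imaginary = amp * im / sqrt(2))
    X[1] <- complex(real = amp[1] * re[1], imaginary = 0)
    if (n %% 2 == 0) X[nh] <- complex(real = amp[nh] * re[nh], imaginary = 0)
    full <- c(X, Conj(rev(X[2:(nh - 1L + (n %% 2))])))
    w <- Re(stats::fft(full, inverse = TRUE)) / n
    structure(list(waveform = w, fs = fs, wavelength = wavelength,
                   patient_id = patient_id, system_id = system_id,
                   label = label),
              class = "pa_raw_record")
  })
}
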