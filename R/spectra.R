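#' Calibration profile for band selection
#'
#' Linear-domain gain vectors divided out of the PSD before conversion to
#' dB: a 90-bin transducer frequency response and a 77-entry per-wavelength
#' pulse-energy correction. Defaults are all-ones (no correction).
#'
#' @param transducer_response Positive length-90 vector.
#' @param wavelength_energy Positive length-77 vector.
#' @return A `pa_calibration`.
#' @export
calibration_profile <- function(transducer_response = rep(1, 90L),
                                wavelength_energy = rep(1, 77L)) {
  if (length(transducer_response) != 90L || length(wavelength_energy) != 77L) {
    stop("calibration vectors must have 90 (frequency) and 77 (wavelength) entries",
         call. = FALSE)
  }
  if (any(transducer_response <= 0) || any(wavelength_energy <= 0)) {
    stop("calibration entries must be strictly positive", call. = FALSE)
  }
  structure(list(transducer_response = as.numeric(transducer_response),
                 wavelength_energy = as.numeric(wavelength_energy)),
            class = "pa_calibration")
}

#' Select the analysis band and convert to calibrated dB
#'
#' Picks the 90 analysis bins (1.0--9.9 MHz by default) out of a full Welch
#' PSD, divides by the transducer response and the wavelength energy in the
#' linear power domain, and returns `10 log10` of the result.
#'
#' @param psd Output of [welch_power_spectrum()] (list with `freq`, `psd`).
#' @param calib A [calibration_profile()].
#' @param wavelength Wavelength in nm (selects the energy-correction entry).
#' @param band_start First band bin in MHz (1.0 or 1.1).
#' @return Numeric vector of 90 dB values.
#' @export
band_select_and_calibrate <- function(psd, calib = calibration_profile(),
                                      wavelength = pa_wavelength_grid()[1],
                                      band_start = 1.0) {
  band <- pa_frequency_grid(band_start) * 1e6
  idx <- match(round(band, 3), round(psd$freq, 3))
  if (anyNA(idx)) {
    stop("PSD frequency axis does not cover the 1-10 MHz band at 0.1 MHz spacing",
         call. = FALSE)
  }
  wl_idx <- match(wavelength, pa_wavelength_grid())
  if (is.na(wl_idx)) stop("wavelength not on the 77-entry grid", call. = FALSE)
  p <- psd$psd[idx] / (calib$transducer_response * calib$wavelength_energy[wl_idx])
  10 * log10(p)
}

#' Assemble a 77x90 spectrum matrix from per-wavelength band vectors
#'
#' @param per_wavelength_vectors List of 77 length-90 dB vectors ordered by
#'   (or named after) the wavelength grid.
#' @return Matrix 77x90 with wavelength rownames and frequency colnames.
#' @export
assemble_spectrum_matrix <- function(per_wavelength_vectors) {
  wl <- pa_wavelength_grid()
  if (length(per_wavelength_vectors) != 77L) {
    nm <- names(per_wavelength_vectors)
    missing_wl <- if (!is.null(nm)) setdiff(as.character(wl), nm) else character(0)
    stop(sprintf("expected 77 per-wavelength vectors, got %d%s",
                 length(per_wavelength_vectors),
                 if (length(missing_wl)) paste0("; missing wavelengths: ",
                                                paste(missing_wl, collapse = ", ")) else ""),
         call. = FALSE)
  }
  if (!is.null(names(per_wavelength_vectors))) {
    ord <- match(as.character(wl), names(per_wavelength_vectors))
    if (anyNA(ord)) {
      stop(paste0("missing wavelengths: ",
                  paste(wl[is.na(ord)], collapse = ", ")), call. = FALSE)
    }
    per_wavelength_vectors <- per_wavelength_vectors[ord]
  }
  m <- do.call(rbind, lapply(per_wavelength_vectors, function(v) {
    if (length(v) != 90L) stop("each band vector must have 90 bins", call. = FALSE)
    as.numeric(v)
  }))
  dimnames(m) <- list(as.character(wl), sprintf("%.1f", pa_frequency_grid()))
  m
}
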