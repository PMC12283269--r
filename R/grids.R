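#' Optical wavelength grid of the acquisition protocol
#'
#' The 77 excitation wavelengths used throughout the package: 690--950 nm and
#' 1200--1690 nm in 10 nm steps (27 + 50 entries). The first block covers the
#' haemoglobin window, the second the collagen/lipid overtone window.
#'
#' @return Integer vector of 77 wavelengths in nanometres.
#' @export
#' @examples
#' length(pa_wavelength_grid())
pa_wavelength_grid <- function() {
  c(seq(690L, 950L, by = 10L), seq(1200L, 1690L, by = 10L))
}

#' Acoustic frequency grid of the analysis band
#'
#' The 90 frequency bins of the analysis band: 1.0 to 9.9 MHz in 0.1 MHz
#' steps. The band nominally spans 1--10 MHz; with 90 stored columns at
#' 0.1 MHz resolution the low-anchored reading (first bin at 1.0 MHz, last at
#' 9.9 MHz) is used. `start` can move the anchor to 1.1 MHz for the
#' alternative reading.
#'
#' @param start First bin centre in MHz (1.0 or 1.1).
#' @return Numeric vector of 90 frequencies in MHz.
#' @export
pa_frequency_grid <- function(start = 1.0) {
  stopifnot(start %in% c(1.0, 1.1))
  seq(start, by = 0.1, length.out = 90L)
}

# Median frequency of the 90 discrete band bins (mean of the two central
# bins, 5.4 and 5.5 MHz).
pa_band_median_frequency <- function(start = 1.0) {
  f <- pa_frequency_grid(start)
  stats::median(f)
}
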