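#' Linear-fit features of a band spectrum
#'
#' Ordinary least squares of dB power on frequency (MHz) over the 90-bin
#' analysis band. Returns the conventional quantitative-spectroscopy triple:
#' spectral slope (dB/MHz), intercept (dB, value of the fitted line at
#' 0 MHz) and median (dB, fitted line evaluated at the band's median
#' frequency, 5.45 MHz for the default band). The median is the midband fit
#' value and satisfies `median = slope * f_med + intercept` by construction.
#'
#' @param band_vector Numeric vector of 90 finite dB values.
#' @param freq Frequency grid in MHz (defaults to [pa_frequency_grid()]).
#' @return List with `slope`, `intercept`, `median`, `f_med`.
#' @export
#' @examples
#' f <- pa_frequency_grid()
#' linear_fit_features(-2 * f + 30)  # slope -2, intercept 30, median 19.1
linear_fit_features <- function(band_vector, freq = pa_frequency_grid()) {
  if (length(band_vector) != length(freq)) {
    stop("band_vector and freq must have equal length", call. = FALSE)
  }
  if (!all(is.finite(band_vector))) {
    stop("band_vector must be finite", call. = FALSE)
  }
  fm <- mean(freq)
  fc <- freq - fm
  slope <- sum(fc * band_vector) / sum(fc^2)
  intercept <- mean(band_vector) - slope * fm
  f_med <- stats::median(freq)
  list(slope = slope, intercept = intercept,
       median = slope * f_med + intercept, f_med = f_med)
}

#' Per-wavelength linear-fit features for a whole cohort
#'
#' Applies [linear_fit_features()] to every (sample, wavelength) row of a
#' cohort's spectrum matrices.
#'
#' @param cohort A `pa_cohort`.
#' @return Data frame with columns `sample_id`, `patient_id`, `system_id`,
#'   `label`, `wavelength`, `slope`, `intercept`, `median`.
#' @export
cohort_feature_table <- function(cohort) {
  stopifnot(inherits(cohort, "pa_cohort"))
  fr <- cohort$freq
  fm <- mean(fr); fc <- fr - fm; ss <- sum(fc^2); f_med <- stats::median(fr)
  n <- nrow(cohort$meta); wl <- cohort$wavelength
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- cohort$spectra[i, , ]
    slope <- as.numeric(m %*% fc) / ss
    intercept <- rowMeans(m) - slope * fm
    out[[i]] <- data.frame(
      sample_id = cohort$meta$sample_id[i],
      patient_id = cohort$meta$patient_id[i],
      system_id = cohort$meta$system_id[i],
      label = cohort$meta$label[i],
      wavelength = wl,
      slope = slope, intercept = intercept,
      median = slope * f_med + intercept,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Wide slope+median feature matrix (n x 154) used by the classical
# baselines: one slope and one median column per wavelength.
feature_matrix <- function(cohort) {
  ft <- cohort_feature_table(cohort)
  ids <- unique(ft$sample_id)
  wl <- sort(unique(ft$wavelength))
  n <- length(ids)
  X <- matrix(NA_real_, n, 2L * length(wl))
  colnames(X) <- c(sprintf("slope_%d", wl), sprintf("median_%d", wl))
  ft <- ft[order(match(ft$sample_id, ids), ft$wavelength), ]
  X[, seq_along(wl)] <- matrix(ft$slope, n, length(wl), byrow = TRUE)
  X[, length(wl) + seq_along(wl)] <- matrix(ft$median, n, length(wl), byrow = TRUE)
  meta <- ft[!duplicated(ft$sample_id), c("sample_id", "patient_id", "system_id", "label")]
  rownames(X) <- meta$sample_id
  list(X = X, meta = meta, wavelength = wl)
}
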