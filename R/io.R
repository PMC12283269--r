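#' Write a cohort to a plain-text dataset directory
#'
#' Portable text container for a cohort: `spectra.csv` (one row per sample,
#' 6930 value columns in wavelength-major order), `manifest.csv`
#' (sample_id, patient_id, system_id, label, optional split) and
#' `attrs.json` (wavelength grid, frequency grid, units, schema version,
#' provenance). Values are written with 17 significant digits so the round
#' trip is exact.
#'
#' @param cohort A `pa_cohort`.
#' @param path Directory to create/overwrite.
#' @param split Optional `pa_split` recorded in the manifest.
#' @param provenance Free-text provenance string stored in the attributes.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path, split = NULL,
                          provenance = "pascl synthetic cohort") {
  stopifnot(inherits(cohort, "pa_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$meta)
  flat <- matrix(cohort$spectra, nrow = n)  # col = (f-1)*77 + w
  chr <- matrix(sprintf("%.17g", flat), nrow = n)
  colnames(chr) <- sprintf("v%04d", seq_len(ncol(chr)))
  dt <- data.table::data.table(sample_id = cohort$meta$sample_id, chr)
  data.table::fwrite(dt, file.path(path, "spectra.csv"))
  manifest <- cohort$meta
  if (!is.null(split)) {
    manifest$split <- NA_character_
    for (s in c("train", "val", "test")) {
      manifest$split[manifest$patient_id %in% split[[s]]] <- s
    }
  }
  data.table::fwrite(manifest, file.path(path, "manifest.csv"))
  attrs <- list(schema_version = 1L,
                wavelength_nm = cohort$wavelength,
                frequency_mhz = cohort$freq,
                units = "dB",
                n_samples = n,
                provenance = provenance)
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset directory back into a cohort
#'
#' Validates the schema (required manifest fields, spectrum shape, aligned
#' sample counts) and reconstructs the `pa_cohort`. Latent generator
#' parameters are not persisted.
#'
#' @param path Dataset directory written by [write_dataset()].
#' @return A `pa_cohort` (without `latent`).
#' @export
read_dataset <- function(path) {
  need <- c("spectra.csv", "manifest.csv", "attrs.json")
  have <- file.exists(file.path(path, need))
  if (!all(have)) {
    stop(paste0("dataset is missing file(s): ",
                paste(need[!have], collapse = ", ")), call. = FALSE)
  }
  attrs <- jsonlite::read_json(file.path(path, "attrs.json"), simplifyVector = TRUE)
  manifest <- as.data.frame(data.table::fread(file.path(path, "manifest.csv")))
  for (f in c("sample_id", "patient_id", "system_id", "label")) {
    if (!f %in% names(manifest)) {
      stop(sprintf("manifest is missing required field '%s'", f), call. = FALSE)
    }
  }
  sp <- data.table::fread(file.path(path, "spectra.csv"))
  ids <- sp$sample_id
  flat <- as.matrix(sp[, -1])
  storage.mode(flat) <- "double"
  if (ncol(flat) != 77L * 90L) {
    stop(sprintf("spectra have %d columns; expected 6930 (77 x 90)", ncol(flat)),
         call. = FALSE)
  }
  if (nrow(flat) != nrow(manifest) || !identical(ids, manifest$sample_id)) {
    stop("spectra and manifest sample ids are not aligned", call. = FALSE)
  }
  spectra <- array(flat, dim = c(nrow(flat), 77L, 90L))
  structure(list(spectra = spectra,
                 meta = manifest[, c("sample_id", "patient_id", "system_id",
                                     "label",
                                     intersect("split", names(manifest)))],
                 wavelength = as.numeric(attrs$wavelength_nm),
                 freq = as.numeric(attrs$frequency_mhz),
                 latent = NULL),
            class = "pa_cohort")
}
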