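#' Specification of a synthetic photoacoustic cohort
#'
#' Describes the generative model for a two-system cohort of multi-wavelength
#' photoacoustic power spectra. Per sample, wavelength \eqn{\lambda} and
#' frequency \eqn{f} (MHz), the dB-scale log power is
#' \deqn{S(\lambda, f) = a(\lambda) f + b(\lambda) + u_p(\lambda) +
#'   g_s(\lambda, f) + \varepsilon,}
#' where the class-dependent slope \eqn{a} and intercept \eqn{b} carry
#' Gaussian band offsets centred on the characteristic wavelengths 700, 1210
#' and 1370 nm, \eqn{u_p} is a per-patient random effect shared by all of a
#' patient's detection points, \eqn{g_s} is a smooth per-system calibration
#' gain (in dB) and \eqn{\varepsilon \sim N(0, \mathtt{noise\_sd}^2)}.
#' Tumour tissue is more heterogeneous, so its mean spectral slope exceeds
#' the normal-tissue slope.
#'
#' The patient effect has an intercept component (sd `patient_effect_sd`, dB)
#' and a proportional slope component (sd `0.1 * patient_effect_sd` dB/MHz),
#' so patient heterogeneity perturbs both the level and the tilt of the
#' spectrum, as individual variation does in practice.
#'
#' @param n_patients_per_system Integer vector (one entry per system) of
#'   volunteer counts. Default `c(12, 10)`: twelve volunteers on the
#'   blackbody-calibrated system, ten on the field-profile system.
#' @param points_per_patient Integer range (min, max) of detection points per
#'   volunteer; each patient's count is drawn uniformly from this range.
#' @param tumor_fraction Target marginal probability that a detection point
#'   is tumour. Patients may be all-normal: with probability 0.3 a patient's
#'   tumour propensity is 0, otherwise it is uniform on an interval chosen so
#'   the marginal matches `tumor_fraction`.
#' @param class_params List with per-class generative parameters:
#'   `slope_mean` (named `normal`/`tumor`, dB/MHz), `slope_sd`,
#'   `intercept_mean` (dB), `intercept_sd`, `band_slope_delta` (extra tumour
#'   slope at the characteristic bands, dB/MHz), `band_intercept_delta`
#'   (extra tumour level at the bands, dB), `band_width_nm`, and the
#'   frequency-localised tumour signature `freq_feature_amp` (dB),
#'   `freq_feature_center` (MHz), `freq_feature_sd` (MHz): a spectral bump
#'   at the characteristic wavelengths that a first-order linear fit
#'   captures only weakly, emulating the fine heterogeneity structure that
#'   motivates learning features beyond slope and median.
#' @param patient_effect_sd Patient random-effect scale in dB.
#' @param wavelength_jitter_sd Per-shot pulse-energy fluctuation: an
#'   independent intercept jitter per (sample, wavelength) in dB. Each
#'   wavelength's spectrum comes from a separate laser shot, so its energy
#'   error is independent across wavelengths.
#' @param system_gain List of 77x90 dB gain matrices, one per system, or
#'   `NULL` for the built-in default (system 1 identity, system 2 a smooth
#'   wavelength-dependent shift with a mild spectral tilt).
#' @param system_noise_scale Per-system multiplier on `noise_sd`; the second
#'   system's field-profile energy calibration leaves a substantially
#'   larger residual error than a blackbody reference, modelled as scale 3.
#' @param noise_sd Additive dB noise per matrix element.
#' @param wavelength_grid,freq_grid The spectral grids; defaults are the
#'   package grids and must have 77 and 90 entries.
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `pa_cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients_per_system = c(12L, 10L),
                        points_per_patient = c(3L, 6L),
                        tumor_fraction = 0.4,
                        class_params = list(),
                        patient_effect_sd = 1.5,
                        wavelength_jitter_sd = 0.5,
                        system_gain = NULL,
                        system_noise_scale = NULL,
                        noise_sd = 0.7,
                        wavelength_grid = pa_wavelength_grid(),
                        freq_grid = pa_frequency_grid(),
                        seed = 42L) {
  defaults <- list(
    slope_mean = c(normal = -1.3, tumor = -1.15),
    slope_sd = c(normal = 0.15, tumor = 0.15),
    intercept_mean = c(normal = 25, tumor = 25),
    intercept_sd = c(normal = 1.0, tumor = 1.0),
    band_slope_delta = 0.05,
    band_intercept_delta = 0.3,
    band_centers_nm = c(700, 1210, 1370),
    band_width_nm = 40,
    freq_feature_amp = 3.5,
    freq_feature_center = 7.0,
    freq_feature_sd = 0.8
  )
  cp <- utils::modifyList(defaults, class_params)

  if (length(wavelength_grid) != 77L ||
      !isTRUE(all.equal(as.numeric(wavelength_grid), as.numeric(pa_wavelength_grid())))) {
    stop("wavelength_grid must be the 77-entry grid 690-950, 1200-1690 nm, step 10 nm",
         call. = FALSE)
  }
  if (length(freq_grid) != 90L) {
    stop("freq_grid must have exactly 90 bins", call. = FALSE)
  }
  stopifnot(length(points_per_patient) == 2L,
            points_per_patient[1] >= 1L,
            points_per_patient[2] >= points_per_patient[1],
            tumor_fraction >= 0, tumor_fraction <= 1,
            patient_effect_sd >= 0, wavelength_jitter_sd >= 0, noise_sd >= 0)
  if (cp$slope_mean[["tumor"]] <= cp$slope_mean[["normal"]]) {
    stop("tumor mean slope must exceed normal mean slope", call. = FALSE)
  }

  n_sys <- length(n_patients_per_system)
  if (is.null(system_gain)) {
    system_gain <- default_system_gains(n_sys, wavelength_grid, freq_grid)
  }
  if (length(system_gain) != n_sys) {
    stop("system_gain must supply one 77x90 matrix per system", call. = FALSE)
  }
  for (g in system_gain) {
    if (!is.matrix(g) || !all(dim(g) == c(77L, 90L)) || !all(is.finite(g))) {
      stop("each system gain must be a finite 77x90 matrix (dB)", call. = FALSE)
    }
  }
  if (is.null(system_noise_scale)) {
    system_noise_scale <- c(1, rep(3, n_sys - 1L))
  }
  stopifnot(length(system_noise_scale) == n_sys, all(system_noise_scale >= 0))

  structure(list(
    n_patients_per_system = as.integer(n_patients_per_system),
    points_per_patient = as.integer(points_per_patient),
    tumor_fraction = tumor_fraction,
    class_params = cp,
    patient_effect_sd = patient_effect_sd,
    wavelength_jitter_sd = wavelength_jitter_sd,
    system_gain = system_gain,
    system_noise_scale = system_noise_scale,
    noise_sd = noise_sd,
    wavelength_grid = as.numeric(wavelength_grid),
    freq_grid = as.numeric(freq_grid),
    seed = as.integer(seed)
  ), class = "pa_cohort_spec")
}

# Smooth default calibration gains: system 1 is the reference (0 dB);
# further systems get a cosine wavelength ripple plus a mild spectral tilt,
# emulating a different energy-calibration chain.
default_system_gains <- function(n_sys, wl, fr) {
  lapply(seq_len(n_sys), function(s) {
    if (s == 1L) return(matrix(0, 77L, 90L))
    amp <- 3 * (s - 1L)
    wshift <- amp * cos(2 * pi * (wl - wl[1]) / 1200) + amp / 2
    tilt <- -0.2 * (s - 1L) * (fr - stats::median(fr))
    outer(wshift, rep(1, 90L)) + outer(rep(1, 77L), tilt)
  })
}

# Gaussian bump profile over wavelength, unit height at each band centre.
band_bump <- function(wl, centers, width) {
  b <- rep(0, length(wl))
  for (c0 in centers) b <- b + exp(-((wl - c0)^2) / (2 * width^2))
  pmin(b, 1)
}

#' Generate a synthetic cohort of spectrum samples
#'
#' Draws patients, per-patient detection points with binary labels, and
#' 77x90 dB power-spectrum matrices from the generative model described in
#' [cohort_spec()]. The latent generating parameters (per-sample slope and
#' intercept curves, patient effects, class profiles) are retained so
#' recovery can be checked against the preprocessing fits.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `pa_cohort`: a list with `spectra` (array
#'   `N x 77 x 90`, dB), `meta` (data.frame with `sample_id`, `patient_id`,
#'   `system_id`, `label`), `wavelength`, `freq`, and `latent` (true
#'   per-sample slope/intercept curves before system gain and noise, patient
#'   effects, class profiles).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients_per_system = c(3, 2), seed = 1))
#' dim(co$spectra)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "pa_cohort_spec"))
  cp <- spec$class_params
  wl <- spec$wavelength_grid
  fr <- spec$freq_grid
  bump <- band_bump(wl, cp$band_centers_nm, cp$band_width_nm)
  # The tumour frequency signature is orthogonalised against the {1, f}
  # basis of the first-order linear fit: slope/median summaries are blind
  # to it by construction, so it models the fine spectral structure that
  # motivates learned features.
  fbump <- exp(-((fr - cp$freq_feature_center)^2) / (2 * cp$freq_feature_sd^2))
  P <- cbind(1, fr)
  fbump_orth <- as.numeric(fbump - P %*% solve(crossprod(P), crossprod(P, fbump)))
  # deterministic class profiles a_c(lambda), b_c(lambda)
  class_profiles <- list(
    normal = list(slope = rep(cp$slope_mean[["normal"]], 77L),
                  intercept = rep(cp$intercept_mean[["normal"]], 77L)),
    tumor = list(slope = cp$slope_mean[["tumor"]] + cp$band_slope_delta * bump,
                 intercept = cp$intercept_mean[["tumor"]] + cp$band_intercept_delta * bump)
  )

  with_seed(spec$seed, {
    # patient table
    pat <- list(); k <- 0L
    p_all_normal <- 0.25
    # marginal tumour fraction = (1 - p0) * mean(unif(lo, hi)); solve the
    # midpoint, with a moderate half-width so cohort-level label balance
    # does not swing wildly between seeds
    mid <- spec$tumor_fraction / (1 - p_all_normal)
    lo <- max(0, mid - 0.235); hi <- min(1, mid + 0.235)
    for (s in seq_along(spec$n_patients_per_system)) {
      for (p in seq_len(spec$n_patients_per_system[s])) {
        k <- k + 1L
        npts <- sample(seq(spec$points_per_patient[1], spec$points_per_patient[2]), 1L)
        theta <- if (stats::runif(1) < p_all_normal) 0 else stats::runif(1, lo, hi)
        pat[[k]] <- list(
          patient_id = sprintf("S%d_P%02d", s, p),
          system_id = s, n_points = npts, theta = theta,
          u_intercept = stats::rnorm(1, 0, spec$patient_effect_sd),
          u_slope = stats::rnorm(1, 0, 0.1 * spec$patient_effect_sd)
        )
      }
    }

    n_total <- sum(vapply(pat, function(p) p$n_points, integer(1)))
    spectra <- array(NA_real_, dim = c(n_total, 77L, 90L))
    meta <- data.frame(
      sample_id = character(n_total), patient_id = character(n_total),
      system_id = integer(n_total), label = integer(n_total),
      stringsAsFactors = FALSE
    )
    lat_slope <- matrix(NA_real_, n_total, 77L)
    lat_intercept <- matrix(NA_real_, n_total, 77L)

    i <- 0L
    for (p in pat) {
      for (j in seq_len(p$n_points)) {
        i <- i + 1L
        lab <- as.integer(stats::runif(1) < p$theta)
        cls <- if (lab == 1L) "tumor" else "normal"
        a <- class_profiles[[cls]]$slope +
          stats::rnorm(1, 0, cp$slope_sd[[cls]]) + p$u_slope
        b <- class_profiles[[cls]]$intercept +
          stats::rnorm(1, 0, cp$intercept_sd[[cls]]) + p$u_intercept
        clean <- outer(a, fr) + outer(b, rep(1, 90L))
        if (lab == 1L && cp$freq_feature_amp != 0) {
          clean <- clean + cp$freq_feature_amp * outer(bump, fbump_orth)
        }
        if (spec$wavelength_jitter_sd > 0) {
          clean <- clean + stats::rnorm(77L, 0, spec$wavelength_jitter_sd)
        }
        gain <- spec$system_gain[[p$system_id]]
        sdn <- spec$noise_sd * spec$system_noise_scale[p$system_id]
        noise <- if (sdn > 0) matrix(stats::rnorm(77L * 90L, 0, sdn), 77L, 90L) else 0
        spectra[i, , ] <- clean + gain + noise
        meta$sample_id[i] <- sprintf("%s_pt%02d", p$patient_id, j)
        meta$patient_id[i] <- p$patient_id
        meta$system_id[i] <- p$system_id
        meta$label[i] <- lab
        lat_slope[i, ] <- a
        lat_intercept[i, ] <- b
      }
    }

    structure(list(
      spectra = spectra, meta = meta,
      wavelength = wl, freq = fr,
      latent = list(slope = lat_slope, intercept = lat_intercept,
                    patients = do.call(rbind, lapply(pat, function(p) {
                      data.frame(patient_id = p$patient_id, system_id = p$system_id,
                                 theta = p$theta, u_intercept = p$u_intercept,
                                 u_slope = p$u_slope, stringsAsFactors = FALSE)
                    })),
                    class_profiles = class_profiles),
      spec = spec
    ), class = "pa_cohort")
  })
}

#' @export
print.pa_cohort <- function(x, ...) {
  cat(sprintf("pa_cohort: %d samples, %d patients, %d system(s); %d tumour / %d normal\n",
              nrow(x$meta), length(unique(x$meta$patient_id)),
              length(unique(x$meta$system_id)),
              sum(x$meta$label == 1L), sum(x$meta$label == 0L)))
  invisible(x)
}

#' Apply a per-system calibration gain to a cohort
#'
#' Adds a system-specific dB gain surface to every sample of the matching
#' system. Multiplicative gain in the linear power domain is an additive
#' shift in dB; labels and metadata are untouched.
#'
#' @param cohort A `pa_cohort`.
#' @param system_gain List of 77x90 dB gain matrices indexed by system id.
#' @return The cohort with shifted spectra.
#' @export
apply_system_profile <- function(cohort, system_gain) {
  stopifnot(inherits(cohort, "pa_cohort"))
  for (g in system_gain) {
    if (!is.matrix(g) || !all(dim(g) == c(77L, 90L))) {
      stop("each system gain must be a 77x90 matrix", call. = FALSE)
    }
    if (!all(is.finite(g))) stop("system gain must be finite", call. = FALSE)
  }
  for (i in seq_len(nrow(cohort$meta))) {
    s <- cohort$meta$system_id[i]
    if (s <= length(system_gain)) {
      cohort$spectra[i, , ] <- cohort$spectra[i, , ] + system_gain[[s]]
    }
  }
  cohort
}

#' Subset a cohort by sample index or metadata predicate
#'
#' @param cohort A `pa_cohort`.
#' @param idx Integer or logical index over samples.
#' @return The subsetted `pa_cohort`.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "pa_cohort"))
  cohort$spectra <- cohort$spectra[idx, , , drop = FALSE]
  cohort$meta <- cohort$meta[idx, , drop = FALSE]
  rownames(cohort$meta) <- NULL
  if (!is.null(cohort$latent$slope)) {
    cohort$latent$slope <- cohort$latent$slope[idx, , drop = FALSE]
    cohort$latent$intercept <- cohort$latent$intercept[idx, , drop = FALSE]
  }
  cohort
}
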