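test_that("spectral grids match the acquisition protocol", {
  wl <- pa_wavelength_grid()
  expect_length(wl, 77L)
  expect_identical(wl[1], 690L)
  expect_identical(wl[27], 950L)
  expect_identical(wl[28], 1200L)
  expect_identical(wl[77], 1690L)
  expect_true(all(diff(wl) %in% c(10L, 250L)))
  fr <- pa_frequency_grid()
  expect_length(fr, 90L)
  expect_equal(fr[1], 1.0)
  expect_equal(fr[90], 9.9)
  expect_equal(unique(round(diff(fr), 10)), 0.1)
  expect_equal(pascl:::pa_band_median_frequency(), 5.45)
})

test_that("cohort spec enforces its invariants", {
  expect_error(cohort_spec(wavelength_grid = 1:76), "77")
  expect_error(cohort_spec(freq_grid = 1:89), "90")
  expect_error(cohort_spec(class_params = list(
    slope_mean = c(normal = -1, tumor = -2))), "exceed")
  expect_error(cohort_spec(system_gain = list(matrix(0, 10, 10),
                                              matrix(0, 77, 90))), "77x90")
})

test_that("generation is deterministic and correctly shaped", {
  a <- generate_cohort(tiny_spec(seed = 3))
  b <- generate_cohort(tiny_spec(seed = 3))
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$spectra, generate_cohort(tiny_spec(seed = 4))$spectra))
  expect_equal(dim(a$spectra)[2:3], c(77L, 90L))
  expect_true(all(is.finite(a$spectra)))
  expect_true(all(a$meta$label %in% 0:1))
  # per-patient point counts within the configured range
  cnt <- table(a$meta$patient_id)
  expect_true(all(cnt >= 3 & cnt <= 5))
  # both all-normal and mixed patients occur across seeds
  mix <- sapply(split(a$meta$label, a$meta$patient_id), mean)
  expect_true(any(mix == 0))
})

test_that("latent parameters are recovered exactly without noise", {
  sp <- tiny_spec(seed = 5, patient_effect_sd = 0, noise_sd = 0,
                  class_params = list(slope_sd = c(normal = 0, tumor = 0),
                                      intercept_sd = c(normal = 0, tumor = 0),
                                      freq_feature_amp = 0),
                  system_gain = list(matrix(0, 77, 90), matrix(0, 77, 90)),
                  system_noise_scale = c(1, 1))
  co <- generate_cohort(sp)
  ft <- cohort_feature_table(co)
  prof <- co$latent$class_profiles
  for (lab in 0:1) {
    cls <- if (lab == 1) "tumor" else "normal"
    sub <- ft[ft$label == lab, ]
    for (wi in c(1, 2, 40, 77)) {
      w <- co$wavelength[wi]
      got <- sub$slope[sub$wavelength == w]
      expect_equal(got, rep(prof[[cls]]$slope[wi], length(got)),
                   tolerance = 1e-10)
    }
  }
  # and generic latent slope agreement per sample
  expect_equal(ft$slope[ft$sample_id == co$meta$sample_id[1]],
               co$latent$slope[1, ], tolerance = 1e-10)
})

test_that("patient effect monotonically inflates between-patient slope variance", {
  vars <- sapply(c(0.5, 1.5, 4), function(sdp) {
    co <- generate_cohort(tiny_spec(seed = 11, patient_effect_sd = sdp))
    ft <- cohort_feature_table(co)
    sub <- ft[ft$wavelength == 800 & ft$label == 0, ]
    pm <- tapply(sub$slope, sub$patient_id, mean)
    stats::var(pm[!is.na(pm)])
  })
  expect_true(all(diff(vars) > 0))
})

test_that("system profiles shift spectra without touching metadata", {
  co <- generate_cohort(tiny_spec(seed = 2))
  ident <- lapply(1:2, function(i) matrix(0, 77, 90))
  expect_identical(apply_system_profile(co, ident)$spectra, co$spectra)
  plus6 <- lapply(1:2, function(i) matrix(6, 77, 90))
  shifted <- apply_system_profile(co, plus6)
  expect_equal(shifted$spectra, co$spectra + 6)
  expect_identical(shifted$meta, co$meta)
  expect_error(apply_system_profile(co, list(matrix(0, 5, 5))), "77x90")
  expect_error(apply_system_profile(co, list(matrix(NA_real_, 77, 90))),
               "finite")
})

test_that("a nonuniform gain widens the between-system separation", {
  sp <- tiny_spec(seed = 6,
                  system_gain = list(matrix(0, 77, 90), matrix(0, 77, 90)),
                  system_noise_scale = c(1, 1))
  co <- generate_cohort(sp)
  centroid_gap <- function(cohort) {
    # 2-d embedding: per-sample mean level and mean fitted slope
    ft <- cohort_feature_table(cohort)
    emb <- cbind(tapply(ft$median, ft$sample_id, mean),
                 tapply(ft$slope, ft$sample_id, mean))
    meta <- cohort$meta[match(rownames(emb), cohort$meta$sample_id), ]
    c1 <- colMeans(emb[meta$system_id == 1, , drop = FALSE])
    c2 <- colMeans(emb[meta$system_id == 2, , drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }
  gain <- pascl:::default_system_gains(2, pa_wavelength_grid(), pa_frequency_grid())
  expect_gt(centroid_gap(apply_system_profile(co, gain)), centroid_gap(co))
})

test_that("waveform synthesis honours its contract", {
  expect_error(synthesize_waveform(rep(0, 90), 1000), "2500")
  expect_error(synthesize_waveform(rep(NA_real_, 90), 5000), "finite")
  # pure-tone target: Welch PSD argmax at the 5.0 MHz bin
  target <- rep(-30, 90)
  target[match(5.0, pa_frequency_grid())] <- 20
  rec <- synthesize_waveform(target, 25000, seed = 2)
  ps <- welch_power_spectrum(rec)
  expect_equal(ps$freq[which.max(ps$psd)], 5.0e6)
  # determinism and seed-dependence
  r1 <- synthesize_waveform(target, 5000, seed = 9)
  r2 <- synthesize_waveform(target, 5000, seed = 9)
  r3 <- synthesize_waveform(target, 5000, seed = 10)
  expect_identical(r1$waveform, r2$waveform)
  expect_false(identical(r1$waveform, r3$waveform))
})
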