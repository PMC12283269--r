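test_that("Welch configuration fixes the 0.1 MHz resolution", {
  cfg <- welch_config()
  expect_equal(cfg$fs / cfg$nfft, 0.1e6)
  expect_equal(cfg$window_length, 2500L)
  expect_equal(cfg$overlap, 0.90)
  expect_error(welch_config(overlap = 1), "overlap")
})

test_that("Welch estimator identifies tones, DC, and total power", {
  fs <- 250e6
  t <- (0:24999) / fs
  ps <- welch_power_spectrum(sin(2 * pi * 5e6 * t))
  expect_equal(unique(round(diff(ps$freq), 6)), 0.1e6)
  expect_true(all(ps$psd >= 0))
  expect_equal(ps$freq[which.max(ps$psd)], 5e6)

  dc <- welch_power_spectrum(rep(3.2, 10000))
  expect_equal(dc$freq[which.max(dc$psd)], 0)
  # all power in the DC main lobe (the Hamming window spreads it over a
  # few neighbouring bins); nothing beyond
  expect_lt(sum(dc$psd[-(1:4)]) / dc$psd[1], 1e-6)

  # Parseval: integrated density ~ variance, cross-checked against a
  # direct single-segment periodogram oracle
  set.seed(4)
  w <- rnorm(50000, sd = 1.7)
  pw <- welch_power_spectrum(w)
  expect_equal(sum(pw$psd) * 0.1e6, var(w), tolerance = 0.05)
  seg <- w[1:2500]
  per <- abs(fft(seg))^2 / (fs * 2500)
  oracle_total <- (per[1] + 2 * sum(per[2:1250]) + per[1251]) * 0.1e6
  expect_equal(sum(pw$psd) * 0.1e6, oracle_total, tolerance = 0.1)

  expect_error(welch_power_spectrum(rnorm(1000)), "2500")
})

test_that("band selection and calibration follow the dB algebra", {
  psd <- list(freq = (0:1250) * 0.1e6, psd = rep(1, 1251))
  out <- band_select_and_calibrate(psd)
  expect_length(out, 90L)
  expect_equal(out, rep(0, 90))
  # doubling the transducer response drops every bin by 10 log10 2
  cal2 <- calibration_profile(transducer_response = rep(2, 90))
  expect_equal(band_select_and_calibrate(psd, cal2), rep(-10 * log10(2), 90),
               tolerance = 1e-12)
  # band edges: bin 1 <-> 1.0 MHz, bin 90 <-> 9.9 MHz
  psd2 <- psd
  psd2$psd[psd2$freq == 1.0e6] <- 10
  psd2$psd[psd2$freq == 9.9e6] <- 100
  out2 <- band_select_and_calibrate(psd2)
  expect_equal(out2[1], 10)
  expect_equal(out2[90], 20)
  expect_error(calibration_profile(transducer_response = rep(0, 90)),
               "positive")
  short <- list(freq = (0:50) * 0.1e6, psd = rep(1, 51))
  expect_error(band_select_and_calibrate(short), "band")
})

test_that("spectrum matrices assemble in grid order with error reporting", {
  vecs <- lapply(seq_len(77), function(i) rep(i, 90))
  names(vecs) <- as.character(pa_wavelength_grid())
  m <- assemble_spectrum_matrix(vecs)
  expect_equal(dim(m), c(77L, 90L))
  expect_equal(unname(m["700", 1]), 2)  # 700 nm is the second grid entry
  # shuffled names are re-ordered onto the grid
  m2 <- assemble_spectrum_matrix(rev(vecs))
  expect_equal(m, m2)
  expect_error(assemble_spectrum_matrix(vecs[-5]), "76")
  bad <- vecs; names(bad)[3] <- "9999"
  expect_error(assemble_spectrum_matrix(bad), "710")
})

test_that("linear-fit features are exact on lines and equivariant", {
  f <- pa_frequency_grid()
  ft <- linear_fit_features(-2 * f + 30)
  expect_equal(ft$slope, -2)
  expect_equal(ft$intercept, 30)
  expect_equal(ft$median, -2 * 5.45 + 30)
  expect_equal(ft$median, 19.1)
  cst <- linear_fit_features(rep(4.2, 90))
  expect_equal(cst$slope, 0)
  expect_equal(cst$intercept, 4.2)
  expect_equal(cst$median, 4.2)
  expect_error(linear_fit_features(c(rep(1, 89), NA)), "finite")
  # adding k dB shifts intercept and median, not slope
  set.seed(8)
  v <- rnorm(90)
  a <- linear_fit_features(v)
  b <- linear_fit_features(v + 3.5)
  expect_equal(b$slope, a$slope)
  expect_equal(b$intercept, a$intercept + 3.5)
  expect_equal(b$median, a$median + 3.5)
})

test_that("slope is recovered within 0.05 dB/MHz under 0.5 dB noise", {
  f <- pa_frequency_grid()
  set.seed(12)
  slopes <- replicate(200, {
    linear_fit_features(-1.1 * f + 20 + rnorm(90, 0, 0.5))$slope
  })
  expect_lt(abs(mean(slopes) + 1.1), 0.05)
})

test_that("synthesis -> Welch -> band selection closes the loop", {
  f <- pa_frequency_grid()
  target <- -1.5 * f + 28
  rec <- synthesize_waveform(target, 200000, seed = 21)
  ps <- welch_power_spectrum(rec)
  expect_equal(unique(round(diff(ps$freq), 6)), 0.1e6)
  band <- band_select_and_calibrate(ps)
  expect_lt(max(abs(band - target)), 1.5)
  # flat target at a shorter length: the estimator is unbiased but
  # noisier (90%-overlapped segments are strongly correlated), so only
  # the mean error is bounded
  flat <- synthesize_waveform(rep(0, 90), 50000, seed = 22)
  bflat <- band_select_and_calibrate(welch_power_spectrum(flat))
  expect_lt(mean(abs(bflat)), 0.8)
})

test_that("preprocessing a cohort is deterministic", {
  co <- generate_cohort(tiny_spec(seed = 14))
  expect_identical(cohort_feature_table(co), cohort_feature_table(co))
})
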