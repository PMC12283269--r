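#' Noise specification for the robustness benchmark
#'
#' Two noise families applied to preprocessed spectrum matrices:
#' * `uniform` -- elementwise `U(-rA, +rA)` with `A` the sample's peak
#'   absolute value ("signal amplitude"), so the perturbation scales with
#'   each sample's own magnitude;
#' * `gaussian` -- elementwise `N(0, sigma^2)` with an absolute `sigma` in
#'   the units of the spectra (dB).
#'
#' @param kind `"uniform"` or `"gaussian"`.
#' @param param Ratio `r` (uniform) or `sigma` (gaussian); nonnegative.
#' @param replicates Noisy copies per sample (default 10).
#' @param seed Integer seed.
#' @param amplitude `"sample"` (default, per-sample peak), `"element"`
#'   (per-element magnitude) or `"dataset"` (global peak) definitions of
#'   the uniform-noise amplitude.
#' @return A `pa_noise_spec`.
#' @export
noise_spec <- function(kind = c("uniform", "gaussian"), param,
                       replicates = 10L, seed = 42L,
                       amplitude = c("sample", "element", "dataset")) {
  kind <- match.arg(kind)
  if (param < 0) stop("noise parameter must be nonnegative", call. = FALSE)
  stopifnot(replicates >= 1L)
  structure(list(kind = kind, param = param,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), amplitude = match.arg(amplitude)),
            class = "pa_noise_spec")
}

#' Add noise to a spectrum matrix
#'
#' @param m Numeric matrix (a 77x90 spectrum, or any matrix).
#' @param spec A [noise_spec()].
#' @param seed Seed override (defaults to the spec's).
#' @param dataset_amplitude Peak absolute value of the full dataset, used
#'   when `spec$amplitude == "dataset"`.
#' @return The perturbed matrix.
#' @export
add_noise <- function(m, spec, seed = NULL, dataset_amplitude = NULL) {
  stopifnot(inherits(spec, "pa_noise_spec"))
  if (spec$param == 0) return(m)
  with_seed(seed %||% spec$seed, {
    if (spec$kind == "uniform") {
      A <- switch(spec$amplitude,
                  sample = max(abs(m)),
                  element = abs(m),
                  dataset = dataset_amplitude %||% max(abs(m)))
      m + stats::runif(length(m), -1, 1) * spec$param * A
    } else {
      m + stats::rnorm(length(m), 0, spec$param)
    }
  })
}

#' Noise-robustness evaluation of a trained model
#'
#' Evaluates the model on the clean test set, keeps only the correctly
#' classified samples, then creates `replicates` independently perturbed
#' copies of each and reports the fraction still classified correctly
#' (accuracy under noise), the 2-d head outputs of the noisy copies, and
#' their silhouette. By construction the zero-noise accuracy is exactly 1.
#'
#' @param model Trained `pa_model`.
#' @param data Test `pa_cohort` or `list(x, y)`.
#' @param spec A [noise_spec()].
#' @return List with `accuracy`, `silhouette`, `embedding` (data.frame of
#'   head outputs with labels), `n_clean_correct`, `n_noisy`.
#' @export
robustness_eval <- function(model, data, spec) {
  xy <- as_xy(data)
  clean <- predict(model, xy$x)
  keep <- which(clean$pred == xy$y)
  if (length(keep) == 0L) {
    stop("no correctly classified clean samples; robustness undefined",
         call. = FALSE)
  }
  x <- xy$x[keep, , , drop = FALSE]
  y <- xy$y[keep]
  n <- length(keep)
  R <- spec$replicates
  noisy <- array(NA_real_, dim = c(n * R, dim(x)[2], dim(x)[3]))
  ylong <- integer(n * R)
  for (i in seq_len(n)) {
    for (r in seq_len(R)) {
      noisy[(i - 1L) * R + r, , ] <-
        add_noise(x[i, , ], spec, seed = derive_seed(spec$seed, "noise", i, r))
      ylong[(i - 1L) * R + r] <- y[i]
    }
  }
  pr <- predict(model, noisy)
  sil <- if (length(unique(ylong)) > 1L) {
    silhouette_score(cbind(pr$out0, pr$out1), ylong)
  } else NA_real_
  list(accuracy = mean(pr$pred == ylong),
       silhouette = sil,
       embedding = data.frame(out0 = pr$out0, out1 = pr$out1,
                              label = ylong, pred = pr$pred),
       n_clean_correct = n, n_noisy = n * R)
}

#' Noise sweep over models and noise magnitudes
#'
#' Full factorial robustness benchmark: every model crossed with every
#' noise magnitude of the grid, reporting accuracy under noise and
#' silhouette per cell.
#'
#' @param models Named list of trained `pa_model`s.
#' @param data Test `pa_cohort` or `list(x, y)`.
#' @param params Numeric vector of noise magnitudes.
#' @param kind Noise family.
#' @param replicates,seed Passed to [noise_spec()].
#' @return Tidy data.frame: model, kind, param, accuracy, silhouette.
#' @export
noise_sweep <- function(models, data, params,
                        kind = c("uniform", "gaussian"),
                        replicates = 10L, seed = 42L) {
  kind <- match.arg(kind)
  if (length(models) == 0L) stop("empty model set", call. = FALSE)
  if (length(params) == 0L) stop("empty noise grid", call. = FALSE)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  rows <- list()
  for (mn in names(models)) {
    for (p in params) {
      res <- robustness_eval(models[[mn]], data,
                             noise_spec(kind, p, replicates = replicates,
                                        seed = derive_seed(seed, kind, mn)))
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, kind = kind, param = p,
        accuracy = res$accuracy, silhouette = res$silhouette)
    }
  }
  do.call(rbind, rows)
}

#' Default noise grids for the robustness benchmark
#'
#' Spans gentle to strong regimes on the default synthetic cohort:
#' uniform amplitude ratios 0.05--0.4 and absolute Gaussian sigmas
#' 0.5--4 dB. The top levels push accuracy well below the clean value
#' while staying short of the regime where every model degrades to
#' coin-flipping and comparisons stop being informative.
#'
#' @param kind Noise family.
#' @return Numeric vector of magnitudes.
#' @export
default_noise_grid <- function(kind = c("uniform", "gaussian")) {
  switch(match.arg(kind),
         uniform = c(0.05, 0.1, 0.2, 0.4),
         gaussian = c(0.5, 1, 2, 4))
}

#' Transfer decline between two systems' scores
#'
#' Relative drop `100 * (score1 - score2) / score1` in percent when the
#' same modelling procedure is trained and evaluated on a second
#' acquisition system.
#'
#' @param score1,score2 Scores on systems 1 and 2; `score1 > 0`.
#' @param digits Rounding for reporting (1 decimal, as conventionally
#'   printed); use `NULL` for the raw value.
#' @return Percent decline.
#' @export
#' @examples
#' transfer_decline(0.826, 0.696)  # 15.7
transfer_decline <- function(score1, score2, digits = 1L) {
  if (score1 <= 0) stop("score1 must be positive", call. = FALSE)
  d <- 100 * (score1 - score2) / score1
  if (is.null(digits)) d else round(d, digits)
}
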