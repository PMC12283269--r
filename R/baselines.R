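#' Single-feature threshold classifier
#'
#' The conventional signal-processing baseline: a scalar decision rule on
#' one linear-fit feature (slope or median) at one wavelength. The
#' threshold is placed at the midpoint maximising Youden's J
#' (sensitivity + specificity - 1) on the training data, and the
#' orientation (greater-is-tumour vs lesser-is-tumour) is learned from the
#' data.
#'
#' @param values Numeric training feature values.
#' @param labels Integer 0/1 training labels (both classes required).
#' @param wavelength,feature Optional metadata recorded on the fit.
#' @return A `pa_threshold`: threshold, orientation (+1 means
#'   greater-is-tumour), training Youden's J.
#' @export
threshold_classifier <- function(values, labels, wavelength = NA,
                                 feature = NA_character_) {
  stopifnot(length(values) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in training features", call. = FALSE)
  }
  if (length(unique(values)) < 2L) {
    stop("degenerate single-valued feature", call. = FALSE)
  }
  v <- sort(unique(values))
  cands <- (v[-1] + v[-length(v)]) / 2
  cands <- c(v[1] - 1, cands, v[length(v)] + 1)
  best <- list(j = -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  for (thr in cands) {
    for (orient in c(1, -1)) {
      pred <- as.integer(orient * values > orient * thr)
      j <- sum(pred == 1 & labels == 1) / n1 + sum(pred == 0 & labels == 0) / n0 - 1
      if (j > best$j) best <- list(j = j, threshold = thr, orientation = orient)
    }
  }
  structure(list(threshold = best$threshold, orientation = best$orientation,
                 youden_j = best$j, wavelength = wavelength, feature = feature),
            class = "pa_threshold")
}

#' @rdname threshold_classifier
#' @param object A `pa_threshold`.
#' @param values New feature values.
#' @param ... Unused.
#' @export
predict.pa_threshold <- function(object, values, ...) {
  as.integer(object$orientation * values > object$orientation * object$threshold)
}

# Shrunk covariance: (1 - gamma) * S + gamma * mean(diag(S)) * I. Keeps the
# discriminants well defined when features outnumber samples.
shrink_cov <- function(S, gamma) {
  (1 - gamma) * S + gamma * mean(diag(S)) * diag(nrow(S))
}

#' Gaussian discriminant baselines with shrinkage covariance
#'
#' Linear (pooled covariance) and quadratic (per-class covariance)
#' Gaussian class-conditional discriminants. Covariances are shrunk toward
#' a scaled identity, `(1 - gamma) S + gamma tr(S)/p I`, so the fits remain
#' defined when features outnumber samples (154 slope+median features, or
#' the full 6930-bin representation, against a few dozen training points).
#' Predictions expose a continuous discriminant score usable for AUC.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Integer 0/1 labels; each class needs at least 2 samples.
#' @param gamma Shrinkage intensity in `(0, 1]` (default 0.2).
#' @return A `pa_lda` / `pa_qda` fit.
#' @export
lda_fit <- function(X, y, gamma = 0.2) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), gamma > 0, gamma <= 1)
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples", call. = FALSE)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  S <- ((n0 - 1) * stats::cov(X[y == 0, , drop = FALSE]) +
        (n1 - 1) * stats::cov(X[y == 1, , drop = FALSE])) / (n0 + n1 - 2)
  Sc <- shrink_cov(S, gamma)
  w <- solve(Sc, mu1 - mu0)
  # threshold from equal-prior Gaussian discriminant; priors from data
  b <- -0.5 * sum(w * (mu1 + mu0)) + log(n1 / n0)
  structure(list(w = w, b = b, mu0 = mu0, mu1 = mu1, gamma = gamma),
            class = "pa_lda")
}

#' @rdname lda_fit
#' @param object A fitted discriminant.
#' @param X New data matrix.
#' @param ... Unused.
#' @export
predict.pa_lda <- function(object, X, ...) {
  X <- as.matrix(X)
  s <- as.numeric(X %*% object$w) + object$b
  data.frame(pred = as.integer(s > 0), score = s)
}

#' @rdname lda_fit
#' @export
qda_fit <- function(X, y, gamma = 0.2) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), gamma > 0, gamma <= 1)
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples", call. = FALSE)
  fit_class <- function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    Sc <- shrink_cov(stats::cov(Xi), gamma)
    ch <- chol(Sc)
    list(mu = colMeans(Xi), chol = ch,
         logdet = 2 * sum(log(diag(ch))), prior = log(nrow(Xi) / nrow(X)))
  }
  structure(list(c0 = fit_class(0L), c1 = fit_class(1L), gamma = gamma),
            class = "pa_qda")
}

#' @rdname lda_fit
#' @export
predict.pa_qda <- function(object, X, ...) {
  X <- as.matrix(X)
  logp <- function(cl) {
    d <- sweep(X, 2L, cl$mu)
    z <- backsolve(cl$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$prior
  }
  s <- logp(object$c1) - logp(object$c0)
  data.frame(pred = as.integer(s > 0), score = s)
}

#' Validation-driven single-feature screening
#'
#' Scores every (wavelength, frequency-bin) scalar of the 77x90 spectrum
#' by the validation accuracy of a one-dimensional linear discriminant
#' (class-mean midpoint threshold) fit on the training data, and retains
#' the top `k`. The result is exportable as a 77x90 mask for overlay on
#' the mean spectrum.
#'
#' @param train_x,train_y Training spectra (`N x 77 x 90`) and labels.
#' @param val_x,val_y Validation spectra and labels.
#' @param k Number of features to keep (default 20; at most 6930).
#' @return A `pa_screen`: data.frame `selected` (wavelength_idx, freq_idx,
#'   val_accuracy) and the logical 77x90 `mask`.
#' @export
lda_feature_screen <- function(train_x, train_y, val_x, val_y, k = 20L) {
  if (k > 77L * 90L) stop("k exceeds the 6930 available features", call. = FALSE)
  if (length(val_y) == 0L) stop("validation set is empty", call. = FALSE)
  n_tr <- dim(train_x)[1]
  tr <- matrix(train_x, nrow = n_tr)              # n x 6930, wavelength-fastest
  va <- matrix(val_x, nrow = dim(val_x)[1])
  mu0 <- colMeans(tr[train_y == 0, , drop = FALSE])
  mu1 <- colMeans(tr[train_y == 1, , drop = FALSE])
  thr <- (mu0 + mu1) / 2
  orient <- sign(mu1 - mu0)
  pred <- sweep(sweep(va, 2L, thr), 2L, orient, `*`) > 0
  acc <- colMeans(pred == matrix(val_y == 1, nrow(va), ncol(va)))
  ord <- order(acc, decreasing = TRUE)[seq_len(k)]
  # column index c of the n x 6930 matrix maps back to (wl, fr) of 77 x 90
  wl_idx <- ((ord - 1L) %% 77L) + 1L
  fr_idx <- ((ord - 1L) %/% 77L) + 1L
  mask <- matrix(FALSE, 77L, 90L)
  mask[cbind(wl_idx, fr_idx)] <- TRUE
  structure(list(
    selected = data.frame(wavelength_idx = wl_idx, freq_idx = fr_idx,
                          wavelength = pa_wavelength_grid()[wl_idx],
                          freq = pa_frequency_grid()[fr_idx],
                          val_accuracy = acc[ord]),
    mask = mask, k = k), class = "pa_screen")
}

#' Fit and evaluate all classical baselines on a split cohort
#'
#' Runs the six single-feature thresholds (slope and median at 700, 1210
#' and 1370 nm), shrinkage LDA on the full per-wavelength slope+median
#' feature table (154 features), and shrinkage QDA on the twelve
#' characteristic-wavelength features (slope and median at the three
#' bands) -- per-class covariances of 154 features are not estimable from
#' a few dozen samples, so the quadratic rule gets the low-dimensional
#' characteristic set. Training uses the train split; the five-metric set
#' is reported on the test split.
#'
#' @param splits List of `pa_cohort`s with `train` and `test` (from
#'   [split_cohort()]).
#' @param wavelengths Wavelengths for the threshold baselines.
#' @param gamma Shrinkage for LDA/QDA.
#' @return Data frame: method, and the five metrics plus score.
#' @export
baseline_suite <- function(splits, wavelengths = c(700, 1210, 1370),
                           gamma = 0.2) {
  fm_tr <- feature_matrix(splits$train)
  fm_te <- feature_matrix(splits$test)
  y_tr <- fm_tr$meta$label; y_te <- fm_te$meta$label
  rows <- list()
  addrow <- function(name, ms) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = name, accuracy = ms$accuracy, precision = ms$precision,
      recall = ms$recall, specificity = ms$specificity, auc = ms$auc,
      score = ms$score)
  }
  for (w in wavelengths) {
    for (feat in c("slope", "median")) {
      col <- sprintf("%s_%d", feat, w)
      fit <- threshold_classifier(fm_tr$X[, col], y_tr, wavelength = w,
                                  feature = feat)
      pred <- predict(fit, fm_te$X[, col])
      sc <- fit$orientation * fm_te$X[, col]
      addrow(sprintf("%s@%d", feat, w), metric_set(y_te, pred, sc))
    }
  }
  l <- lda_fit(fm_tr$X, y_tr, gamma = gamma)
  pl <- predict(l, fm_te$X)
  addrow("lda", metric_set(y_te, pl$pred, pl$score))
  qcols <- as.vector(outer(c("slope_", "median_"), wavelengths, paste0))
  q <- qda_fit(fm_tr$X[, qcols], y_tr, gamma = gamma)
  pq <- predict(q, fm_te$X[, qcols])
  addrow("qda", metric_set(y_te, pq$pred, pq$score))
  do.call(rbind, rows)
}
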