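#' Confusion counts from labels and predictions
#'
#' @param truth,pred Integer 0/1 vectors (1 = tumour = positive class).
#' @return A `pa_confusion`: list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 TN = sum(truth == 0 & pred == 0),
                 FP = sum(truth == 0 & pred == 1),
                 FN = sum(truth == 1 & pred == 0)),
            class = "pa_confusion")
}

#' Threshold classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A zero denominator yields 0
#' for that metric with a `degenerate` flag, matching the reporting
#' convention for classifiers that never predict a class.
#'
#' @param counts A [confusion_counts()] or list with `TP`, `TN`, `FP`, `FN`.
#' @return List with the four metrics and `degenerate` (character vector of
#'   metrics that hit a zero denominator).
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be nonnegative", call. = FALSE)
    degen <- character(0)
    safe <- function(num, den, name) {
      if (den == 0) { degen <<- c(degen, name); 0 } else num / den
    }
    list(accuracy = safe(TP + TN, TP + TN + FP + FN, "accuracy"),
         precision = safe(TP, TP + FP, "precision"),
         recall = safe(TP, TP + FN, "recall"),
         specificity = safe(TN, TN + FP, "specificity"),
         degenerate = degen)
  })
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the fraction of positive--negative
#' score pairs ranked correctly, with ties credited 0.5 (via midranks).
#' `strict = TRUE` counts only strictly ordered pairs, the formula as
#' printed.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Integer 0/1 labels.
#' @param strict Drop the 0.5 tie credit.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels, strict = FALSE) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop("AUC requires at least one positive and one negative", call. = FALSE)
  }
  if (strict) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    return(sum(outer(pos, neg, ">")) / (P * N))
  }
  r <- rank(scores)  # midranks credit ties 0.5
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Five-metric set and their mean score
#'
#' Combines the four confusion metrics with AUC; `score` is the arithmetic
#' mean of the five and is the model-comparison index used throughout.
#'
#' @param truth,pred Integer 0/1 vectors.
#' @param scores Positive-class scores for the AUC (if omitted, `pred` is
#'   used, which degrades AUC to a balanced accuracy).
#' @return A `pa_metric_set`: accuracy, precision, recall, specificity,
#'   auc, score, degenerate.
#' @export
metric_set <- function(truth, pred, scores = NULL) {
  cm <- classification_metrics(confusion_counts(truth, pred))
  auc <- auc_rank(scores %||% pred, truth)
  out <- list(accuracy = cm$accuracy, precision = cm$precision,
              recall = cm$recall, specificity = cm$specificity, auc = auc)
  out$score <- score(out)
  out$degenerate <- cm$degenerate
  structure(out, class = "pa_metric_set")
}

#' Mean of the five evaluation metrics
#'
#' @param metrics List (or `pa_metric_set`) containing `accuracy`,
#'   `precision`, `recall`, `specificity`, `auc`.
#' @return Scalar mean.
#' @export
#' @examples
#' score(list(accuracy = 0.71, precision = 0.86, recall = 0.54,
#'            specificity = 0.88, auc = 0.90))  # 0.778
score <- function(metrics) {
  need <- c("accuracy", "precision", "recall", "specificity", "auc")
  missing <- setdiff(need, names(metrics))
  if (length(missing)) {
    stop(paste0("missing metric(s): ", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  mean(unlist(metrics[need]))
}

#' Evaluate a trained model on a cohort
#'
#' @param model Trained `pa_model`.
#' @param data `pa_cohort` or `list(x, y)`.
#' @return List with `metrics` (a `pa_metric_set`), `pred` (prediction data
#'   frame) and `truth`.
#' @export
evaluate_model <- function(model, data) {
  xy <- as_xy(data)
  pr <- predict(model, xy$x)
  list(metrics = metric_set(xy$y, pr$pred, pr$score), pred = pr, truth = xy$y)
}

#' Subsampled evaluation protocol
#'
#' Systematically subsamples the test set at fractions 10% to 100%; at each
#' fraction draws `reps` random (stratified where possible) subsets,
#' evaluates the five metrics on each, and averages. The per-repetition
#' values are kept for the paired statistical comparison of models.
#'
#' @param model Trained `pa_model`.
#' @param data Test `pa_cohort` or `list(x, y)`.
#' @param fractions Subsampling fractions (default `seq(0.1, 1, 0.1)`).
#' @param reps Repetitions per fraction (default 10).
#' @param seed Integer seed.
#' @return List with `summary` (data.frame, one row per fraction with mean
#'   metrics) and `raw` (one row per fraction x repetition).
#' @export
subsample_evaluate <- function(model, data, fractions = seq(0.1, 1, by = 0.1),
                               reps = 10L, seed = 42L) {
  xy <- as_xy(data)
  n <- length(xy$y)
  stopifnot(n >= 2L)
  pr <- predict(model, xy$x)  # predictions are deterministic; subsample rows
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (r in seq_len(reps)) {
      idx <- with_seed(derive_seed(seed, "subsample", fi, r), {
        k <- max(1L, round(f * n))
        if (k >= n) seq_len(n) else {
          # stratified draw where both classes allow it
          i1 <- which(xy$y == 1); i0 <- which(xy$y == 0)
          k1 <- round(k * length(i1) / n); k0 <- k - k1
          if (k1 >= 1 && k0 >= 1 && k1 <= length(i1) && k0 <= length(i0)) {
            c(sample(i1, k1), sample(i0, k0))
          } else sample.int(n, k)
        }
      })
      truth <- xy$y[idx]
      flag <- length(unique(truth)) < 2L
      cm <- classification_metrics(confusion_counts(truth, pr$pred[idx]))
      auc <- if (flag) NA_real_ else auc_rank(pr$score[idx], truth)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, rep = r, n = length(idx),
        accuracy = cm$accuracy, precision = cm$precision, recall = cm$recall,
        specificity = cm$specificity, auc = auc,
        score = if (flag) NA_real_ else
          mean(c(cm$accuracy, cm$precision, cm$recall, cm$specificity, auc)),
        single_class = flag)
    }
  }
  raw <- do.call(rbind, rows)
  summary <- stats::aggregate(
    raw[, c("accuracy", "precision", "recall", "specificity", "auc", "score")],
    by = list(fraction = raw$fraction), FUN = mean, na.rm = TRUE)
  list(summary = summary, raw = raw)
}

#' Compare two models' per-repetition metrics
#'
#' Two-sided t-test on paired or independent per-repetition metric vectors.
#' The unpaired variant is Welch's unequal-variance test; `paired = TRUE`
#' is appropriate when both vectors share the same subsample draws.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param paired Use the paired test.
#' @return List with `statistic`, `p_value`, `estimate`.
#' @export
compare_models <- function(values_a, values_b, paired = FALSE) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0 && !paired) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0,
                estimate = mean(values_a) - mean(values_b)))
  }
  tt <- stats::t.test(values_a, values_b, paired = paired, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       estimate = mean(values_a) - mean(values_b))
}

#' Mean silhouette of a labelled embedding
#'
#' Standard silhouette with Euclidean distance:
#' \eqn{s_i = (b_i - a_i) / \max(a_i, b_i)} with \eqn{a_i} the mean
#' intra-cluster and \eqn{b_i} the mean nearest-other-cluster distance;
#' singleton clusters contribute 0, as do points where both distances are 0.
#'
#' @param points Numeric matrix, one row per point (typically the 2-d head
#'   outputs).
#' @param labels Cluster labels (>= 2 distinct values).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  stopifnot(nrow(points) == length(labels))
  d <- stats::dist(points)
  if (all(d == 0)) return(0)
  sil <- cluster::silhouette(labels, d)
  widths <- sil[, "sil_width"]
  widths[is.nan(widths)] <- 0
  mean(widths)
}

#' Scatter plot of 2-d head outputs with the decision boundary
#'
#' The two head outputs are the axes; the predicted label is the larger of
#' the two, so the line `y = x` is the decision boundary.
#'
#' @param points N x 2 matrix of head outputs.
#' @param labels Integer 0/1 labels for colouring.
#' @param file Output path (`.png` or `.svg`).
#' @param decision_boundary Draw the `y = x` line.
#' @return The file path, invisibly.
#' @export
export_embedding_plot <- function(points, labels, file,
                                  decision_boundary = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("no points to plot", call. = FALSE)
  if (ncol(points) != 2L) stop("points must be 2-dimensional", call. = FALSE)
  df <- data.frame(x = points[, 1], y = points[, 2],
                   label = factor(labels, levels = c(0, 1),
                                  labels = c("normal", "tumour")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "head output 0", y = "head output 1", colour = NULL) +
    ggplot2::theme_minimal()
  if (decision_boundary) {
    p <- p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed")
  }
  ggplot2::ggsave(file, p, width = 5, height = 4, dpi = 150)
  invisible(file)
}
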