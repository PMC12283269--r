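# Shared fixtures: everything is generated in code at test time.

# A small two-system cohort spec for fast end-to-end tests.
tiny_spec <- function(seed = 7L, ...) {
  cohort_spec(n_patients_per_system = c(6L, 5L), points_per_patient = c(3L, 5L),
              seed = seed, ...)
}

# A quick training config (few epochs) for mechanics-only tests.
quick_cfg <- function(kind = "cnn", epochs = 3L, seed = 42L) {
  cfg <- default_train_config(kind, seed = seed)
  cfg$epochs <- as.integer(epochs)
  cfg
}

# Brute-force supervised contrastive loss, a literal triple loop over the
# printed formula. Z: rows are embeddings.
scl_brute_force <- function(Z, y, t) {
  M <- nrow(Z)
  cosine <- function(i, j) {
    sum(Z[i, ] * Z[j, ]) / sqrt(sum(Z[i, ]^2) * sum(Z[j, ]^2))
  }
  total <- 0
  for (i in seq_len(M)) {
    M_yi <- sum(y == y[i])
    if (M_yi < 2) next
    for (j in seq_len(M)) {
      if (j == i || y[j] != y[i]) next
      num <- exp(cosine(i, j) / t)
      den <- num
      for (k in seq_len(M)) {
        if (y[k] != y[i]) den <- den + exp(cosine(i, k) / t)
      }
      total <- total - (1 / (M_yi - 1)) * log(num / den)
    }
  }
  total
}

# Brute-force mean silhouette from the definition.
silhouette_brute_force <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  D <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(D[i, labels == cl])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Trapezoidal ROC-integration AUC oracle.
auc_trapezoid <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(labels == 1); N <- sum(labels == 0)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / P, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / N, numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
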