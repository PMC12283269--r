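#' Architecture plan of the spectrum classifier
#'
#' The layer plan shared by all three model variants: two 2-D convolution
#' layers (64 then 4 kernels, same-padding) each followed by max pooling
#' (2x2 then 3x3, floor division), a 256-unit fully connected encoder
#' output, a small projector used by the contrastive models, and a 2-unit
#' prediction head. With a 77x90 input the feature maps run
#' 64x77x90 -> 64x38x45 -> 4x38x45 -> 4x12x15 -> 256 -> 2 (projector 4).
#' The convolution kernel size is not part of the plan's printed shape
#' sequence; 3x3 is the default and is configurable.
#'
#' @param conv1_kernels,conv2_kernels Kernel counts of the two conv layers.
#' @param pool1,pool2 Pooling factors.
#' @param encoder_out_dim Dimension of the encoder representation `h`.
#' @param projector_dim Dimension of the contrastive projection `z`.
#' @param head_dim Number of classes at the prediction head.
#' @param conv_kernel_size Odd kernel size for both conv layers.
#' @return A `pa_architecture`.
#' @export
architecture_spec <- function(conv1_kernels = 64L, pool1 = 2L,
                              conv2_kernels = 4L, pool2 = 3L,
                              encoder_out_dim = 256L, projector_dim = 4L,
                              head_dim = 2L, conv_kernel_size = 3L) {
  stopifnot(projector_dim >= 1L, conv_kernel_size %% 2L == 1L)
  structure(list(conv1_kernels = as.integer(conv1_kernels),
                 pool1 = as.integer(pool1),
                 conv2_kernels = as.integer(conv2_kernels),
                 pool2 = as.integer(pool2),
                 encoder_out_dim = as.integer(encoder_out_dim),
                 projector_dim = as.integer(projector_dim),
                 head_dim = as.integer(head_dim),
                 conv_kernel_size = as.integer(conv_kernel_size)),
            class = "pa_architecture")
}

# The canonical shape sequence the architecture must reproduce.
validate_architecture <- function(arch) {
  checks <- list(
    c("Conv1", arch$conv1_kernels, 64L),
    c("Max-pooling1", arch$pool1, 2L),
    c("Conv2", arch$conv2_kernels, 4L),
    c("Max-pooling2", arch$pool2, 3L),
    c("Fully-connected", arch$encoder_out_dim, 256L),
    c("Prediction head", arch$head_dim, 2L)
  )
  for (ch in checks) {
    if (as.integer(ch[2]) != as.integer(ch[3])) {
      stop(sprintf("architecture mismatch at layer %s: got %s, expected %s",
                   ch[1], ch[2], ch[3]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Shape sequence of the forward pass
#'
#' @param arch A [architecture_spec()].
#' @return Named list of feature-map dimensions at each stage.
#' @export
model_shapes <- function(arch = architecture_spec()) {
  h1 <- 77L %/% arch$pool1; w1 <- 90L %/% arch$pool1
  h2 <- h1 %/% arch$pool2; w2 <- w1 %/% arch$pool2
  list(input = c(77L, 90L),
       conv1 = c(arch$conv1_kernels, 77L, 90L),
       pool1 = c(arch$conv1_kernels, h1, w1),
       conv2 = c(arch$conv2_kernels, h1, w1),
       pool2 = c(arch$conv2_kernels, h2, w2),
       flatten = arch$conv2_kernels * h2 * w2,
       fc = arch$encoder_out_dim,
       projector = arch$projector_dim,
       head = arch$head_dim)
}

#' Build a classifier model
#'
#' Constructs one of the three variants with seeded uniform fan-in weight
#' initialisation:
#' * `cnn` — encoder + 2-unit head, trained with cross-entropy;
#' * `sc` — encoder + projector for supervised-contrastive representation
#'   learning, plus a head attached for the downstream phase;
#' * `scl_adjust` — architecturally identical to `cnn`, trained with the
#'   combined loss `SCL * ratio + CEL * (1 - ratio)`.
#'
#' `cnn` and `scl_adjust` share identical parameter shapes and, given equal
#' weights, identical forward passes.
#'
#' @param kind One of `"cnn"`, `"sc"`, `"scl_adjust"`.
#' @param arch A [architecture_spec()].
#' @param seed Integer seed for initialisation.
#' @param validate Check the architecture against the canonical plan.
#' @return A `pa_model`.
#' @export
build_model <- function(kind = c("cnn", "sc", "scl_adjust"),
                        arch = architecture_spec(), seed = 42L,
                        validate = TRUE) {
  kind <- match.arg(kind)
  if (validate) validate_architecture(arch)
  ks2 <- arch$conv_kernel_size^2
  flat <- model_shapes(arch)$flatten
  with_seed(derive_seed(seed, "init", kind), {
    l1 <- init_dense(arch$conv1_kernels, 1L * ks2)
    l2 <- init_dense(arch$conv2_kernels, arch$conv1_kernels * ks2)
    l3 <- init_dense(arch$encoder_out_dim, flat)
    lh <- init_dense(arch$head_dim, arch$encoder_out_dim)
    lp <- init_dense(arch$projector_dim, arch$encoder_out_dim)
    params <- list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b,
                   W3 = l3$W, b3 = l3$b, W4 = lh$W, b4 = lh$b)
    if (kind == "sc") {
      params$Wp <- lp$W
      params$bp <- lp$b
    }
    structure(list(kind = kind, arch = arch, params = params, seed = seed,
                   trained = FALSE),
              class = "pa_model")
  })
}

#' Number of trainable parameters
#'
#' Pure function of the architecture. With the default 3x3 kernels the
#' single-phase models have 640 + 2308 + 184576 + 514 = 188038 parameters;
#' the two-stage variant adds the projector.
#'
#' @param model A `pa_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

# Forward pass for a batch. x: array N x 77 x 90 (or 77 x 90 single
# sample). Returns h (256 x B), logits (2 x B) and z (projector, sc only).
model_forward <- function(model, x, keep = FALSE) {
  if (length(dim(x)) == 2L) {
    xm <- matrix(as.vector(x), nrow = 1L)
    B <- 1L
  } else {
    B <- dim(x)[1]
    xm <- matrix(as.vector(aperm(x, c(2L, 3L, 1L))), nrow = 1L)
  }
  if (!is.null(model$norm)) {
    if (isTRUE(model$norm$center)) {
      # per-sample mean removal: global level carries patient/system
      # offsets, not class information
      means <- colMeans(matrix(as.vector(xm), ncol = B))
      xm <- xm - rep(means, each = length(xm) / B)
    } else if (!is.null(model$norm$mean)) {
      xm <- xm - model$norm$mean
    }
    xm <- xm / model$norm$sd
  }
  fw <- encoder_forward(model$params, xm, B, model$arch, keep = keep)
  out <- list(h = fw$h, B = B, fw = if (keep) fw else NULL)
  out$logits <- model$params$W4 %*% fw$h + model$params$b4
  if (!is.null(model$params$Wp)) {
    out$z <- model$params$Wp %*% fw$h + model$params$bp
  }
  out
}

#' Predict labels and class scores for spectrum samples
#'
#' @param object A trained `pa_model`.
#' @param x Array `N x 77 x 90` of dB spectra (or a `pa_cohort`).
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Data frame with `pred` (0/1), `score` (softmax probability of
#'   class 1) and the two head outputs `out0`, `out1`.
#' @export
predict.pa_model <- function(object, x, batch_size = 64L, ...) {
  if (inherits(x, "pa_cohort")) x <- x$spectra
  if (length(dim(x)) == 2L) x <- array(x, dim = c(1L, dim(x)))
  n <- dim(x)[1]
  out <- vector("list", ceiling(n / batch_size))
  for (bi in seq_along(out)) {
    idx <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)
    fw <- model_forward(object, x[idx, , , drop = FALSE])
    lg <- fw$logits
    p1 <- 1 / (1 + exp(lg[1, ] - lg[2, ]))
    out[[bi]] <- data.frame(pred = as.integer(lg[2, ] > lg[1, ]),
                            score = p1, out0 = lg[1, ], out1 = lg[2, ])
  }
  do.call(rbind, out)
}

#' Cosine similarity of two embedding vectors
#'
#' \eqn{s_{ij} = z_i^\top z_j / (\lVert z_i\rVert \lVert z_j\rVert)}.
#'
#' @param z_i,z_j Nonzero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(z_i, z_j) {
  stopifnot(length(z_i) == length(z_j))
  ni <- sqrt(sum(z_i^2)); nj <- sqrt(sum(z_j^2))
  if (ni == 0 || nj == 0) {
    stop("cosine similarity is undefined for zero vectors", call. = FALSE)
  }
  sum(z_i * z_j) / (ni * nj)
}

# Internal: supervised contrastive loss and gradient. Z is d x M (columns
# are embeddings), y a 0/1 label vector, t the temperature. As printed, the
# per-anchor denominator is the pair's own exponential plus the sum over
# different-label samples; `canonical = TRUE` switches to the standard
# formulation whose denominator sums over all other samples. Anchors whose
# label appears only once in the batch are skipped (the 1/(M_yi - 1) weight
# is undefined for them).
scl_loss_grad <- function(Z, y, t, canonical = FALSE, eps = 1e-12) {
  M <- ncol(Z)
  d <- nrow(Z)
  norms <- pmax(sqrt(colSums(Z^2)), eps)
  U <- sweep(Z, 2L, norms, "/")
  S <- crossprod(U)
  E <- exp(S / t)
  same <- outer(y, y, "==")
  diffm <- !same
  posm <- same; diag(posm) <- FALSE
  m_y <- vapply(seq_len(M), function(i) sum(y == y[i]), numeric(1))
  wts <- ifelse(m_y > 1, 1 / (m_y - 1), 0)
  negsum <- rowSums(E * diffm)
  if (canonical) {
    othersum <- rowSums(E) - diag(E)
    denom <- matrix(othersum, M, M)
  } else {
    denom <- E + negsum  # recycles negsum down columns: denom[i,j] = E[i,j] + negsum[i]
  }
  terms <- (S / t - log(denom)) * posm
  loss <- -sum(wts * rowSums(terms))

  # dL/dS as if entries were independent; symmetrised through U afterwards
  if (canonical) {
    npos <- rowSums(posm)
    offdiag <- matrix(TRUE, M, M); diag(offdiag) <- FALSE
    G <- -(wts / t) * posm + (wts * npos / t) * (E / denom) * offdiag
  } else {
    R <- rowSums(posm / denom)
    G <- -(wts / t) * posm * (1 - E / denom)
    G <- G + (wts / t) * diffm * E * R
  }
  dU <- U %*% (G + t(G))
  dots <- colSums(U * dU)
  dZ <- sweep(dU - sweep(U, 2L, dots, "*"), 2L, norms, "/")
  list(loss = loss, dZ = dZ)
}

#' Supervised contrastive loss of an embedding batch
#'
#' Temperature-scaled contrastive loss over a labelled batch of embeddings:
#' each anchor is pulled toward same-label partners and pushed from
#' different-label samples via cosine similarities. As printed, the
#' denominator of the inner fraction contains the positive pair's own
#' exponential plus the different-label exponentials; `canonical = TRUE`
#' instead uses all other samples in the denominator (the standard
#' supervised-contrastive formulation). Anchors with no same-label partner
#' in the batch contribute zero.
#'
#' @param Z Numeric matrix, one embedding per row (M x d).
#' @param y Integer 0/1 labels, length M.
#' @param t Positive temperature (default 0.5).
#' @param canonical Use the all-others denominator variant.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' Z <- matrix(1, 4, 4)  # identical embeddings, two per class
#' scl_loss(Z, c(0, 0, 1, 1))  # -4 * log(1/3)
scl_loss <- function(Z, y, t = 0.5, canonical = FALSE) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) stop("batch must contain at least 2 samples", call. = FALSE)
  stopifnot(length(y) == nrow(Z), t > 0)
  scl_loss_grad(t(Z), as.integer(y), t, canonical = canonical)$loss
}

# Internal: mean softmax cross-entropy and gradient. logits 2 x B.
ce_loss_grad <- function(logits, y) {
  B <- ncol(logits)
  m <- pmax(logits[1, ], logits[2, ])
  lse <- m + log(exp(logits[1, ] - m) + exp(logits[2, ] - m))
  picked <- ifelse(y == 1L, logits[2, ], logits[1, ])
  loss <- mean(lse - picked)
  p <- rbind(exp(logits[1, ] - lse), exp(logits[2, ] - lse))
  onehot <- rbind(1 - y, y)
  list(loss = loss, dlogits = (p - onehot) / B)
}

#' Softmax cross-entropy loss
#'
#' Mean negative log-likelihood of the true labels under the softmax of
#' 2-dimensional logits.
#'
#' @param logits Numeric matrix, one row per sample (M x 2), or a length-2
#'   vector for a single sample.
#' @param y Integer 0/1 labels.
#' @return Nonnegative scalar.
#' @export
cross_entropy_loss <- function(logits, y) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  stopifnot(ncol(logits) == 2L, length(y) == nrow(logits))
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1", call. = FALSE)
  ce_loss_grad(t(logits), as.integer(y))$loss
}

#' Combined supervised-contrastive plus cross-entropy loss
#'
#' `SCL * ratio + CEL * (1 - ratio)`; `ratio = 0` is pure cross-entropy,
#' `ratio = 1` pure contrastive loss.
#'
#' @param logits M x 2 logits matrix.
#' @param Z M x d embedding matrix the contrastive term acts on.
#' @param y Integer 0/1 labels.
#' @param ratio Weight in `[0, 1]` (default 0.7).
#' @param t Temperature (default 0.5).
#' @param canonical Passed to [scl_loss()].
#' @return Scalar loss.
#' @export
combined_loss <- function(logits, Z, y, ratio = 0.7, t = 0.5,
                          canonical = FALSE) {
  if (ratio < 0 || ratio > 1) stop("ratio must lie in [0, 1]", call. = FALSE)
  scl <- if (ratio > 0) scl_loss(Z, y, t = t, canonical = canonical) else 0
  cel <- if (ratio < 1) cross_entropy_loss(logits, y) else 0
  ratio * scl + (1 - ratio) * cel
}
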