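# CNN engine. The conv/pool hot path lives in src/conv_ops.cpp; the *_ref
# functions below are slow pure-R references used as oracles in the tests.
#
# Activation layout: a feature map with C channels over an H x W grid for a
# batch of B samples is a C x (H*W*B) matrix. Column index = (b-1)*H*W + p
# with p = (j-1)*H + i (column-major within the map), which matches R's
# array layout so flattening is a dim<- away. Convolutions use same-padding;
# pooling is max with floor division of the grid (77 -> 38, 90 -> 45 under
# 2x2; 38 -> 12, 45 -> 15 under 3x3).

conv_forward <- function(x, Wk, b, C, H, W, B, k = 3L, relu_out = FALSE) {
  .conv_fwd_cpp(x, Wk, b, C, H, W, B, k, relu_out)
}

conv_backward <- function(x, Wk, dY, C, H, W, B, k = 3L, need_dx = TRUE) {
  .conv_bwd_cpp(x, Wk, dY, C, H, W, B, k, need_dx)
}

pool_forward <- function(x, C, H, W, B, k) {
  .maxpool_fwd_cpp(x, C, H, W, B, k)
}

pool_backward <- function(dY, arg, C, H, W, B, k) {
  .maxpool_bwd_cpp(dY, arg, C, H, W, B, k)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- pure-R reference implementations (test oracles) ----

conv_forward_ref <- function(x, Wk, b, C, H, W, B, k = 3L) {
  pad <- (k - 1L) %/% 2L
  HW <- H * W
  y <- matrix(0, nrow(Wk), HW * B)
  for (bb in seq_len(B)) {
    xa <- array(x[, (bb - 1L) * HW + seq_len(HW), drop = FALSE], c(C, H, W))
    xp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
    xp[, pad + seq_len(H), pad + seq_len(W)] <- xa
    for (j in seq_len(W)) {
      for (i in seq_len(H)) {
        patch <- as.vector(xp[, i:(i + k - 1L), j:(j + k - 1L), drop = FALSE])
        # column order must match im2col: offset-major blocks of C channels
        patch <- as.vector(array(patch, c(C, k, k)))
        y[, (bb - 1L) * HW + (j - 1L) * H + i] <- Wk %*% patch + b
      }
    }
  }
  y
}

pool_forward_ref <- function(x, C, H, W, B, k) {
  Ho <- H %/% k; Wo <- W %/% k
  y <- matrix(0, C, Ho * Wo * B)
  for (bb in seq_len(B)) {
    xa <- array(x[, (bb - 1L) * H * W + seq_len(H * W), drop = FALSE], c(C, H, W))
    for (jo in seq_len(Wo)) {
      for (io in seq_len(Ho)) {
        block <- xa[, (io - 1L) * k + seq_len(k), (jo - 1L) * k + seq_len(k),
                    drop = FALSE]
        y[, (bb - 1L) * Ho * Wo + (jo - 1L) * Ho + io] <-
          apply(array(block, c(C, k * k)), 1L, max)
      }
    }
  }
  y
}

# ---- shared layers ----

# Rectifier-scaled uniform fan-in initialisation (bound sqrt(6/fan_in))
# for weights; biases on the conservative 1/sqrt(fan_in) scale.
init_dense <- function(n_out, fan_in) {
  lim <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(n_out * fan_in, -lim, lim), n_out, fan_in),
       b = stats::runif(n_out, -1 / sqrt(fan_in), 1 / sqrt(fan_in)))
}

# Forward pass of the shared encoder. xmat: 1 x (77*90*B) standardised
# input. Returns the 256-d representation h and, when keep = TRUE, the
# caches needed for backprop. The rectifier is fused into the conv kernels;
# post-activation maps double as the backward masks (y > 0).
encoder_forward <- function(params, xmat, B, arch, keep = FALSE) {
  k <- arch$conv_kernel_size
  r1 <- conv_forward(xmat, params$W1, params$b1, 1L, 77L, 90L, B, k, relu_out = TRUE)
  p1 <- pool_forward(r1, arch$conv1_kernels, 77L, 90L, B, arch$pool1)
  r2 <- conv_forward(p1$y, params$W2, params$b2, arch$conv1_kernels, 38L, 45L, B, k,
                     relu_out = TRUE)
  p2 <- pool_forward(r2, arch$conv2_kernels, 38L, 45L, B, arch$pool2)
  flat <- p2$y
  dim(flat) <- c(arch$conv2_kernels * 12L * 15L, B)
  hpre <- params$W3 %*% flat + params$b3
  h <- relu(hpre)
  if (!keep) return(list(h = h))
  list(h = h, hpre = hpre,
       cache = list(x = xmat, r1 = r1, arg1 = p1$arg, p1y = p1$y,
                    r2 = r2, arg2 = p2$arg, flat = flat))
}

# Backward pass of the encoder given dL/dh (and optionally a gradient
# injected directly at the pre-activation of the 256-unit layer, used by
# the combined loss whose contrastive term acts there). Returns parameter
# gradients.
encoder_backward <- function(params, dh, fw, B, arch, dhpre_extra = NULL) {
  k <- arch$conv_kernel_size
  ca <- fw$cache
  dhpre <- dh * (fw$h > 0)
  if (!is.null(dhpre_extra)) dhpre <- dhpre + dhpre_extra
  dW3 <- tcrossprod(dhpre, ca$flat)
  db3 <- rowSums(dhpre)
  dflat <- crossprod(params$W3, dhpre)
  dim(dflat) <- c(arch$conv2_kernels, 12L * 15L * B)
  dr2 <- pool_backward(dflat, ca$arg2, arch$conv2_kernels, 38L, 45L, B, arch$pool2)
  dc2 <- .relu_bwd_cpp(dr2, ca$r2)
  bw2 <- conv_backward(ca$p1y, params$W2, dc2, arch$conv1_kernels, 38L, 45L, B, k,
                       need_dx = TRUE)
  dr1 <- pool_backward(bw2$dx, ca$arg1, arch$conv1_kernels, 77L, 90L, B, arch$pool1)
  dc1 <- .relu_bwd_cpp(dr1, ca$r1)
  bw1 <- conv_backward(ca$x, params$W1, dc1, 1L, 77L, 90L, B, k, need_dx = FALSE)
  list(W1 = bw1$dW, b1 = as.numeric(bw1$db), W2 = bw2$dW, b2 = as.numeric(bw2$db),
       W3 = dW3, b3 = db3)
}

# One SGD-with-momentum update (v <- mom v + g; p <- p - lr v).
sgd_update <- function(params, grads, state, lr, momentum) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    v <- state[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, state = state)
}
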