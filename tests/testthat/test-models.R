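test_that("forward pass reproduces the printed layer-shape sequence", {
  m <- build_model("cnn", seed = 1)
  sh <- model_shapes(m$arch)
  expect_equal(sh$conv1, c(64L, 77L, 90L))
  expect_equal(sh$pool1, c(64L, 38L, 45L))
  expect_equal(sh$conv2, c(4L, 38L, 45L))
  expect_equal(sh$pool2, c(4L, 12L, 15L))
  expect_equal(sh$flatten, 720L)
  expect_equal(sh$fc, 256L)
  expect_equal(sh$head, 2L)
  expect_equal(sh$projector, 4L)

  # actual tensors, not just the plan
  x <- array(rnorm(3 * 77 * 90), c(3, 77, 90))
  fw <- pascl:::model_forward(m, x, keep = TRUE)
  expect_equal(dim(fw$fw$cache$r1), c(64L, 77L * 90L * 3L))
  expect_equal(dim(fw$fw$cache$p1y), c(64L, 38L * 45L * 3L))
  expect_equal(dim(fw$fw$cache$r2), c(4L, 38L * 45L * 3L))
  expect_equal(dim(fw$fw$cache$flat), c(720L, 3L))
  expect_equal(dim(fw$h), c(256L, 3L))
  expect_equal(dim(fw$logits), c(2L, 3L))
  msc <- build_model("sc", seed = 1)
  expect_equal(dim(pascl:::model_forward(msc, x)$z), c(4L, 3L))
})

test_that("architecture violations are rejected naming the first bad layer", {
  bad <- architecture_spec(conv1_kernels = 32L)
  expect_error(build_model("cnn", arch = bad), "Conv1")
  bad2 <- architecture_spec(encoder_out_dim = 128L)
  expect_error(build_model("cnn", arch = bad2), "Fully-connected")
})

test_that("parameter count is the closed-form layer arithmetic", {
  m <- build_model("cnn", seed = 1)
  # conv1 64*(9+1) + conv2 4*(576+1) + fc 256*(720+1) + head 2*(256+1)
  expect_identical(n_parameters(m), 640 + 2308 + 184576 + 514)
  expect_identical(n_parameters(m), 188038)
  msc <- build_model("sc", seed = 1)
  expect_identical(n_parameters(msc), 188038 + 4 * 257)
})

test_that("cnn and scl_adjust share shapes and forward passes exactly", {
  a <- build_model("cnn", seed = 3)
  b <- build_model("scl_adjust", seed = 4)
  expect_identical(lapply(a$params, dim), lapply(b$params, dim))
  b$params <- a$params
  x <- array(rnorm(2 * 77 * 90), c(2, 77, 90))
  fa <- pascl:::model_forward(a, x)
  fb <- pascl:::model_forward(b, x)
  expect_identical(fa$logits, fb$logits)
})

test_that("compiled conv/pool kernels agree with the pure-R references", {
  set.seed(11)
  x <- matrix(rnorm(2 * 77 * 90), nrow = 1)
  W1 <- matrix(rnorm(64 * 9), 64, 9); b1 <- rnorm(64)
  yc <- pascl:::conv_forward(x, W1, b1, 1L, 77L, 90L, 2L)
  expect_equal(yc, pascl:::conv_forward_ref(x, W1, b1, 1L, 77L, 90L, 2L),
               tolerance = 1e-12)
  # multi-channel layer on a smaller grid
  x2 <- matrix(rnorm(5 * 6 * 8 * 3), nrow = 5)
  W2 <- matrix(rnorm(4 * 45), 4, 45); b2 <- rnorm(4)
  expect_equal(pascl:::conv_forward(x2, W2, b2, 5L, 6L, 8L, 3L),
               pascl:::conv_forward_ref(x2, W2, b2, 5L, 6L, 8L, 3L),
               tolerance = 1e-12)
  p <- pascl:::pool_forward(yc, 64L, 77L, 90L, 2L, 2L)
  expect_equal(p$y, pascl:::pool_forward_ref(yc, 64L, 77L, 90L, 2L, 2L))
})

test_that("backpropagation matches finite differences", {
  m <- build_model("cnn", seed = 5)
  x <- array(rnorm(2 * 77 * 90), c(2, 77, 90))
  y <- c(0L, 1L)
  fw <- pascl:::model_forward(m, x, keep = TRUE)
  ce <- pascl:::ce_loss_grad(fw$logits, y)
  dh <- crossprod(m$params$W4, ce$dlogits)
  g <- pascl:::encoder_backward(m$params, dh, fw$fw, 2L, m$arch)
  loss_of <- function(p) {
    mm <- m; mm$params <- p
    pascl:::ce_loss_grad(pascl:::model_forward(mm, x)$logits, y)$loss
  }
  set.seed(6)
  for (nm in c("W1", "b1", "W2", "W3", "b3")) {
    idx <- sample(length(m$params[[nm]]), min(4L, length(m$params[[nm]])))
    for (i in idx) {
      p2 <- m$params
      p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      expect_equal((loss_of(p2) - ce$loss) / 1e-6, g[[nm]][i],
                   tolerance = 1e-3)
    }
  }
})

test_that("cosine similarity follows the definition", {
  z <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(z, z), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(1, 0, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(1, 2), c(3, 4)),
               cosine_similarity(c(3, 4), c(1, 2)))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("contrastive loss reproduces hand-derived values and edge cases", {
  # identical embeddings, two per class, t = 0.5: each anchor term
  # ln(e^2 / (e^2 + 2 e^2)) = ln(1/3); loss = -4 ln(1/3)
  Z <- matrix(rep(c(1, 2, 0.5, -1), each = 4), 4, 4)
  expect_equal(scl_loss(Z, c(0, 0, 1, 1), t = 0.5), -4 * log(1 / 3),
               tolerance = 1e-12)
  # one sample per class: both anchors skipped
  expect_equal(scl_loss(matrix(rnorm(8), 2, 4), c(0, 1)), 0)
  # no negatives: inner fraction is 1 for every pair
  expect_equal(scl_loss(matrix(rnorm(12), 3, 4), c(1, 1, 1)), 0,
               tolerance = 1e-12)
  expect_error(scl_loss(matrix(1, 1, 4), 0L), "at least 2")
})

test_that("contrastive loss equals the brute-force triple loop", {
  set.seed(42)
  worst <- 0
  for (rep in 1:200) {
    M <- sample(4:16, 1)
    d <- sample(2:8, 1)
    Z <- matrix(rnorm(M * d), M, d)
    y <- sample(0:1, M, replace = TRUE)
    t <- runif(1, 0.2, 2)
    a <- scl_loss(Z, y, t)
    b <- scl_brute_force(Z, y, t)
    if (b != 0) worst <- max(worst, abs(a - b) / abs(b)) else worst <- max(worst, abs(a - b))
  }
  expect_lt(worst, 1e-6)
})

test_that("contrastive loss is scale- and permutation-invariant", {
  set.seed(9)
  Z <- matrix(rnorm(8 * 4), 8, 4)
  y <- c(0, 0, 0, 1, 1, 1, 0, 1)
  base <- scl_loss(Z, y)
  Z2 <- Z; Z2[3, ] <- 7.5 * Z2[3, ]
  expect_equal(scl_loss(Z2, y), base, tolerance = 1e-10)
  p <- sample(8)
  expect_equal(scl_loss(Z[p, ], y[p]), base, tolerance = 1e-10)
})

test_that("increasing a positive pair's similarity decreases the loss", {
  # anchors 1,2 share a label; moving z2 toward z1 tightens the positive pair
  y <- c(0, 0, 1, 1)
  Zfar <- rbind(c(1, 0), c(0.2, 1), c(-1, 0.3), c(-0.5, -1))
  Znear <- Zfar
  Znear[2, ] <- c(0.9, 0.2)  # nearly aligned with z1
  expect_lt(scl_loss(Znear, y), scl_loss(Zfar, y))
})

test_that("cross-entropy and combined loss follow the printed arithmetic", {
  expect_equal(cross_entropy_loss(c(0, 0), 1L), log(2))
  expect_equal(cross_entropy_loss(c(0, 0), 0L), log(2))
  big <- c(100, -100)
  expect_lt(cross_entropy_loss(big, 0L), 1e-10)
  expect_equal(cross_entropy_loss(rbind(big, c(0, 0)), c(0L, 1L)),
               (0 + log(2)) / 2, tolerance = 1e-10)
  expect_error(cross_entropy_loss(c(0, 0), 2L), "0 or 1")

  Z <- matrix(1, 4, 4); y <- c(0L, 0L, 1L, 1L)
  logits <- matrix(0, 4, 2)
  scl <- scl_loss(Z, y); cel <- cross_entropy_loss(logits, y)
  expect_equal(combined_loss(logits, Z, y, ratio = 0), cel)
  expect_equal(combined_loss(logits, Z, y, ratio = 1), scl)
  expect_equal(combined_loss(logits, Z, y, ratio = 0.7),
               0.7 * scl + 0.3 * cel)
  expect_equal(combined_loss(logits, Z, y, ratio = 0.7),
               0.7 * 4.394449 + 0.3 * 0.6931472, tolerance = 1e-6)
  expect_error(combined_loss(logits, Z, y, ratio = 1.2), "ratio")
})

test_that("contrastive gradient matches finite differences", {
  set.seed(13)
  Z <- matrix(rnorm(20), 4, 5)  # d x M internal layout
  y <- c(0L, 1L, 0L, 1L, 1L)
  g <- pascl:::scl_loss_grad(Z, y, 0.5)
  num <- Z * 0
  for (i in seq_along(Z)) {
    e <- Z; e[i] <- e[i] + 1e-6
    num[i] <- (pascl:::scl_loss_grad(e, y, 0.5)$loss - g$loss) / 1e-6
  }
  expect_equal(num, g$dZ, tolerance = 1e-4)
  gc <- pascl:::scl_loss_grad(Z, y, 0.5, canonical = TRUE)
  numc <- Z * 0
  for (i in seq_along(Z)) {
    e <- Z; e[i] <- e[i] + 1e-6
    numc[i] <- (pascl:::scl_loss_grad(e, y, 0.5, canonical = TRUE)$loss - gc$loss) / 1e-6
  }
  expect_equal(numc, gc$dZ, tolerance = 1e-4)
})
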