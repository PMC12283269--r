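#' Patient-grouped train/validation/test split
#'
#' Splits at the volunteer level so no patient contributes samples to more
#' than one partition: `floor(0.75 * n)` patients are drawn for
#' train+validation, about 20% of those (2 for the twelve-patient design)
#' become the validation patients, and every remaining patient goes to the
#' test set.
#'
#' @param patient_ids Character vector of distinct patient ids.
#' @param seed Integer seed.
#' @param val_patients Number of validation patients; default
#'   `max(1, round(0.2 * n_trainval))`.
#' @return A `pa_split`: list with `train`, `val`, `test` patient-id sets.
#' @export
grouped_split <- function(patient_ids, seed = 42L, val_patients = NULL) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (n < 4L) stop("need at least 4 patients to populate train/val/test", call. = FALSE)
  n_trainval <- floor(0.75 * n)
  n_val <- val_patients %||% max(1L, round(0.2 * n_trainval))
  if (n_trainval - n_val < 1L || n - n_trainval < 1L) {
    stop("too few patients to populate all three splits", call. = FALSE)
  }
  with_seed(derive_seed(seed, "split"), {
    shuffled <- sample(patient_ids)
    trainval <- shuffled[seq_len(n_trainval)]
    val <- trainval[seq_len(n_val)]
    structure(list(train = sort(setdiff(trainval, val)), val = sort(val),
                   test = sort(setdiff(shuffled, trainval))),
              class = "pa_split")
  })
}

#' Split a cohort into train/validation/test cohorts
#'
#' @param cohort A `pa_cohort`.
#' @param split A `pa_split` (default: [grouped_split()] of the cohort's
#'   patients with `seed`).
#' @param seed Seed forwarded to [grouped_split()].
#' @param require_both_classes When drawing the split internally, redraw
#'   (deterministically, bounded attempts) until every partition contains
#'   both classes and the training partition has at least two samples of
#'   each -- a single-class test or validation set leaves the five-metric
#'   score undefined. Ignored when `split` is supplied.
#' @return List of `pa_cohort`s named `train`, `val`, `test`.
#' @export
split_cohort <- function(cohort, split = NULL, seed = 42L,
                         require_both_classes = TRUE) {
  stopifnot(inherits(cohort, "pa_cohort"))
  make <- function(sp) {
    lapply(list(train = sp$train, val = sp$val, test = sp$test),
           function(p) subset_cohort(cohort, cohort$meta$patient_id %in% p))
  }
  if (!is.null(split)) {
    stopifnot(!anyDuplicated(c(split$train, split$val, split$test)))
    return(make(split))
  }
  pts <- unique(cohort$meta$patient_id)
  out <- NULL
  for (attempt in 0:49) {
    sp <- grouped_split(pts, seed = derive_seed(seed, "attempt", attempt))
    cand <- make(sp)
    ok <- all(vapply(cand, function(co) length(unique(co$meta$label)) == 2L,
                     logical(1))) &&
      min(table(cand$train$meta$label)) >= 2L
    if (ok || !require_both_classes) { out <- cand; break }
    out <- cand  # fall back to the last draw if nothing satisfies
  }
  out
}

#' Class-balanced batch construction
#'
#' Shuffles samples into batches of `batch_size` (final short batch kept).
#' In balanced mode -- required when a contrastive loss is served -- every
#' batch receives at least two samples of each class whenever the class
#' counts allow it, so no anchor is left without a positive partner.
#'
#' @param labels Integer 0/1 labels.
#' @param batch_size Batch size.
#' @param seed Integer seed; batches differ per epoch by deriving from it.
#' @param balanced Enforce the two-per-class floor.
#' @return List of integer index vectors.
#' @export
make_batches <- function(labels, batch_size, seed = 42L, balanced = TRUE) {
  n <- length(labels)
  stopifnot(n >= 1L, batch_size >= 1L)
  if (balanced && batch_size < 4L) {
    stop("balanced (contrastive) batching requires batch_size >= 4", call. = FALSE)
  }
  nb <- ceiling(n / batch_size)
  sizes <- rep(batch_size, nb)
  sizes[nb] <- n - (nb - 1L) * batch_size
  with_seed(seed, {
    if (!balanced) {
      perm <- sample.int(n)
      return(split(perm, rep(seq_len(nb), times = sizes)))
    }
    shuffle <- function(v) if (length(v) > 1L) sample(v) else v
    idx <- list(shuffle(which(labels == 0L)), shuffle(which(labels == 1L)))
    counts <- lengths(idx)
    alloc <- matrix(0L, nb, 2L)  # counts per batch per class
    cap <- sizes
    pick1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
    # pairs first (smaller class first), then leftovers, always within
    # capacity, preferring batches already holding the class
    for (cl in order(counts)) {
      left <- counts[cl]
      while (left >= 2L) {
        open <- which(cap >= 2L & alloc[, cl] == 0L)
        if (length(open) == 0L) break
        b <- pick1(open)
        alloc[b, cl] <- alloc[b, cl] + 2L
        cap[b] <- cap[b] - 2L
        left <- left - 2L
      }
      while (left > 0L) {
        open <- which(cap >= 1L & alloc[, cl] > 0L)
        if (length(open) == 0L) open <- which(cap >= 1L)
        b <- pick1(open)
        alloc[b, cl] <- alloc[b, cl] + 1L
        cap[b] <- cap[b] - 1L
        left <- left - 1L
      }
    }
    # repair singletons by swapping with a batch that has spares
    for (pass in 1:20) {
      fixed <- TRUE
      for (cl in 1:2) {
        oth <- 3L - cl
        for (b in which(alloc[, cl] == 1L & sizes > 1L)) {
          donors <- which(alloc[, cl] >= 3L)
          donors <- donors[donors != b]
          if (length(donors) && alloc[b, oth] >= 1L) {
            d <- pick1(donors)
            alloc[b, cl] <- alloc[b, cl] + 1L; alloc[d, cl] <- alloc[d, cl] - 1L
            alloc[b, oth] <- alloc[b, oth] - 1L; alloc[d, oth] <- alloc[d, oth] + 1L
            fixed <- FALSE
          }
        }
      }
      if (fixed) break
    }
    batches <- vector("list", nb)
    pos <- c(1L, 1L)
    for (b in seq_len(nb)) {
      take <- integer(0)
      for (cl in 1:2) {
        k <- alloc[b, cl]
        if (k > 0L) {
          take <- c(take, idx[[cl]][pos[cl]:(pos[cl] + k - 1L)])
          pos[cl] <- pos[cl] + k
        }
      }
      batches[[b]] <- if (length(take) > 1L) sample(take) else take
    }
    batches
  })
}

#' Training configuration
#'
#' @param lr Learning rate (> 0).
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size (default 8).
#' @param epochs Training epochs (default 20).
#' @param ratio Combined-loss weight for the `scl_adjust` kind (default 0.3).
#' @param t Contrastive temperature (default 0.5).
#' @param seed Global training seed (default 42).
#' @param clip_norm Global gradient-norm ceiling; gradients are rescaled
#'   when their joint L2 norm exceeds it. High-momentum SGD (0.95) at
#'   lr 0.01 is otherwise prone to overshooting on small batches. `Inf`
#'   disables clipping.
#' @param scl_target Layer the contrastive term acts on in `scl_adjust`:
#'   the 256-d penultimate pre-activation features (default) or the 2-d
#'   logits.
#' @param freeze_encoder Freeze the encoder during the two-stage model's
#'   downstream phase (default TRUE, a linear probe).
#' @return A `pa_train_config`.
#' @export
train_config <- function(lr = 0.001, momentum = 0.7, batch_size = 8L,
                         epochs = 20L, ratio = 0.3, t = 0.5, seed = 42L,
                         clip_norm = 1,
                         scl_target = c("penultimate", "logits"),
                         freeze_encoder = TRUE) {
  stopifnot(lr > 0, momentum >= 0, momentum < 1, epochs >= 1L,
            ratio >= 0, ratio <= 1, t > 0, clip_norm > 0)
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), ratio = ratio, t = t,
                 seed = as.integer(seed), clip_norm = clip_norm,
                 scl_target = match.arg(scl_target),
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "pa_train_config")
}

#' Default per-model training hyperparameters
#'
#' The selected operating points of the three variants: the plain
#' classifier at lr 0.001 / momentum 0.7; both contrastive variants at
#' lr 0.01 / momentum 0.95, the combined-loss model with ratio 0.3. The
#' gradient-norm ceiling is per-model: the low-learning-rate classifier
#' runs at 5 (clipping rarely binds and never throttles it), while the
#' high-momentum contrastive optimisers use 1, which keeps their training
#' stable across cohorts.
#'
#' @param kind Model kind.
#' @param seed Training seed.
#' @return A [train_config()].
#' @export
default_train_config <- function(kind = c("cnn", "sc", "scl_adjust"),
                                 seed = 42L) {
  kind <- match.arg(kind)
  switch(kind,
         cnn = train_config(lr = 0.001, momentum = 0.7, clip_norm = 5,
                            seed = seed),
         sc = train_config(lr = 0.01, momentum = 0.95, clip_norm = 1,
                           seed = seed),
         scl_adjust = train_config(lr = 0.01, momentum = 0.95, ratio = 0.3,
                                   clip_norm = 1, seed = seed))
}

# Convert a cohort (or list(x, y)) into the arrays the trainer consumes.
as_xy <- function(data) {
  if (inherits(data, "pa_cohort")) {
    list(x = data$spectra, y = as.integer(data$meta$label))
  } else {
    stopifnot(is.list(data), !is.null(data$x), !is.null(data$y))
    list(x = data$x, y = as.integer(data$y))
  }
}

# One optimisation phase over epochs. loss_fn(model, xb (B-array), yb)
# must return list(loss, grads). Returns model + history.
run_phase <- function(model, x, y, cfg, loss_fn, trainable, balanced, phase = "train") {
  state <- list()
  history <- numeric(cfg$epochs)
  n <- length(y)
  for (ep in seq_len(cfg$epochs)) {
    batches <- make_batches(y, cfg$batch_size,
                            seed = derive_seed(cfg$seed, phase, "epoch", ep),
                            balanced = balanced)
    ep_loss <- 0; ep_n <- 0L
    for (bt in batches) {
      res <- loss_fn(model, x[bt, , , drop = FALSE], y[bt])
      if (!is.finite(res$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
             call. = FALSE)
      }
      grads <- res$grads[trainable]
      cn <- cfg$clip_norm %||% Inf
      if (is.finite(cn)) {
        gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
        if (gnorm > cn) grads <- lapply(grads, function(g) g * (cn / gnorm))
      }
      upd <- sgd_update(model$params[trainable], grads, state, cfg$lr, cfg$momentum)
      model$params[trainable] <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + res$loss * length(bt)
      ep_n <- ep_n + length(bt)
    }
    history[ep] <- ep_loss / ep_n
  }
  list(model = model, history = history)
}

#' Train a classifier on a cohort
#'
#' Seeded SGD-with-momentum training of the three variants:
#' * `cnn`: one phase, cross-entropy;
#' * `scl_adjust`: one phase, `SCL * ratio + CEL * (1 - ratio)` with the
#'   contrastive term on the penultimate features (configurable);
#' * `sc`: representation phase (encoder + projector under the contrastive
#'   loss) followed by a downstream phase training the 2-unit head with
#'   cross-entropy on a frozen encoder (set `freeze_encoder = FALSE` in the
#'   config to fine-tune).
#'
#' @param model A `pa_model` from [build_model()].
#' @param data Training data: a `pa_cohort` or `list(x = N x 77 x 90 array,
#'   y = labels)`.
#' @param cfg A [train_config()]; defaults to the model kind's
#'   [default_train_config()].
#' @return The trained `pa_model` with an attached `history` (per-epoch
#'   mean loss per phase).
#' @export
train_model <- function(model, data, cfg = NULL) {
  stopifnot(inherits(model, "pa_model"))
  cfg <- cfg %||% default_train_config(model$kind)
  xy <- as_xy(data)
  x <- xy$x; y <- xy$y
  if (model$kind != "cnn" && length(unique(y)) < 2L) {
    stop("contrastive training requires both classes present", call. = FALSE)
  }
  # input normalisation: per-sample mean removal (the global dB level
  # carries patient and acquisition offsets, not class structure) plus a
  # global scale from the training set; the constants travel with the
  # model so inference applies the same transform
  if (is.null(model$norm)) {
    centered <- sweep(x, 1L, apply(x, 1L, mean))
    model$norm <- list(center = TRUE, sd = max(stats::sd(centered), 1e-8))
  }
  enc_names <- c("W1", "b1", "W2", "b2", "W3", "b3")

  if (model$kind == "cnn" || (model$kind == "scl_adjust" && cfg$ratio == 0)) {
    loss_fn <- function(m, xb, yb) {
      fw <- model_forward(m, xb, keep = TRUE)
      ce <- ce_loss_grad(fw$logits, yb)
      dh <- crossprod(m$params$W4, ce$dlogits)
      g <- encoder_backward(m$params, dh, fw$fw, fw$B, m$arch)
      g$W4 <- tcrossprod(ce$dlogits, fw$h); g$b4 <- rowSums(ce$dlogits)
      list(loss = ce$loss, grads = g)
    }
    ph <- run_phase(model, x, y, cfg, loss_fn, c(enc_names, "W4", "b4"),
                    balanced = length(unique(y)) > 1L)
    model <- ph$model
    model$history <- list(train = ph$history)
  } else if (model$kind == "scl_adjust") {
    ratio <- cfg$ratio; tt <- cfg$t
    on_logits <- identical(cfg$scl_target, "logits")
    loss_fn <- function(m, xb, yb) {
      fw <- model_forward(m, xb, keep = TRUE)
      ce <- ce_loss_grad(fw$logits, yb)
      # the contrastive term acts on the penultimate layer's pre-activation
      # values (signed, so cosine similarities span [-1, 1]) or the logits
      target <- if (on_logits) fw$logits else fw$fw$hpre
      scl <- scl_loss_grad(target, yb, tt)
      dlogits <- (1 - ratio) * ce$dlogits
      if (on_logits) dlogits <- dlogits + ratio * scl$dZ
      dh <- crossprod(m$params$W4, dlogits)
      g <- encoder_backward(m$params, dh, fw$fw, fw$B, m$arch,
                            dhpre_extra = if (on_logits) NULL else ratio * scl$dZ)
      g$W4 <- tcrossprod(dlogits, fw$h); g$b4 <- rowSums(dlogits)
      list(loss = ratio * scl$loss + (1 - ratio) * ce$loss, grads = g)
    }
    ph <- run_phase(model, x, y, cfg, loss_fn, c(enc_names, "W4", "b4"),
                    balanced = TRUE)
    model <- ph$model
    model$history <- list(train = ph$history)
  } else {  # sc: two-stage protocol
    tt <- cfg$t
    repr_fn <- function(m, xb, yb) {
      fw <- model_forward(m, xb, keep = TRUE)
      z <- m$params$Wp %*% fw$h + m$params$bp
      scl <- scl_loss_grad(z, yb, tt)
      dh <- crossprod(m$params$Wp, scl$dZ)
      g <- encoder_backward(m$params, dh, fw$fw, fw$B, m$arch)
      g$Wp <- tcrossprod(scl$dZ, fw$h); g$bp <- rowSums(scl$dZ)
      list(loss = scl$loss, grads = g)
    }
    ph1 <- run_phase(model, x, y, cfg, repr_fn, c(enc_names, "Wp", "bp"),
                     balanced = TRUE, phase = "repr")
    model <- ph1$model
    down_fn <- function(m, xb, yb) {
      fw <- model_forward(m, xb, keep = !cfg$freeze_encoder)
      ce <- ce_loss_grad(fw$logits, yb)
      g <- list(W4 = tcrossprod(ce$dlogits, fw$h), b4 = rowSums(ce$dlogits))
      if (!cfg$freeze_encoder) {
        dh <- crossprod(m$params$W4, ce$dlogits)
        g <- c(encoder_backward(m$params, dh, fw$fw, fw$B, m$arch), g)
      }
      list(loss = ce$loss, grads = g)
    }
    down_trainable <- if (cfg$freeze_encoder) c("W4", "b4") else c(enc_names, "W4", "b4")
    ph2 <- run_phase(model, x, y, cfg, down_fn, down_trainable,
                     balanced = length(unique(y)) > 1L, phase = "down")
    model <- ph2$model
    model$history <- list(representation = ph1$history, downstream = ph2$history)
  }
  model$trained <- TRUE
  model$config <- cfg
  model
}

#' Hyperparameter search space
#'
#' Sampling distributions for the random search: log-uniform learning rate
#' on `[1e-4, 1e-1]`, uniform momentum on `[0.5, 0.99]`, batch size from
#' `{8, 16, 32}`, combined-loss ratio from `0.1..0.9` in steps of 0.1, and
#' projector dimension from `{2, 4, 8, 16}`.
#'
#' @param n_rounds Number of random configurations (the full protocol uses
#'   500; scale down for quick studies).
#' @return A `pa_search_space`.
#' @export
search_space <- function(n_rounds = 500L) {
  stopifnot(n_rounds >= 1L)
  structure(list(
    n_rounds = as.integer(n_rounds),
    lr = function() 10^stats::runif(1, -4, -1),
    momentum = function() stats::runif(1, 0.5, 0.99),
    batch_size = function() sample(c(8L, 16L, 32L), 1L),
    ratio = function() sample(seq(0.1, 0.9, by = 0.1), 1L),
    projector_dim = function() sample(c(2L, 4L, 8L, 16L), 1L)
  ), class = "pa_search_space")
}

#' Random hyperparameter search
#'
#' Samples `n_rounds` configurations, trains each on the training cohort,
#' scores it on the validation cohort with the five-metric mean, and
#' returns the best configuration (ties broken by earlier round) plus the
#' full leaderboard.
#'
#' @param space A [search_space()].
#' @param train_data,val_data `pa_cohort`s (or `list(x, y)`).
#' @param kind Model kind to search.
#' @param seed Search seed.
#' @param epochs Epochs per round.
#' @return List with `best_config`, `best_score`, `leaderboard`
#'   (data.frame, one row per round).
#' @export
random_search <- function(space, train_data, val_data,
                          kind = c("cnn", "sc", "scl_adjust"), seed = 42L,
                          epochs = 20L) {
  kind <- match.arg(kind)
  stopifnot(inherits(space, "pa_search_space"))
  val <- as_xy(val_data)
  rows <- vector("list", space$n_rounds)
  configs <- vector("list", space$n_rounds)
  for (r in seq_len(space$n_rounds)) {
    draw <- with_seed(derive_seed(seed, "search", r), {
      list(lr = space$lr(), momentum = space$momentum(),
           batch_size = space$batch_size(), ratio = space$ratio(),
           projector_dim = space$projector_dim())
    })
    cfg <- train_config(lr = draw$lr, momentum = draw$momentum,
                        batch_size = draw$batch_size, epochs = epochs,
                        ratio = draw$ratio, seed = seed)
    arch <- architecture_spec(projector_dim = draw$projector_dim)
    fit <- tryCatch({
      m <- build_model(kind, arch = arch, seed = seed)
      train_model(m, train_data, cfg)
    }, error = function(e) NULL)
    sc <- if (is.null(fit)) NA_real_ else {
      ev <- evaluate_model(fit, val_data)
      ev$metrics$score
    }
    rows[[r]] <- data.frame(round = r, lr = draw$lr, momentum = draw$momentum,
                            batch_size = draw$batch_size, ratio = draw$ratio,
                            projector_dim = draw$projector_dim,
                            val_score = sc)
    configs[[r]] <- cfg
  }
  leaderboard <- do.call(rbind, rows)
  if (all(is.na(leaderboard$val_score))) {
    stop("every search round failed", call. = FALSE)
  }
  best <- which.max(ifelse(is.na(leaderboard$val_score), -Inf,
                           leaderboard$val_score))  # earliest max on ties
  list(best_config = configs[[best]], best_round = best,
       best_score = leaderboard$val_score[best], leaderboard = leaderboard)
}
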