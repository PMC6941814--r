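# Forward/backward passes and the Adam training loop. A batch is a
# (4, L, B) array; conv feature maps are (F, L', B) arrays. Each conv
# block (conv -> batch norm -> ReLU -> max-pool -> dropout) runs as one
# fused compiled call whose backprop intermediates stay on the C++ side;
# dropout draws come from R's RNG so runs are reproducible from a seed.

sigmoid <- function(z) 1 / (1 + exp(-z))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Training-mode forward pass. Returns list(probs, caches).
forward_train <- function(model, x, dropout = TRUE) {
  caches <- vector("list", length(model$conv_meta))
  h <- x
  B <- dim(x)[3]
  p <- model$params
  rate <- if (dropout) model$spec$dropout_conv else 0
  for (i in seq_along(model$conv_meta)) {
    m <- model$conv_meta[[i]]
    fb <- conv_block_forward_cpp(h, p[[paste0("conv", i, "_W")]],
                                 p[[paste0("conv", i, "_b")]],
                                 p[[paste0("conv", i, "_gamma")]],
                                 p[[paste0("conv", i, "_beta")]], BN_EPS,
                                 m$pool_size, m$pool_stride, rate > 0,
                                 rate)
    caches[[i]] <- fb$cache
    h <- fb$out
  }
  flat <- matrix(h, nrow = model$flat_dim, ncol = B)
  hz <- p$dense_W %*% flat + p$dense_b
  ha <- pmax(hz, 0)
  if (dropout && model$spec$dropout_dense > 0) {
    dmask <- matrix((runif(length(ha)) >= model$spec$dropout_dense) /
                      (1 - model$spec$dropout_dense), nrow(ha), ncol(ha))
    hd <- ha * dmask
  } else {
    dmask <- NULL
    hd <- ha
  }
  z2 <- p$out_W %*% hd + p$out_b
  list(probs = sigmoid(z2),
       caches = list(conv = caches, flat = flat, ha = ha, dmask = dmask,
                     hd = hd))
}

# Backward pass; y is (n_classes, B). Returns list(grads, bn) where bn
# holds the batch-norm batch statistics per conv layer.
backward <- function(model, fw, y) {
  p <- model$params
  B <- ncol(y)
  grads <- list()
  dz2 <- (fw$probs - y) / length(y)
  grads$out_W <- dz2 %*% t(fw$caches$hd)
  grads$out_b <- rowSums(dz2)
  dhd <- crossprod(p$out_W, dz2)
  if (!is.null(fw$caches$dmask)) dhd <- dhd * fw$caches$dmask
  dhz <- dhd * (fw$caches$ha > 0)
  grads$dense_W <- dhz %*% t(fw$caches$flat)
  grads$dense_b <- rowSums(dhz)
  dflat <- crossprod(p$dense_W, dhz)
  nconv <- length(model$conv_meta)
  lastm <- model$conv_meta[[nconv]]
  dh <- array(dflat, dim = c(lastm$F, model$feature_lens[nconv], B))
  bn <- vector("list", nconv)
  for (i in rev(seq_len(nconv))) {
    bb <- conv_block_backward_cpp(fw$caches$conv[[i]], dh,
                                  p[[paste0("conv", i, "_W")]],
                                  p[[paste0("conv", i, "_gamma")]],
                                  need_dx = i > 1L)
    grads[[paste0("conv", i, "_W")]] <- bb$dW
    grads[[paste0("conv", i, "_b")]] <- as.numeric(bb$db)
    grads[[paste0("conv", i, "_gamma")]] <- as.numeric(bb$dgamma)
    grads[[paste0("conv", i, "_beta")]] <- as.numeric(bb$dbeta)
    bn[[i]] <- list(mean = as.numeric(bb$bn_mean),
                    var = as.numeric(bb$bn_var))
    if (i > 1L) dh <- bb$dx
  }
  l2 <- model$spec$l2_strength
  if (l2 > 0) {
    for (nm in grep("_W$", names(p), value = TRUE))
      grads[[nm]] <- grads[[nm]] + l2 * p[[nm]]
  }
  list(grads = grads, bn = bn)
}

# Evaluation-mode forward pass: running batch-norm stats, no dropout.
forward_eval <- function(model, x) {
  h <- x
  p <- model$params
  for (i in seq_along(model$conv_meta)) {
    m <- model$conv_meta[[i]]
    h <- conv_block_eval_cpp(h, p[[paste0("conv", i, "_W")]],
                             p[[paste0("conv", i, "_b")]],
                             p[[paste0("conv", i, "_gamma")]],
                             p[[paste0("conv", i, "_beta")]],
                             model$bn_stats[[i]]$mean,
                             model$bn_stats[[i]]$var, BN_EPS,
                             m$pool_size, m$pool_stride)
  }
  flat <- matrix(h, nrow = model$flat_dim, ncol = dim(x)[3])
  ha <- pmax(p$dense_W %*% flat + p$dense_b, 0)
  sigmoid(p$out_W %*% ha + p$out_b)
}

bce_loss <- function(probs, y) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Predict class probabilities
#'
#' @param object A trained (or untrained) `cnn_model`.
#' @param x A 4 x L x N one-hot array or a `synthetic_dataset`.
#' @param split When `x` is a dataset, which split to predict
#'   (`"test"`, `"train"`, `"validation"`, or `"all"`).
#' @param batch_size Sequences per forward pass.
#' @param ... Unused.
#' @return N x n_classes matrix of sigmoid outputs.
#' @export
predict.cnn_model <- function(object, x, split = "test", batch_size = 250L,
                              ...) {
  if (inherits(x, "synthetic_dataset")) {
    idx <- if (identical(split, "all")) seq_len(dim(x$x)[3])
           else x$split[[split]]
    x <- x$x[, , idx, drop = FALSE]
  }
  n <- dim(x)[3]
  out <- matrix(NA_real_, n, object$spec$n_classes)
  for (s in split_batches(n, batch_size)) {
    out[s, ] <- t(forward_eval(object, x[, , s, drop = FALSE]))
  }
  out
}

split_batches <- function(n, size) {
  unname(split(seq_len(n), ceiling(seq_len(n) / size)))
}

#' Train a CNN on a synthetic dataset
#'
#' Mini-batch Adam on binary cross-entropy with L2 regularization on
#' weight matrices, dropout after every convolution block (0.1) and the
#' dense layer (0.5), and early stopping by checkpoint selection: the
#' returned parameters are those of the epoch with the lowest validation
#' loss.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param dataset A `synthetic_dataset` with train and validation splits.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Constant Adam learning rate.
#' @param seed Optional seed for shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @param time_budget Optional wall-clock budget in seconds; training
#'   stops after the first epoch that exceeds it (at least two epochs
#'   always run). Useful for fitting fixed-protocol runs into a
#'   compute allowance; the checkpointed best-validation parameters are
#'   returned as usual.
#' @return The trained `cnn_model` with `history` (tibble of per-epoch
#'   train/validation losses) and `best_epoch`.
#' @export
train_cnn <- function(model, dataset, epochs = 100L, batch_size = 100L,
                      learning_rate = 3e-4, seed = NULL, verbose = FALSE,
                      time_budget = NULL) {
  t_start <- Sys.time()
  if (!is.null(seed)) set.seed(seed)
  tr <- dataset$split$train
  va <- dataset$split$validation
  yt <- t(dataset$y)  # classes x N
  adam <- list(m = lapply(model$params, function(p) p * 0),
               v = lapply(model$params, function(p) p * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_loss <- Inf
  best_params <- model$params
  best_stats <- model$bn_stats
  best_epoch <- NA_integer_
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    tl <- 0
    nb <- 0L
    for (bidx in split_batches(length(ord), batch_size)) {
      ids <- ord[bidx]
      xb <- dataset$x[, , ids, drop = FALSE]
      yb <- yt[, ids, drop = FALSE]
      fw <- forward_train(model, xb)
      tl <- tl + bce_loss(fw$probs, yb)
      nb <- nb + 1L
      bk <- backward(model, fw, yb)
      grads <- bk$grads
      L_ins <- c(dim(xb)[2], model$feature_lens[-length(model$feature_lens)])
      for (i in seq_along(model$conv_meta)) {
        N <- L_ins[i] * dim(xb)[3]  # pre-pool positions x batch
        ub <- bk$bn[[i]]$var * N / max(N - 1, 1)
        model$bn_stats[[i]]$mean <- BN_MOMENTUM * model$bn_stats[[i]]$mean +
          (1 - BN_MOMENTUM) * bk$bn[[i]]$mean
        model$bn_stats[[i]]$var <- BN_MOMENTUM * model$bn_stats[[i]]$var +
          (1 - BN_MOMENTUM) * ub
      }
      adam$t <- adam$t + 1L
      corr1 <- 1 - b1^adam$t
      corr2 <- 1 - b2^adam$t
      for (nm in names(grads)) {
        g <- grads[[nm]]
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g * g
        model$params[[nm]] <- model$params[[nm]] -
          learning_rate * (adam$m[[nm]] / corr1) /
            (sqrt(adam$v[[nm]] / corr2) + eps)
      }
    }
    if (!is.finite(tl))
      stop("training diverged (non-finite loss) at epoch ", ep)
    vp <- predict(model, dataset$x[, , va, drop = FALSE])
    vl <- bce_loss(t(vp), yt[, va, drop = FALSE])
    hist[[ep]] <- c(train_loss = tl / nb, val_loss = vl)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tl / nb, vl))
    if (vl < best_loss) {
      best_loss <- vl
      best_params <- model$params
      best_stats <- model$bn_stats
      best_epoch <- ep
    }
    if (!is.null(time_budget) && ep >= 2L &&
        as.numeric(Sys.time() - t_start, units = "secs") > time_budget) {
      hist <- hist[seq_len(ep)]
      break
    }
  }
  model$params <- best_params
  model$bn_stats <- best_stats
  model$history <- tibble::tibble(
    epoch = seq_along(hist),
    train_loss = vapply(hist, `[[`, numeric(1), "train_loss"),
    val_loss = vapply(hist, `[[`, numeric(1), "val_loss"))
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}
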