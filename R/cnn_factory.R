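#' Architecture specifications for the CNN family
#'
#' Every network in the family shares the same backbone: one-hot DNA in,
#' two (or three) convolution blocks (cross-correlation with "same"
#' zero-padding -> batch norm -> ReLU -> max-pool -> dropout 0.1), a
#' 512-unit fully-connected ReLU layer with dropout 0.5, and 12 sigmoid
#' outputs. The variants differ only in max-pool geometry and filter
#' sizes. For the coupled-pool variants the two pool sizes multiply to
#' 100, so the flattened input to the dense layer — and hence the total
#' parameter count — is identical across them.
#'
#' Variant names and their geometry (pool1, pool2 sizes; pool stride
#' equals pool size unless noted):
#' * `CNN-1`, `CNN-2`, `CNN-4`, `CNN-10`, `CNN-25`, `CNN-50`, `CNN-100`:
#'   coupled pools (1,100) ... (100,1), filter sizes 19/5.
#' * `CNN_9-4`, `CNN_9-25`: first-layer filter size 9.
#' * `CNN_3-2`, `CNN_3-50`: first-layer filter size 3.
#' * `CNN-50-2`: pool1 window 50 with stride 2, then pool2 50/50 — same
#'   feature-map shapes as CNN-2 but a large pooled receptive field.
#' * `CNN_19-1_-2`: second-layer filter size 1, pools (2,50).
#' * `CNN-1-1-100`: three conv layers (30, 128, 128 filters; sizes 19,
#'   5, 5); the only pooling is a window of 100 after layer 3.
#' * `CNN-25(60)` (likewise 90, 120): CNN-25 with more first-layer
#'   filters; or pass `n_filters1`.
#'
#' @param name Variant name (see above).
#' @param n_filters1 Optional override of the number of first-layer
#'   filters.
#' @return An `architecture_spec`.
#' @export
cnn_variant <- function(name, n_filters1 = NULL) {
  nm <- name
  fmatch <- regmatches(nm, regexec("^(CNN-25)\\((\\d+)\\)$", nm))[[1]]
  if (length(fmatch)) {
    nm <- fmatch[2]
    if (is.null(n_filters1)) n_filters1 <- as.integer(fmatch[3])
  }
  coupled <- c("CNN-1" = 1, "CNN-2" = 2, "CNN-4" = 4, "CNN-10" = 10,
               "CNN-25" = 25, "CNN-50" = 50, "CNN-100" = 100)
  conv <- function(f, k, p, s = p)
    list(n_filters = f, filter_size = k, stride = 1L,
         pool_size = as.integer(p), pool_stride = as.integer(s))
  layers <- if (nm %in% names(coupled)) {
    p1 <- coupled[[nm]]
    list(conv(30L, 19L, p1), conv(128L, 5L, 100 / p1))
  } else if (nm == "CNN_9-4") {
    list(conv(30L, 9L, 4), conv(128L, 5L, 25))
  } else if (nm == "CNN_9-25") {
    list(conv(30L, 9L, 25), conv(128L, 5L, 4))
  } else if (nm == "CNN_3-2") {
    list(conv(30L, 3L, 2), conv(128L, 5L, 50))
  } else if (nm == "CNN_3-50") {
    list(conv(30L, 3L, 50), conv(128L, 5L, 2))
  } else if (nm == "CNN-50-2") {
    list(conv(30L, 19L, 50, 2), conv(128L, 5L, 50))
  } else if (nm == "CNN_19-1_-2") {
    list(conv(30L, 19L, 2), conv(128L, 1L, 50))
  } else if (nm == "CNN-1-1-100") {
    list(conv(30L, 19L, 1), conv(128L, 5L, 1), conv(128L, 5L, 100))
  } else {
    stop("unknown variant '", name, "'; valid names: ",
         paste(c(names(coupled), "CNN_9-4", "CNN_9-25", "CNN_3-2",
                 "CNN_3-50", "CNN-50-2", "CNN_19-1_-2", "CNN-1-1-100",
                 "CNN-25(<n>)"), collapse = ", "))
  }
  if (!is.null(n_filters1)) {
    layers[[1]]$n_filters <- as.integer(n_filters1)
    name <- sprintf("%s(%d)", nm, as.integer(n_filters1))
  }
  structure(list(name = name, conv_layers = layers, dense_units = 512L,
                 n_classes = 12L, dropout_conv = 0.1, dropout_dense = 0.5,
                 l2_strength = 1e-6, padding = "same"),
            class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat("<architecture_spec> ", x$name, "\n", sep = "")
  for (i in seq_along(x$conv_layers)) {
    cl <- x$conv_layers[[i]]
    cat(sprintf("  conv%d: %d filters x %d, pool %d (stride %d)\n", i,
                cl$n_filters, cl$filter_size, cl$pool_size, cl$pool_stride))
  }
  cat(sprintf("  dense %d -> %d sigmoid outputs\n", x$dense_units,
              x$n_classes))
  invisible(x)
}

#' All built-in variant names
#' @return Character vector.
#' @export
cnn_variant_names <- function() {
  c("CNN-1", "CNN-2", "CNN-4", "CNN-10", "CNN-25", "CNN-50", "CNN-100",
    "CNN_9-4", "CNN_9-25", "CNN_3-2", "CNN_3-50", "CNN-50-2",
    "CNN_19-1_-2", "CNN-1-1-100")
}

# Feature-map length after each conv block (pool output = ceil(L/stride))
feature_lengths <- function(spec, input_length) {
  L <- input_length
  out <- integer(length(spec$conv_layers))
  for (i in seq_along(spec$conv_layers)) {
    L <- as.integer(ceiling(L / spec$conv_layers[[i]]$pool_stride))
    if (L < 1) stop("pooling chain reduces feature-map length below 1")
    out[i] <- L
  }
  out
}

#' Build an untrained CNN from a spec
#'
#' Weights use He initialization (normal with sd `sqrt(2/fan_in)`);
#' biases start at zero, batch-norm scales at one.
#'
#' @param spec An `architecture_spec` from [cnn_variant()].
#' @param input_length Sequence length the network will see.
#' @param seed Optional integer seed for the initialization.
#' @return A `cnn_model` (untrained).
#' @export
build_cnn <- function(spec, input_length = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- feature_lengths(spec, input_length)
  params <- list()
  C <- 4L
  meta <- list()
  for (i in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[i]]
    K <- cl$filter_size
    Fn <- cl$n_filters
    fan_in <- C * K
    params[[paste0("conv", i, "_W")]] <-
      matrix(rnorm(Fn * fan_in, sd = sqrt(2 / fan_in)), Fn, fan_in)
    params[[paste0("conv", i, "_b")]] <- numeric(Fn)
    params[[paste0("conv", i, "_gamma")]] <- rep(1, Fn)
    params[[paste0("conv", i, "_beta")]] <- numeric(Fn)
    meta[[i]] <- list(K = K, C = C, F = Fn, pad_l = (K - 1L) %/% 2L,
                      pool_size = cl$pool_size,
                      pool_stride = cl$pool_stride)
    C <- Fn
  }
  flat_dim <- as.integer(C * lens[length(lens)])
  params$dense_W <- matrix(rnorm(spec$dense_units * flat_dim,
                                 sd = sqrt(2 / flat_dim)),
                           spec$dense_units, flat_dim)
  params$dense_b <- numeric(spec$dense_units)
  params$out_W <- matrix(rnorm(spec$n_classes * spec$dense_units,
                               sd = sqrt(2 / spec$dense_units)),
                         spec$n_classes, spec$dense_units)
  params$out_b <- numeric(spec$n_classes)
  bn_stats <- lapply(meta, function(m)
    list(mean = numeric(m$F), var = rep(1, m$F)))
  structure(list(spec = spec, input_length = as.integer(input_length),
                 conv_meta = meta, feature_lens = lens, flat_dim = flat_dim,
                 params = params, bn_stats = bn_stats, trained = FALSE,
                 history = NULL, best_epoch = NA_integer_),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> ", x$spec$name, ", input length ", x$input_length,
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  cat("  parameters: ", n_parameters(x), "\n", sep = "")
  if (x$trained)
    cat(sprintf("  best epoch %d (validation loss %.4f)\n", x$best_epoch,
                min(x$history$val_loss)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `cnn_model`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}
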