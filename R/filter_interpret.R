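#' Scan convolutional filters across sequences
#'
#' Runs the network in evaluation mode up to the requested convolutional
#' layer and records, per (sequence, filter), the maximum activation
#' (taken after batch norm and ReLU, before any pooling) and the
#' leftmost 0-based feature-map position achieving it.
#'
#' Layers deeper than 1 can only be scanned when no pooling precedes
#' them (all earlier pool sizes and strides equal 1): pooling obscures
#' the spatial correspondence between feature map and sequence, so the
#' alignment below would be meaningless and the function refuses.
#'
#' @param model A trained `cnn_model`.
#' @param x A 4 x L x N one-hot array, or a `synthetic_dataset` (its
#'   test split is scanned).
#' @param layer 1-based convolutional layer index.
#' @param batch_size Sequences per forward pass.
#' @return A `filter_scan`: list with `max` (F x N activation matrix),
#'   `pos` (F x N 0-based positions), `layer`, `receptive_field`, and
#'   `align_offset` (subtract from `pos` for the 0-based sequence start
#'   of the receptive-field window).
#' @export
scan_activations <- function(model, x, layer = 1L, batch_size = 250L) {
  if (inherits(x, "synthetic_dataset"))
    x <- x$x[, , x$split$test, drop = FALSE]
  nconv <- length(model$conv_meta)
  if (layer < 1L || layer > nconv)
    stop("layer must be in 1..", nconv)
  if (layer > 1L) {
    pooled <- vapply(model$conv_meta[seq_len(layer - 1L)],
                     function(m) m$pool_size > 1L || m$pool_stride > 1L,
                     logical(1))
    if (any(pooled))
      stop("layer ", layer, " is preceded by max-pooling; ",
           "alignment-based visualization is only valid when all ",
           "earlier pool sizes are 1")
  }
  ks <- vapply(model$conv_meta[seq_len(layer)], `[[`, integer(1), "K")
  pads <- vapply(model$conv_meta[seq_len(layer)], `[[`, integer(1),
                 "pad_l")
  n <- dim(x)[3]
  Fn <- model$conv_meta[[layer]]$F
  mx <- matrix(NA_real_, Fn, n)
  pos <- matrix(NA_integer_, Fn, n)
  for (s in split_batches(n, batch_size)) {
    h <- x[, , s, drop = FALSE]
    for (i in seq_len(layer)) {
      p <- model$params
      h <- conv_block_eval_cpp(h, p[[paste0("conv", i, "_W")]],
                               p[[paste0("conv", i, "_b")]],
                               p[[paste0("conv", i, "_gamma")]],
                               p[[paste0("conv", i, "_beta")]],
                               model$bn_stats[[i]]$mean,
                               model$bn_stats[[i]]$var, BN_EPS, 1L, 1L)
    }
    sm <- scan_max_cpp(h)
    mx[, s] <- sm$max
    pos[, s] <- sm$pos
  }
  structure(list(max = mx, pos = pos, layer = as.integer(layer),
                 receptive_field = as.integer(sum(ks - 1L) + 1L),
                 align_offset = as.integer(sum(pads))),
            class = "filter_scan")
}

# Analytic maximum activation per first-layer filter: fold batch norm
# into the convolution weights and sum the largest per-position weight
# (inputs are one-hot, so exactly one channel is active per position).
analytic_max_activation <- function(model) {
  m <- model$conv_meta[[1]]
  g <- model$params$conv1_gamma / sqrt(model$bn_stats[[1]]$var + BN_EPS)
  off <- model$params$conv1_beta +
    g * (model$params$conv1_b - model$bn_stats[[1]]$mean)
  W <- model$params$conv1_W  # F x (C*K), channel fastest
  vapply(seq_len(m$F), function(f) {
    wf <- matrix(W[f, ], m$C, m$K) * g[f]
    sum(apply(wf, 2, max)) + off[f]
  }, numeric(1))
}

#' Build position probability matrices from filter activations
#'
#' Implements the activation-alignment procedure: sequences whose
#' maximum activation for a filter is below `threshold_frac` of that
#' filter's maximum achievable activation are discarded; from each
#' surviving sequence the receptive-field-sized subsequence aligned at
#' the maximally activating position is extracted (windows running off
#' either sequence end are dropped); base counts per column are
#' normalized into a PPM.
#'
#' The "maximum achievable activation" is by default the empirical
#' maximum observed over all scanned sequences; `max_mode = "analytic"`
#' instead uses the batch-norm-folded upper bound over one-hot inputs
#' (first layer only).
#'
#' @param scan A `filter_scan` from [scan_activations()].
#' @param x The same sequences that were scanned (4 x L x N array or
#'   `synthetic_dataset`, test split).
#' @param threshold_frac Activation cutoff as a fraction of the maximum,
#'   in (0, 1].
#' @param max_mode `"empirical"` or `"analytic"`.
#' @param model Required for `max_mode = "analytic"`.
#' @return A list of `filter_ppm` objects (one per filter). A filter
#'   with no surviving subsequences yields an `empty` PPM with
#'   `n_sites = 0`.
#' @export
build_ppm <- function(scan, x, threshold_frac = 0.7,
                      max_mode = c("empirical", "analytic"),
                      model = NULL) {
  max_mode <- match.arg(max_mode)
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("threshold_frac must be in (0, 1]")
  if (inherits(x, "synthetic_dataset"))
    x <- x$x[, , x$split$test, drop = FALSE]
  W <- scan$receptive_field
  off <- scan$align_offset
  L <- dim(x)[2]
  n <- dim(x)[3]
  Fn <- nrow(scan$max)
  maxes <- switch(max_mode,
    empirical = apply(scan$max, 1, max),
    analytic = {
      if (is.null(model)) stop("max_mode = 'analytic' requires `model`")
      if (scan$layer != 1L)
        stop("analytic maximum is only defined for layer 1")
      analytic_max_activation(model)
    })
  lapply(seq_len(Fn), function(f) {
    thr <- threshold_frac * maxes[f]
    keep <- which(scan$max[f, ] >= thr & scan$max[f, ] > 0)
    starts <- scan$pos[f, keep] - off  # 0-based window starts
    ok <- starts >= 0L & starts + W <= L
    keep <- keep[ok]
    starts <- starts[ok]
    counts <- matrix(0, 4, W, dimnames = list(DNA_BASES, NULL))
    for (i in seq_along(keep))
      counts <- counts + x[, (starts[i] + 1L):(starts[i] + W), keep[i]]
    n_sites <- length(keep)
    mat <- if (n_sites > 0) sweep(counts, 2, colSums(counts), "/")
           else counts
    structure(list(filter_index = f, layer = scan$layer, matrix = mat,
                   n_sites = n_sites, activation_threshold = thr,
                   empty = n_sites == 0L),
              class = "filter_ppm")
  })
}

#' @export
print.filter_ppm <- function(x, ...) {
  cat("<filter_ppm> layer ", x$layer, " filter ", x$filter_index,
      ", width ", ncol(x$matrix), ", ", x$n_sites, " sites",
      if (x$empty) " (empty)", "\n", sep = "")
  invisible(x)
}

#' Per-position information content in bits
#'
#' `IC_i = 2 + sum_n p_i(n) log2 p_i(n)` with `0 log 0 = 0`: 0 bits at a
#' uniform column, 2 bits at a deterministic one. Logo letter heights
#' are `p_i(n) * IC_i`.
#'
#' @param ppm A `filter_ppm`, `motif_pwm`, or bare 4 x W probability
#'   matrix.
#' @return Numeric vector of per-position IC.
#' @export
information_content <- function(ppm) {
  if (is.matrix(ppm)) {
    m <- ppm
  } else {
    if (isTRUE(ppm$empty))
      stop("information content of an empty PPM is undefined")
    m <- ppm$matrix
  }
  plogp <- m * log2(m)
  plogp[m == 0] <- 0
  2 + colSums(plogp)
}

#' Export filter PPMs to a MEME minimal motif file
#'
#' Empty PPMs are skipped with a message; the output round-trips through
#' [load_motifs()].
#'
#' @param ppms List of `filter_ppm` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_meme <- function(ppms, path) {
  write_meme(ppms, path)
}
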