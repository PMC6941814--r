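# Shared fixtures built in code.

fixture_pool <- function() default_motif_pool()

# A deterministic single-motif "pool": one TF whose PWM is a fixed
# consensus, handy for degenerate-case tests.
consensus_motif <- function(name = "FIXED", seq = "ACGTA", p = 1) {
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - p) / 3, 4, length(idx))
  m[cbind(idx, seq_along(idx))] <- p
  motif_pwm(name, m)
}

small_dataset <- function(n = 60, seed = 11, pool = fixture_pool()) {
  generate_dataset(pool, n_sequences = n, seed = seed)
}

# Tiny architecture used to keep training-behaviour tests fast.
tiny_spec <- function() {
  spec <- cnn_variant("CNN-25")
  spec$conv_layers[[1]] <- list(n_filters = 8L, filter_size = 7L,
                                stride = 1L, pool_size = 25L,
                                pool_stride = 25L)
  spec$conv_layers[[2]] <- list(n_filters = 8L, filter_size = 3L,
                                stride = 1L, pool_size = 4L,
                                pool_stride = 4L)
  spec$dense_units <- 16L
  spec
}
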