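# Build a model whose first-layer filter is a hand-planted pattern
# detector: weights are log-odds of a consensus, batch-norm neutralized.
planted_model <- function(consensus = "ACGTACG", n_filters = 2L,
                          input_length = 40L) {
  spec <- cnn_variant("CNN-25")
  K <- nchar(consensus)
  spec$conv_layers[[1]] <- list(n_filters = n_filters, filter_size = K,
                                stride = 1L, pool_size = 1L,
                                pool_stride = 1L)
  spec$conv_layers[[2]] <- list(n_filters = 4L, filter_size = 3L,
                                stride = 1L, pool_size = 10L,
                                pool_stride = 10L)
  spec$dense_units <- 8L
  m <- build_cnn(spec, input_length, seed = 1)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  W <- matrix(-1, 4, K)
  W[cbind(idx, seq_len(K))] <- 1
  m$params$conv1_W[1, ] <- as.numeric(W)
  # neutralize batch norm for the planted filter in eval mode
  m$bn_stats[[1]]$mean[] <- 0
  m$bn_stats[[1]]$var[] <- 1 - motifrep:::BN_EPS
  m$params$conv1_gamma[] <- 1
  m$params$conv1_beta[] <- 0
  m
}

seq_with_site <- function(site, at, length = 40L) {
  set.seed(nchar(site) + at)
  s <- sample(c("A", "C", "G", "T"), length, TRUE)
  s[at:(at + nchar(site) - 1)] <- strsplit(site, "")[[1]]
  paste(s, collapse = "")
}

test_that("scan finds the planted site at its exact position", {
  m <- planted_model("ACGTACG")
  x <- array(0, c(4, 40, 3))
  at <- c(5L, 20L, 30L)
  for (i in 1:3) x[, , i] <- one_hot_encode(seq_with_site("ACGTACG", at[i]))
  sc <- scan_activations(m, x, layer = 1)
  # feature-map position (0-based) of a filter aligned at 1-based start
  # `at` is at + pad - 1 = at + 2
  expect_equal(sc$pos[1, ], at + 2L)
  expect_equal(sc$receptive_field, 7L)
})

test_that("ties resolve to the leftmost position", {
  m <- planted_model("ACGT")
  s <- paste0("ACGTACGT", paste(rep("C", 32), collapse = ""))
  x <- array(one_hot_encode(s), c(4, 40, 1))
  sc <- scan_activations(m, x, layer = 1)
  first <- sc$pos[1, 1]
  # the identical site 4 nt later scores the same; leftmost wins
  expect_equal(first, 1L)  # 1-based start 1 -> 0-based feature pos 1+1-1=1
})

test_that("PPM construction matches hand-assembled alignments", {
  m <- planted_model("ACGTACG")
  x <- array(0, c(4, 40, 5))
  at <- c(5L, 12L, 20L, 26L, 31L)
  for (i in 1:5) x[, , i] <- one_hot_encode(seq_with_site("ACGTACG", at[i]))
  sc <- scan_activations(m, x, layer = 1)
  pp <- build_ppm(sc, x, threshold_frac = 0.7)
  p1 <- pp[[1]]
  expect_false(p1$empty)
  expect_equal(ncol(p1$matrix), 7L)
  expect_equal(p1$n_sites, 5L)
  # all five sites identical -> one-hot PPM at the consensus
  expect_equal(unname(p1$matrix[cbind(match(strsplit("ACGTACG", "")[[1]],
                                            c("A", "C", "G", "T")), 1:7)]),
               rep(1, 7))
})

test_that("threshold_frac = 1 keeps only global maximizers; windows at the edge are dropped", {
  m <- planted_model("ACGTACG")
  # site at position 1 (no left buffer): window would start at 0-based -?
  x <- array(0, c(4, 40, 2))
  x[, , 1] <- one_hot_encode(seq_with_site("ACGTACG", 10L))
  set.seed(1)
  x[, , 2] <- one_hot_encode(paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                                   collapse = ""))
  sc <- scan_activations(m, x, layer = 1)
  pp <- build_ppm(sc, x, threshold_frac = 1)
  expect_equal(pp[[1]]$n_sites, 1L)
})

test_that("empty PPMs are flagged, excluded and unplottable", {
  m <- planted_model("ACGTACG")
  sc <- list(max = matrix(0, 2, 3), pos = matrix(0L, 2, 3), layer = 1L,
             receptive_field = 7L, align_offset = 3L)
  class(sc) <- "filter_scan"
  x <- array(0.25, c(4, 40, 3))
  pp <- build_ppm(sc, x)
  expect_true(all(vapply(pp, function(p) p$empty, logical(1))))
  expect_error(information_content(pp[[1]]), "empty")
  expect_error(autoplot(pp[[1]]), "empty")
  expect_error(write_meme(pp), "no non-empty")
})

test_that("information content matches the closed formula", {
  expect_equal(information_content(matrix(0.25, 4, 1)), 0)
  expect_equal(information_content(matrix(c(1, 0, 0, 0), 4, 1)), 2)
  expect_equal(information_content(matrix(c(0.5, 0.5, 0, 0), 4, 1)), 1)
  # 0 <= IC <= 2 on random PPMs
  set.seed(3)
  for (i in 1:20) {
    p <- matrix(rexp(20), 4, 5)
    p <- sweep(p, 2, colSums(p), "/")
    ic <- information_content(p)
    expect_true(all(ic >= 0 & ic <= 2 + 1e-12))
  }
})

test_that("PPMs are count-additive over disjoint subsequence sets", {
  set.seed(8)
  mk <- function(n) {
    counts <- matrix(0, 4, 5)
    for (i in seq_len(n)) {
      s <- sample(4, 5, TRUE)
      counts[cbind(s, 1:5)] <- counts[cbind(s, 1:5)] + 1
    }
    counts
  }
  c1 <- mk(7); c2 <- mk(13)
  p1 <- sweep(c1, 2, colSums(c1), "/")
  p2 <- sweep(c2, 2, colSums(c2), "/")
  pu <- sweep(c1 + c2, 2, colSums(c1 + c2), "/")
  expect_equal(pu, (7 * p1 + 13 * p2) / 20)
})

test_that("deeper layers are scannable only without preceding pooling", {
  d <- small_dataset(n = 30, seed = 9)
  m25 <- build_cnn(cnn_variant("CNN-25"), 200, seed = 1)
  expect_error(scan_activations(m25, d$x[, , 1:5], layer = 2),
               "preceded by max-pooling")
  m1 <- build_cnn(cnn_variant("CNN-1"), 200, seed = 1)
  sc <- scan_activations(m1, d$x[, , 1:5], layer = 2)
  expect_equal(sc$receptive_field, 19L + 4L)
  expect_equal(nrow(sc$max), 128L)
})

test_that("analytic maximum activation bounds the empirical one", {
  d <- small_dataset(n = 40, seed = 10)
  m <- build_cnn(cnn_variant("CNN-25"), 200, seed = 2)
  sc <- scan_activations(m, d$x[, , d$split$train])
  amax <- motifrep:::analytic_max_activation(m)
  expect_true(all(sc$max <= amax + 1e-4))
  pp <- build_ppm(sc, d$x[, , d$split$train], max_mode = "analytic",
                  model = m)
  expect_length(pp, 30L)
  expect_error(build_ppm(sc, d$x[, , d$split$train],
                         max_mode = "analytic"), "requires")
})

test_that("MEME export of PPMs round-trips through the motif reader", {
  m <- planted_model("ACGTACG")
  x <- array(0, c(4, 40, 4))
  for (i in 1:4) x[, , i] <- one_hot_encode(seq_with_site("ACGTACG",
                                                          5L + 6L * i))
  sc <- scan_activations(m, x)
  pp <- build_ppm(sc, x)
  f <- withr::local_tempfile(fileext = ".meme")
  expect_message(export_meme(pp, f), regexp = NA)  # nothing skipped? allow
  back <- load_motifs(f, "meme")
  expect_equal(back$motifs[[1]]$matrix, pp[[1]]$matrix, tolerance = 1e-5,
               ignore_attr = TRUE)
})
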