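test_that("bundled fixture loads into a valid 12-TF pool", {
  pool <- default_motif_pool()
  expect_s3_class(pool, "motif_pool")
  expect_length(pool$motifs, 24L)
  expect_setequal(names(pool$class_index),
                  c("Arid3", "CEBPB", "FOSL1", "Gabpa", "MEF2A", "MAFK",
                    "MAX", "NFYB", "SP1", "SRF", "STAT1", "YY1"))
  for (m in pool$motifs) {
    expect_true(all(m$matrix >= 0 & m$matrix <= 1))
    expect_equal(colSums(m$matrix), rep(1, ncol(m$matrix)),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  strands <- vapply(pool$motifs, `[[`, character(1), "strand")
  expect_equal(sum(strands == "forward"), 12L)
  expect_equal(sum(strands == "reverse_complement"), 12L)
})

test_that("count matrices are column-normalized without pseudocount", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 TOY",
               "A [10  0]",
               "C [ 0  5]",
               "G [ 0  0]",
               "T [ 0  0]"), f)
  pool <- load_motifs(f, format = "jaspar_pfm")
  expect_equal(pool$motifs[[1]]$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pool$motifs[[1]]$matrix[, 2], c(A = 0, C = 1, G = 0, T = 0))
})

test_that("malformed matrices are rejected with the motif named", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 BADCOL",
               "A [1 0]", "C [0 0]", "G [0 0]", "T [0 0]"), f)
  expect_error(load_motifs(f, format = "jaspar_pfm"), "BADCOL.*column 2")
})

test_that("reverse complement swaps A<->T, C<->G and reverses columns", {
  m <- motif_pwm("toy", matrix(c(1, 0, 0, 0,
                                 0, 1, 0, 0), 4, 2))
  rc <- reverse_complement(m)
  expect_equal(unname(rc$matrix[, 1]), c(0, 0, 1, 0))  # C -> G, reversed
  expect_equal(unname(rc$matrix[, 2]), c(0, 0, 0, 1))  # A -> T
  # involution and preserved normalization for every fixture motif
  for (mm in default_motif_pool()$motifs) {
    back <- reverse_complement(reverse_complement(mm))
    expect_equal(back$matrix, mm$matrix)
    expect_equal(colSums(reverse_complement(mm)$matrix),
                 rep(1, ncol(mm$matrix)), ignore_attr = TRUE)
  }
})

test_that("pool pairs reverse complements correctly", {
  pool <- default_motif_pool()
  for (i in seq(1, 23, by = 2)) {
    fwd <- pool$motifs[[i]]
    rc <- pool$motifs[[i + 1]]
    expect_identical(fwd$name, rc$name)
    expect_equal(rc$matrix,
                 fwd$matrix[4:1, ncol(fwd$matrix):1, drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("sample_site draws from the PWM columns", {
  # degenerate motif -> deterministic site
  m <- consensus_motif(seq = "AAA", p = 1)
  expect_identical(sample_site(m), "AAA")
  # fixed seed -> identical site
  m2 <- default_motif_pool()$motifs[[3]]
  set.seed(99); s1 <- sample_site(m2)
  set.seed(99); s2 <- sample_site(m2)
  expect_identical(s1, s2)
})

test_that("site sampling frequencies match the PWM (chi-square)", {
  set.seed(7)
  m <- default_motif_pool()$motifs[[1]]  # Arid3 forward
  n <- 20000
  sites <- replicate(n, sample_site(m))
  chars <- do.call(rbind, strsplit(sites, ""))
  for (j in seq_len(ncol(m$matrix))) {
    obs <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    p <- m$matrix[, j]
    keep <- p > 0
    pv <- suppressWarnings(
      stats::chisq.test(obs[keep], p = p[keep] / sum(p[keep]))$p.value)
    expect_gt(pv, 1e-4)
    expect_equal(sum(obs[!keep]), 0L, ignore_attr = TRUE)
  }
})

test_that("MEME writer round-trips through the reader", {
  pool <- default_motif_pool()
  f <- withr::local_tempfile(fileext = ".meme")
  fwd <- pool$motifs[c(1, 3, 5)]  # forward strands
  write_meme(fwd, f)
  back <- load_motifs(f, format = "meme")
  for (i in 1:3)
    expect_equal(back$motifs[[2 * i - 1]]$matrix, fwd[[i]]$matrix,
                 tolerance = 1e-5)
})
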