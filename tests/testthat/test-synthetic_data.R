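test_that("one-hot encoding satisfies its contract", {
  expect_equal(one_hot_encode("ACGT"), diag(4), ignore_attr = TRUE)
  m <- one_hot_encode("AAAA")
  expect_equal(m["A", ], rep(1, 4), ignore_attr = TRUE)
  expect_equal(sum(m[-1, ]), 0)
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  enc <- one_hot_encode(s)
  expect_equal(colSums(enc), rep(1, 200), ignore_attr = TRUE)
  expect_identical(one_hot_decode(enc), s)
  expect_error(one_hot_encode("ACGN"), "unknown character")
})

test_that("generated sequences respect buffers, bounds and labels", {
  pool <- fixture_pool()
  set.seed(21)
  for (rep in 1:50) {
    g <- generate_sequence(pool, length = 200)
    expect_equal(nchar(g$sequence), 200L)
    e <- g$embeddings[order(g$embeddings$start), ]
    expect_true(all(e$start >= 1))
    expect_true(all(e$end <= 199))
    if (nrow(e) > 1)
      expect_true(all(e$start[-1] - e$end[-nrow(e)] >= 1))
    expect_true(nrow(e) >= 1 && nrow(e) <= 5)
    # label bits match embedded TF names exactly
    expect_setequal(names(which(g$label == 1)), unique(e$motif_name))
  }
})

test_that("single-TF pool gives a single label bit", {
  single <- motif_pool(list(consensus_motif("ONLY", "ACGTACG")))
  set.seed(3)
  g <- generate_sequence(single, length = 60, min_motifs = 1,
                         max_motifs = 1)
  expect_equal(sum(g$label), 1L)
  expect_equal(names(which(g$label == 1)), "ONLY")
})

test_that("generation is deterministic under a seed", {
  pool <- fixture_pool()
  set.seed(77); g1 <- generate_sequence(pool)
  set.seed(77); g2 <- generate_sequence(pool)
  expect_identical(g1, g2)
  d1 <- generate_dataset(pool, n_sequences = 20, seed = 5)
  d2 <- generate_dataset(pool, n_sequences = 20, seed = 5)
  expect_identical(d1, d2)
})

test_that("split sizes follow floor arithmetic and partition the data", {
  d <- small_dataset(n = 10)
  expect_equal(lengths(d$split), c(train = 7L, validation = 1L, test = 2L))
  all_idx <- sort(unlist(d$split))
  expect_equal(all_idx, 1:10, ignore_attr = TRUE)
})

test_that("labels recomputed from embeddings match the stored matrix", {
  d <- small_dataset(n = 40, seed = 2)
  expect_identical(labels_from_embeddings(d), d$y)
  expect_equal(colSums(d$x[, , 1]), rep(1, 200), ignore_attr = TRUE)
})

test_that("background composition is uniform outside embedded sites", {
  d <- small_dataset(n = 120, seed = 8)
  occupied <- matrix(FALSE, 200, dim(d$x)[3])
  for (r in seq_len(nrow(d$embeddings))) {
    e <- d$embeddings[r, ]
    occupied[(e$start + 1):e$end, e$sequence_id] <- TRUE
  }
  counts <- sapply(1:4, function(b) sum(d$x[b, , ][t(!occupied)]))
  pv <- stats::chisq.test(counts)$p.value
  expect_gt(pv, 1e-4)
})

test_that("marginal class frequency matches the closed-form expectation", {
  # P(class present) = mean_k [1 - (11/12)^k], k uniform on 1..5 —
  # exhaustive expectation over motif draws with replacement from 24
  # strand-motifs (2 per class).
  p_theory <- mean(1 - (11 / 12)^(1:5))
  d <- generate_dataset(fixture_pool(), n_sequences = 3000, seed = 13)
  freq <- colMeans(d$y)
  se <- sqrt(p_theory * (1 - p_theory) / 3000)
  expect_true(all(abs(freq - p_theory) < 4 * se))
})

test_that("FASTA and BED-like exports round-trip the content", {
  d <- small_dataset(n = 8, seed = 4)
  fa <- withr::local_tempfile(fileext = ".fa")
  bed <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_fasta(d, fa)
  write_embeddings_bed(d, bed)
  lines <- readLines(fa)
  expect_equal(sum(startsWith(lines, ">")), 8L)
  expect_identical(lines[2], one_hot_decode(d$x[, , 1]))
  tab <- utils::read.delim(bed)
  expect_equal(nrow(tab), nrow(d$embeddings))
  expect_true(all(tab$end - tab$start > 0))
})
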