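shuffle_cols <- function(m, seed) {
  set.seed(seed)
  m[, sample(ncol(m))]
}

test_that("a motif matches itself at offset 0 with high significance", {
  pool <- fixture_pool()
  set.seed(1)
  for (m in pool$motifs[c(3, 5, 13)]) {
    r <- compare_motifs(m, m, n_shuffle = 200)
    expect_equal(r$offset, 0L)
    expect_equal(r$strand, "forward")
    # every non-degenerate column self-correlates at exactly 1
    expect_equal(r$score, sum(apply(m$matrix, 2, stats::sd) > 1e-9),
                 tolerance = 1e-6)
    expect_lt(r$p_value, 0.01)
  }
})

test_that("reverse-complement queries match on the opposite strand with equal score", {
  pool <- fixture_pool()
  set.seed(2)
  m <- pool$motifs[[3]]  # CEBPB forward
  rc <- reverse_complement(m)
  fwd <- compare_motifs(m, m, n_shuffle = 100)
  rev <- compare_motifs(rc, m, n_shuffle = 100)
  expect_equal(rev$strand, "reverse_complement")
  expect_equal(rev$score, fwd$score, tolerance = 1e-9)
})

test_that("uniform queries never reach significance", {
  set.seed(3)
  q <- matrix(0.25, 4, 10)
  r <- compare_motifs(q, fixture_pool()$motifs[[1]])
  expect_equal(r$score, 0)
  expect_equal(r$p_value, 1)
})

# An idealized filter that learned a whole motif: the motif centered in
# a filter-width PPM with uniform flanks.
filter_copy <- function(m, width = 19L) {
  W <- ncol(m)
  q <- matrix(0.25, 4, max(width, W))
  at <- (ncol(q) - W) %/% 2
  q[, (at + 1):(at + W)] <- m
  q
}

test_that("filter-width copies of every motif match their source", {
  pool <- fixture_pool()
  copies <- lapply(seq_along(pool$motifs), function(i)
    structure(list(filter_index = i, layer = 1L,
                   matrix = filter_copy(pool$motifs[[i]]$matrix),
                   n_sites = 50L, empty = FALSE), class = "filter_ppm"))
  rep_pos <- match_report(copies, pool, n_shuffle = 1000, seed = 7)
  expect_equal(rep_pos$frac_any, 1.0)
  expect_equal(rep_pos$frac_relevant, 1.0)
  # best-match identity holds for motifs not nested inside another
  # pool member (FOSL1's AP-1 core is contained in MAFK, so its best
  # match can be either family member)
  nms <- vapply(pool$motifs, `[[`, character(1), "name")
  check <- nms %in% c("CEBPB", "Gabpa", "MAX", "NFYB", "SP1", "SRF",
                      "STAT1", "YY1")
  expect_equal(rep_pos$results$best_motif[check], nms[check])
})

test_that("the database-column null detects repetitive motifs the shuffle null cannot", {
  pool <- fixture_pool()
  arid <- pool$motifs[[1]]  # 6-bp AT-rich motif, shuffle-ambiguous
  copies <- list(structure(list(filter_index = 1L, layer = 1L,
                                matrix = arid$matrix, n_sites = 50L,
                                empty = FALSE), class = "filter_ppm"))
  set.seed(3)
  r_shuf <- match_report(copies, pool, n_shuffle = 1000,
                         null_model = "shuffle")
  r_db <- match_report(copies, pool, n_shuffle = 1000,
                       null_model = "database")
  expect_false(r_shuf$results$is_match[1])
  expect_true(r_db$results$is_match[1])
})

test_that("fractions use all filters in the denominator, empties included", {
  pool <- fixture_pool()
  good <- lapply(3:4, function(i)  # CEBPB forward/reverse, non-repetitive
    structure(list(filter_index = i, layer = 1L,
                   matrix = pool$motifs[[i]]$matrix, n_sites = 10L,
                   empty = FALSE), class = "filter_ppm"))
  empty <- lapply(3:6, function(i)
    structure(list(filter_index = i, layer = 1L,
                   matrix = matrix(0, 4, 19), n_sites = 0L,
                   empty = TRUE), class = "filter_ppm"))
  set.seed(4)
  rep <- match_report(c(good, empty), pool, n_shuffle = 300)
  expect_equal(rep$n_filters, 6L)
  expect_equal(rep$frac_relevant, 2 / 6)
  expect_true(all(is.na(rep$results$e_value[3:6])))
})

test_that("relevant fraction never exceeds the any-pool fraction", {
  pool <- fixture_pool()
  set.seed(5)
  ppms <- lapply(1:10, function(i) {
    m <- matrix(rexp(4 * 19), 4, 19)
    structure(list(filter_index = i, layer = 1L,
                   matrix = sweep(m, 2, colSums(m), "/"), n_sites = 5L,
                   empty = FALSE), class = "filter_ppm")
  })
  rep <- match_report(ppms, pool, relevant = c("MAX", "SRF"),
                      n_shuffle = 200)
  expect_lte(rep$frac_relevant, rep$frac_any)
})

test_that("significance degrades monotonically with added noise (stochastic)", {
  pool <- fixture_pool()
  target <- pool$motifs[[5]]  # FOSL1
  noised <- function(eps) {
    m <- (1 - eps) * target$matrix + eps * 0.25
    m <- m + eps * matrix(runif(length(m)), 4)
    sweep(m, 2, colSums(m), "/")
  }
  set.seed(6)
  scores <- vapply(c(0, 0.3, 0.8), function(e)
    compare_motifs(noised(e), target, n_shuffle = 100)$score, numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("Tomtom wrapper degrades gracefully when the binary is absent", {
  skip_if(tomtom_available(), "tomtom happens to be installed")
  ppm <- structure(list(filter_index = 1L, layer = 1L,
                        matrix = fixture_pool()$motifs[[1]]$matrix,
                        n_sites = 5L, empty = FALSE),
                   class = "filter_ppm")
  expect_message(r <- run_tomtom(list(ppm), "db.meme"), "not found")
  expect_null(r)
})
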