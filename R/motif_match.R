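# Tomtom-style comparison: a query PPM slides across a target PWM (all
# offsets with >= min_overlap overlapping columns); the score at an
# offset is the sum of column-wise Pearson correlations. Significance
# comes from a permutation null of column-shuffled queries, scaled
# Bonferroni-style by the number of targets to mimic an E-value.

# Standardize columns so that the Pearson correlation between columns a
# and b is crossprod(za, zb); zero-variance columns map to zero.
standardize_cols <- function(m) {
  cent <- sweep(m, 2, colMeans(m))
  ss <- sqrt(colSums(cent^2))
  ss[ss < 1e-12] <- Inf
  sweep(cent, 2, ss, "/")
}

motif_matrix <- function(x) {
  if (is.matrix(x)) x else x$matrix
}

#' Compare a query PPM against a target motif
#'
#' Slides the query across the target (optionally both strands), scoring
#' each offset by the summed column-wise Pearson correlation over
#' overlapping columns, and estimates a permutation p-value from
#' column-shuffled queries (uses the session RNG).
#'
#' @param query A `filter_ppm`, `motif_pwm`, or 4 x W matrix.
#' @param target A `motif_pwm` or 4 x W matrix.
#' @param min_overlap Minimum overlapping columns per offset.
#' @param n_shuffle Permutations for the null.
#' @param both_strands Also score against the target's reverse
#'   complement.
#' @return A list: `score`, `offset` (query start relative to target
#'   start), `strand` (`"forward"` or `"reverse_complement"` relative to
#'   the target as given), `overlap`, `p_value`. A query with zero
#'   variance in every column returns `score = 0`, `p_value = 1`.
#' @export
compare_motifs <- function(query, target, min_overlap = 4L,
                           n_shuffle = 1000L, both_strands = TRUE) {
  q <- motif_matrix(query)
  t_fwd <- motif_matrix(target)
  if (!ncol(q) || !ncol(t_fwd)) stop("query and target must be non-empty")
  Zq <- standardize_cols(q)
  if (all(Zq == 0))
    return(list(score = 0, offset = 0L, strand = "forward",
                overlap = 0L, p_value = 1))
  targets <- list(forward = t_fwd)
  if (both_strands)
    targets$reverse_complement <- t_fwd[4:1, ncol(t_fwd):1, drop = FALSE]
  Ms <- lapply(targets, function(tm) crossprod(Zq, standardize_cols(tm)))
  bests <- lapply(Ms, match_best_cpp, min_ov = min_overlap)
  bi <- which.max(vapply(bests, `[[`, numeric(1), "score"))
  perms <- t(replicate(n_shuffle, sample.int(ncol(q)))) - 1L
  storage.mode(perms) <- "integer"
  null <- do.call(pmax, lapply(Ms, match_null_cpp, perms = perms,
                               min_ov = min_overlap))
  obs <- bests[[bi]]$score
  list(score = obs, offset = bests[[bi]]$offset,
       strand = names(bests)[bi], overlap = bests[[bi]]$overlap,
       p_value = (1 + sum(null >= obs)) / (n_shuffle + 1))
}

#' Match filter PPMs against a motif pool
#'
#' Compares every non-empty PPM against every strand-motif of the pool,
#' assigns each filter its best match (smallest E-value, ties broken by
#' larger overlap then motif name) and reports the fractions of filters
#' with a significant match. E-values are permutation p-values scaled by
#' the number of targets. Empty filters count in the denominators: they
#' are filters that learned nothing.
#'
#' @param ppms List of `filter_ppm` objects (see [build_ppm()]), or of
#'   `motif_pwm`.
#' @param pool A [motif_pool()] or list of `motif_pwm` targets (strands
#'   are compared as given, so include reverse complements in the pool).
#' @param relevant Character vector of ground-truth motif names; a
#'   filter "matches relevant" when a target with one of these names is
#'   significant. Defaults to every name in the pool.
#' @param e_cutoff Significance threshold on the E-value.
#' @param min_overlap Minimum overlapping columns per offset.
#' @param n_shuffle Permutations per filter.
#' @param seed Optional seed for the permutation null.
#' @param n_database Effective database size used to scale permutation
#'   p-values into E-values. Defaults to the number of targets in
#'   `pool`. Set it larger to reproduce the multiple-testing burden of
#'   a full-database search (e.g. 519 for the JASPAR 2016 vertebrate
#'   collection) when only the ground-truth pool is scored; `n_shuffle`
#'   must then resolve p-values below `e_cutoff / n_database`.
#' @param null_model `"shuffle"`: null queries are column permutations
#'   of the query itself (conservative; column-order information only,
#'   so repetitive or palindromic motifs are hard to call).
#'   `"database"`: null queries are random draws of columns from the
#'   pool's own column collection, the analogue of Tomtom's
#'   database-derived null (detects repetitive motifs, at the price of
#'   calling their shuffles too).
#' @return A `match_report`: list with `results` (one tibble row per
#'   filter), `frac_any`, `frac_relevant`, `n_filters`, `e_cutoff`.
#' @export
match_report <- function(ppms, pool = default_motif_pool(),
                         relevant = NULL, e_cutoff = 0.1,
                         min_overlap = 4L, n_shuffle = 1000L,
                         seed = NULL, n_database = NULL,
                         null_model = c("shuffle", "database")) {
  null_model <- match.arg(null_model)
  if (!length(ppms)) stop("no PPMs supplied")
  if (inherits(ppms, c("filter_ppm", "motif_pwm"))) ppms <- list(ppms)
  if (!is.null(seed)) set.seed(seed)
  targets <- if (inherits(pool, "motif_pool")) pool$motifs else pool
  t_names <- vapply(targets, `[[`, character(1), "name")
  t_strands <- vapply(targets, function(t)
    if (is.null(t$strand)) "forward" else t$strand, character(1))
  if (is.null(relevant)) relevant <- unique(t_names)
  n_targets <- length(targets)
  if (is.null(n_database)) n_database <- n_targets
  Zt <- lapply(targets, function(t) standardize_cols(t$matrix))
  Zpool <- if (null_model == "database")
    do.call(cbind, lapply(targets, function(t)
      standardize_cols(t$matrix))) else NULL
  rows <- purrr::map(seq_along(ppms), function(i) {
    ppm <- ppms[[i]]
    fi <- if (!is.null(ppm$filter_index)) ppm$filter_index else i
    ns <- if (!is.null(ppm$n_sites)) ppm$n_sites else NA_integer_
    base <- tibble::tibble(filter_index = fi, n_sites = ns,
                           best_motif = NA_character_,
                           best_strand = NA_character_,
                           best_offset = NA_integer_, score = NA_real_,
                           e_value = NA_real_, is_match = FALSE,
                           matches_relevant = FALSE)
    if (isTRUE(ppm$empty)) return(base)
    Zq <- standardize_cols(motif_matrix(ppm))
    if (all(Zq == 0)) return(base)
    W <- ncol(Zq)
    draws <- if (null_model == "shuffle") {
      t(replicate(n_shuffle, sample.int(W))) - 1L
    } else {
      matrix(sample.int(ncol(Zpool), n_shuffle * W, replace = TRUE) - 1L,
             n_shuffle, W)
    }
    storage.mode(draws) <- "integer"
    evals <- numeric(n_targets)
    offs <- integer(n_targets)
    ovls <- integer(n_targets)
    scrs <- numeric(n_targets)
    for (t in seq_len(n_targets)) {
      M <- crossprod(Zq, Zt[[t]])
      b <- match_best_cpp(M, min_overlap)
      Mnull <- if (null_model == "shuffle") M
               else crossprod(Zpool, Zt[[t]])
      null <- match_null_cpp(Mnull, draws, min_overlap)
      p <- (1 + sum(null >= b$score)) / (n_shuffle + 1)
      evals[t] <- p * n_database
      offs[t] <- b$offset
      ovls[t] <- b$overlap
      scrs[t] <- b$score
    }
    ord <- order(evals, -ovls, t_names)
    b <- ord[1]
    sig <- evals <= e_cutoff
    base$best_motif <- t_names[b]
    base$best_strand <- t_strands[b]
    base$best_offset <- offs[b]
    base$score <- scrs[b]
    base$e_value <- evals[b]
    base$is_match <- any(sig)
    base$matches_relevant <- any(sig & t_names %in% relevant)
    base
  })
  results <- dplyr::bind_rows(rows)
  structure(list(results = results,
                 frac_any = mean(results$is_match),
                 frac_relevant = mean(results$matches_relevant),
                 n_filters = nrow(results), e_cutoff = e_cutoff),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> %d filters; matched %.3f any, %.3f relevant (E <= %g)\n",
    x$n_filters, x$frac_any, x$frac_relevant, x$e_cutoff))
  invisible(x)
}

#' Is the external Tomtom binary available?
#' @return Logical.
#' @export
tomtom_available <- function() nzchar(Sys.which("tomtom"))

#' Run the external MEME-suite Tomtom tool
#'
#' Optional pathway for comparing filter PPMs against an arbitrary motif
#' database (e.g. the full JASPAR vertebrate collection) with Tomtom's
#' own E-values. Requires the `tomtom` binary on the PATH; when absent
#' the feature is disabled with a message and `NULL` is returned.
#'
#' @param ppms List of `filter_ppm` objects.
#' @param database Path to a MEME-format motif database.
#' @param e_cutoff Tomtom E-value threshold.
#' @return Tibble of Tomtom matches (one row per significant
#'   query-target pair), or `NULL` when Tomtom is not installed.
#' @export
run_tomtom <- function(ppms, database, e_cutoff = 0.1) {
  if (!tomtom_available()) {
    message("Tomtom binary not found on PATH; external motif-database ",
            "comparison is disabled. Use match_report() for the ",
            "built-in comparison.")
    return(NULL)
  }
  qfile <- tempfile(fileext = ".meme")
  outdir <- tempfile("tomtom")
  write_meme(ppms, qfile)
  status <- system2("tomtom", c("-thresh", format(e_cutoff), "-evalue",
                                "-oc", outdir, qfile, database))
  if (status != 0) stop("tomtom exited with status ", status)
  parse_tomtom_tsv(file.path(outdir, "tomtom.tsv"))
}

#' Parse a Tomtom TSV output file
#' @param path Path to `tomtom.tsv`.
#' @return Tibble with query, target, offset, p/E/q-values.
#' @export
parse_tomtom_tsv <- function(path) {
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  names(d) <- tolower(gsub("[^A-Za-z_]", "_", names(d)))
  tibble::as_tibble(d)
}
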