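#' One-hot encode a DNA sequence
#'
#' @param seq A DNA string over A, C, G, T.
#' @return A 4 x L binary matrix with rows A, C, G, T; each column sums
#'   to 1.
#' @export
one_hot_encode <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  code <- match(ch, DNA_BASES)
  if (anyNA(code))
    stop("unknown character '", ch[which(is.na(code))[1]], "' in sequence")
  m <- matrix(0, 4, length(code), dimnames = list(DNA_BASES, NULL))
  m[cbind(code, seq_along(code))] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' @param mat A 4 x L one-hot matrix (rows A, C, G, T).
#' @return The DNA string.
#' @export
one_hot_decode <- function(mat) {
  paste(DNA_BASES[apply(mat, 2, which.max)], collapse = "")
}

#' Generate one synthetic regulatory sequence
#'
#' Draws a uniform-background DNA sequence and embeds `k` motif sites,
#' `k` uniform on `min_motifs..max_motifs`, sampled with replacement from
#' the strand-motif pool (forward and reverse complements). Sites are
#' placed by rejection sampling so that every site keeps a buffer of at
#' least 1 nt from both sequence ends and from every other site. Each
#' site is itself sampled from its PWM. The label has one bit per TF
#' class, set when that TF's motif is embedded on either strand; motifs
#' arising by chance in the background are not labelled.
#'
#' @param pool A [motif_pool()].
#' @param length Sequence length in nt.
#' @param min_motifs,max_motifs Range of the number of embedded sites.
#' @return A list with `sequence` (string), `embeddings` (tibble:
#'   `motif_name`, `strand`, `start`, `end`; 0-based half-open), and
#'   `label` (named binary vector over TF classes).
#' @export
generate_sequence <- function(pool, length = 200L, min_motifs = 1L,
                              max_motifs = 5L) {
  widths <- vapply(pool$motifs, function(m) ncol(m$matrix), integer(1))
  if (min_motifs < 1L) stop("min_motifs must be >= 1")
  if (length < max_motifs * (max(widths) + 1L) + 1L)
    stop("sequence length ", length, " too short to always place ",
         max_motifs, " motifs with 1-nt buffers")
  k <- sample(seq.int(min_motifs, max_motifs), 1L)
  picks <- sample.int(base::length(pool$motifs), k, replace = TRUE)
  w <- widths[picks]
  # rejection-sample start positions until all buffers hold
  starts <- NULL
  for (try in seq_len(1000L)) {
    s <- vapply(w, function(wi) sample.int(length - wi - 1L, 1L), integer(1))
    ord <- order(s)
    ss <- s[ord]; ww <- w[ord]
    if (k == 1L || all(ss[-1L] - (ss[-k] + ww[-k]) >= 1L)) {
      starts <- s
      break
    }
  }
  if (is.null(starts)) stop("failed to place motifs after 1000 retries")
  bg <- sample.int(4L, length, replace = TRUE)
  chars <- DNA_BASES[bg]
  for (i in seq_len(k)) {
    m <- pool$motifs[[picks[i]]]$matrix
    site <- vapply(seq_len(w[i]),
                   function(j) sample.int(4L, 1L, prob = m[, j]), integer(1))
    chars[(starts[i] + 1L):(starts[i] + w[i])] <- DNA_BASES[site]
  }
  nms <- vapply(pool$motifs[picks], function(m) m$name, character(1))
  strands <- vapply(pool$motifs[picks], function(m) m$strand, character(1))
  label <- setNames(integer(base::length(pool$class_index)),
                    names(pool$class_index))
  label[nms] <- 1L
  list(sequence = paste(chars, collapse = ""),
       embeddings = tibble::tibble(motif_name = nms, strand = strands,
                                   start = starts, end = starts + w),
       label = label)
}

#' Generate the full synthetic dataset
#'
#' Generates `n_sequences` independent sequences with
#' [generate_sequence()], one-hot encodes them and splits them into
#' train/validation/test by a uniform random permutation. Split sizes are
#' `floor(f1*N)`, `floor(f2*N)` and the remainder.
#'
#' @param pool A [motif_pool()]; defaults to the bundled 12-TF pool.
#' @param n_sequences Number of sequences.
#' @param length Sequence length in nt.
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param min_motifs,max_motifs Range of embedded site counts.
#' @param seed Integer seed controlling the whole generation.
#' @return A `synthetic_dataset`: list with `x` (4 x L x N one-hot
#'   array), `y` (N x n_classes binary matrix), `embeddings` (tibble with
#'   `sequence_id`), `split` (list of index vectors), `length`, `seed`,
#'   and `motif_names`.
#' @export
generate_dataset <- function(pool = default_motif_pool(),
                             n_sequences = 25000L, length = 200L,
                             fractions = c(0.7, 0.1, 0.2),
                             min_motifs = 1L, max_motifs = 5L,
                             seed = 0L) {
  stopifnot(base::length(fractions) == 3L, all(fractions > 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  n_classes <- base::length(pool$class_index)
  x <- array(0, dim = c(4L, length, n_sequences),
             dimnames = list(DNA_BASES, NULL, NULL))
  y <- matrix(0L, n_sequences, n_classes,
              dimnames = list(NULL, names(pool$class_index)))
  embs <- vector("list", n_sequences)
  for (n in seq_len(n_sequences)) {
    g <- generate_sequence(pool, length, min_motifs, max_motifs)
    x[, , n] <- one_hot_encode(g$sequence)
    y[n, ] <- g$label
    embs[[n]] <- g$embeddings
  }
  embeddings <- dplyr::bind_rows(embs, .id = "sequence_id")
  embeddings$sequence_id <- as.integer(embeddings$sequence_id)
  perm <- sample.int(n_sequences)
  n_tr <- floor(fractions[1] * n_sequences)
  n_va <- floor(fractions[2] * n_sequences)
  split <- list(train = sort(perm[seq_len(n_tr)]),
                validation = sort(perm[n_tr + seq_len(n_va)]),
                test = sort(perm[(n_tr + n_va + 1L):n_sequences]))
  structure(list(x = x, y = y, embeddings = embeddings, split = split,
                 length = length, seed = seed,
                 motif_names = names(pool$class_index)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", dim(x$x)[3], " sequences x ", x$length,
      " nt, ", ncol(x$y), " classes\n", sep = "")
  cat("  split: ", paste(names(x$split), lengths(x$split), sep = "=",
                         collapse = ", "),
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Recompute labels from the embedding records
#'
#' Audit helper: rebuilds the N x n_classes label matrix from the
#' per-site ground-truth records; must equal the stored labels exactly.
#'
#' @param dataset A `synthetic_dataset`.
#' @return Binary matrix like `dataset$y`.
#' @export
labels_from_embeddings <- function(dataset) {
  y <- matrix(0L, dim(dataset$x)[3], length(dataset$motif_names),
              dimnames = list(NULL, dataset$motif_names))
  idx <- cbind(dataset$embeddings$sequence_id,
               match(dataset$embeddings$motif_name, dataset$motif_names))
  y[idx] <- 1L
  y
}

#' Write dataset sequences as FASTA
#'
#' Headers are `seq_<id>`; ids are 1-based sequence indices.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset_fasta <- function(dataset, path) {
  n <- dim(dataset$x)[3]
  seqs <- vapply(seq_len(n),
                 function(i) one_hot_decode(dataset$x[, , i]), character(1))
  writeLines(paste0(">seq_", seq_len(n), "\n", seqs), path)
  invisible(path)
}

#' Write the embedding records as a BED-like TSV
#'
#' Columns: sequence_id, start, end, motif_name, strand. Coordinates are
#' 0-based half-open.
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embeddings_bed <- function(dataset, path) {
  d <- dataset$embeddings[, c("sequence_id", "start", "end", "motif_name",
                              "strand")]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
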