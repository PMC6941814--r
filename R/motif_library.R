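#' Position weight matrices for transcription-factor motifs
#'
#' A `motif_pwm` is a named probability matrix over the DNA alphabet:
#' 4 rows (A, C, G, T) by W columns, every column summing to 1. The
#' ground-truth motifs of the synthetic task, the filter-derived PPMs and
#' all comparisons use this representation.
#'
#' @param name Motif identifier, e.g. `"CEBPB"`.
#' @param matrix Numeric 4 x W matrix of column-normalized probabilities,
#'   rows in A, C, G, T order.
#' @param strand `"forward"` or `"reverse_complement"`.
#' @return A `motif_pwm` object.
#' @export
motif_pwm <- function(name, matrix, strand = "forward") {
  strand <- match.arg(strand, c("forward", "reverse_complement"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("motif matrix must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 1L) stop("motif matrix must have at least one column")
  if (any(matrix < 0) || any(matrix > 1))
    stop("motif '", name, "': probabilities must lie in [0, 1]")
  csums <- colSums(matrix)
  bad <- which(abs(csums - 1) > 1e-6)
  if (length(bad))
    stop("motif '", name, "': column ", bad[1], " sums to ", csums[bad[1]],
         ", not 1")
  rownames(matrix) <- DNA_BASES
  structure(list(name = name, matrix = matrix, strand = strand),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat("<motif_pwm> ", x$name, " (", x$strand, "), width ",
      ncol(x$matrix), "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Reverse complement of a motif
#'
#' Swaps rows A<->T and C<->G and reverses the column order; applying it
#' twice returns the original motif.
#'
#' @param motif A [motif_pwm()].
#' @return A `motif_pwm` on the opposite strand.
#' @export
reverse_complement <- function(motif) {
  m <- motif$matrix[4:1, ncol(motif$matrix):1, drop = FALSE]
  rownames(m) <- DNA_BASES
  motif_pwm(motif$name, m,
            strand = if (motif$strand == "forward") "reverse_complement"
                     else "forward")
}

#' Ground-truth motif pool
#'
#' Holds the forward motifs and their reverse complements plus the map
#' from transcription-factor name to label-class index. Labels of the
#' synthetic task have one bit per unique TF name, set when the motif is
#' embedded on either strand.
#'
#' @param motifs List of forward-strand [motif_pwm()] objects with unique
#'   names.
#' @return A `motif_pool` with `2 * length(motifs)` members (forward then
#'   reverse complement, interleaved per TF) and a `class_index` named
#'   integer vector (1-based, in input order).
#' @export
motif_pool <- function(motifs) {
  nms <- vapply(motifs, function(m) m$name, character(1))
  if (anyDuplicated(nms)) stop("motif names must be unique")
  all <- list()
  for (m in motifs) {
    all[[length(all) + 1L]] <- m
    all[[length(all) + 1L]] <- reverse_complement(m)
  }
  structure(list(motifs = all,
                 class_index = setNames(seq_along(nms), nms)),
            class = "motif_pool")
}

#' @export
print.motif_pool <- function(x, ...) {
  cat("<motif_pool> ", length(x$class_index), " TFs (",
      length(x$motifs), " strand-motifs): ",
      paste(names(x$class_index), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.motif_pool <- function(x) length(x$motifs)

#' Load motifs from a MEME or JASPAR file
#'
#' Reads a motif file, column-normalizes counts to probabilities (no
#' pseudocount: embedded sites are sampled from the PWM, never scored
#' against it, so a zero-probability base simply never occurs) and builds
#' the pool of forward plus reverse-complement motifs. Class indices
#' follow file order.
#'
#' @param path Path to a motif file.
#' @param format `"meme"` (minimal motif format) or `"jaspar_pfm"`.
#' @return A [motif_pool()].
#' @export
load_motifs <- function(path, format = c("meme", "jaspar_pfm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  mats <- switch(format,
                 meme = parse_meme(path),
                 jaspar_pfm = parse_jaspar(path))
  fwd <- purrr::imap(mats, function(counts, nm) {
    cs <- colSums(counts)
    if (any(!is.finite(counts)))
      stop("motif '", nm, "': non-numeric entries")
    bad <- which(cs <= 0)
    if (length(bad))
      stop("motif '", nm, "': column ", bad[1], " sums to zero")
    motif_pwm(nm, sweep(counts, 2, cs, "/"))
  })
  motif_pool(unname(fwd))
}

parse_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", path)
  mats <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    if (is.na(h)) stop("motif '", nm, "': missing letter-probability matrix")
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h])))
    if (is.na(w)) stop("motif '", nm, "': cannot parse width")
    rows <- lines[(h + 1):(h + w)]
    vals <- suppressWarnings(lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (any(vapply(vals, function(v) length(v) != 4 || anyNA(v), logical(1))))
      stop("motif '", nm, "': malformed matrix row")
    mats[[nm]] <- t(do.call(rbind, vals))  # 4 x W, rows A C G T
  }
  mats
}

parse_jaspar <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path)
  mats <- list()
  for (s in starts) {
    hdr <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]]
    nm <- hdr[length(hdr)]
    rows <- lines[(s + 1):(s + 4)]
    vals <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[|\\]", "", r)
      suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
    })
    if (length(unique(lengths(vals))) != 1 || anyNA(unlist(vals)))
      stop("motif '", nm, "': malformed JASPAR count matrix")
    mats[[nm]] <- do.call(rbind, vals)
  }
  mats
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A [motif_pool()], a list of [motif_pwm()], or a list of
#'   `filter_ppm` objects (empty PPMs are skipped with a message).
#' @param path Output file.
#' @param nsites Site counts recorded per motif (recycled); `filter_ppm`
#'   objects carry their own.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, nsites = 20L) {
  if (inherits(motifs, "motif_pool")) motifs <- motifs$motifs
  if (inherits(motifs, c("motif_pwm", "filter_ppm"))) motifs <- list(motifs)
  keep <- vapply(motifs, function(m) !isTRUE(m$empty) &&
                   (is.null(m$n_sites) || m$n_sites > 0), logical(1))
  if (any(!keep)) message("skipping ", sum(!keep), " empty PPM(s)")
  motifs <- motifs[keep]
  if (!length(motifs)) stop("no non-empty motifs to write")
  nsites <- rep_len(nsites, length(motifs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -",
               "", "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    nm <- if (!is.null(m$name)) m$name else paste0("filter_", m$filter_index)
    ns <- if (!is.null(m$n_sites)) m$n_sites else nsites[i]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m$matrix), ns), con)
    writeLines(apply(m$matrix, 2, function(p)
      paste(sprintf("%.6f", p), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Sample a binding site from a motif
#'
#' Draws each position independently from the motif's per-column base
#' distribution (uses the session RNG; seed with [set.seed()]).
#'
#' @param motif A [motif_pwm()].
#' @return A DNA string of the motif's width.
#' @export
sample_site <- function(motif) {
  m <- motif$matrix
  idx <- vapply(seq_len(ncol(m)),
                function(j) sample.int(4L, 1L, prob = m[, j]), integer(1))
  paste(DNA_BASES[idx], collapse = "")
}

#' Path to the bundled ground-truth motif fixture
#'
#' Twelve synthetic stand-in PWMs (MEME minimal format) with the names,
#' realistic consensus sequences and widths of the JASPAR vertebrate
#' motifs used by the synthetic task: Arid3, CEBPB, FOSL1, Gabpa, MEF2A,
#' MAFK, MAX, NFYB, SP1, SRF, STAT1, YY1. They are constructed matrices,
#' not JASPAR database entries.
#'
#' @return File path.
#' @export
motifrep_motif_file <- function() {
  system.file("extdata", "tf_motifs_synthetic.meme", package = "motifrep",
              mustWork = TRUE)
}

#' Load the bundled 12-TF ground-truth pool
#'
#' @return A [motif_pool()] with 24 strand-motifs.
#' @export
default_motif_pool <- function() {
  load_motifs(motifrep_motif_file(), format = "meme")
}
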