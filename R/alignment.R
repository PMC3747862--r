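#' Construct a gapless-interior binding-site alignment
#'
#' An alignment is a rectangular set of sites padded with end gaps only:
#' every row has the same width and every column contains at least one
#' non-gap letter. `strand[i] == "-"` records that row `i` is stored as the
#' reverse-complement of the input site it came from.
#'
#' @param seqs character vector of padded sequences over `{A,C,G,T,-}`;
#'   names are used as site ids.
#' @param strand character vector of `"+"`/`"-"` provenance flags (recycled).
#' @param check validate invariants (rectangular, gapless interior, no
#'   all-gap column).
#' @return an object of class `tfbs_alignment` with elements `seqs`, `ids`,
#'   `strand` and `width`.
#' @export
tfbs_alignment <- function(seqs, strand = "+", check = TRUE) {
  ids <- names(seqs)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- sprintf("site_%d", seq_along(seqs))
  strand <- rep_len(strand, length(seqs))
  w <- unique(nchar(seqs))
  if (check) {
    if (length(seqs) == 0L) stop("alignment must contain at least one site")
    if (length(w) != 1L) stop("alignment is not rectangular")
    mat <- alignment_codes(structure(list(seqs = seqs), class = "tfbs_alignment"))
    if (any(apply(mat, 1L, function(r) {
      ng <- which(r != GAP_CODE)
      length(ng) == 0L || any(r[min(ng):max(ng)] == GAP_CODE)
    }))) stop("gap letters must form a contiguous prefix and/or suffix")
    if (any(colSums(mat != GAP_CODE) == 0L))
      stop("every alignment column must contain at least one non-gap letter")
  }
  structure(list(seqs = unname(seqs), ids = ids, strand = strand, width = w[1L]),
            class = "tfbs_alignment")
}

#' @export
print.tfbs_alignment <- function(x, max_rows = 20L, ...) {
  cat(sprintf("Binding-site alignment: %d sites x %d columns\n",
              length(x$seqs), x$width))
  n <- min(length(x$seqs), max_rows)
  for (i in seq_len(n))
    cat(sprintf("  %s  %s (%s)\n", x$seqs[i], x$ids[i], x$strand[i]))
  if (length(x$seqs) > n) cat(sprintf("  ... %d more\n", length(x$seqs) - n))
  invisible(x)
}

#' @export
length.tfbs_alignment <- function(x) length(x$seqs)

## integer code matrix, rows = sites, cols = alignment columns
#' @keywords internal
alignment_codes <- function(a) {
  matrix(dna_encode(paste(a$seqs, collapse = "")),
         nrow = length(a$seqs), byrow = TRUE)
}

#' Recover the original input sites from an alignment
#'
#' Strips end gaps and undoes the reverse-complement for rows stored on the
#' reverse strand.
#'
#' @param a a [tfbs_alignment()].
#' @return named character vector of gap-free input sequences.
#' @export
alignment_sites <- function(a) {
  out <- strip_gaps(a$seqs)
  flip <- a$strand == "-"
  out[flip] <- reverse_complement(out[flip])
  names(out) <- a$ids
  out
}

#' Per-column coverage and information content
#'
#' For each alignment column computes `C_i`, the fraction of non-gap
#' letters, and `IC_i`, the information content in bits with the
#' small-sample correction `e(n) = 3 / (2 ln 2 n)` subtracted and the
#' result clamped to `[0, 2]`:
#' `IC_i = max(0, 2 + sum_u f_i(u) log2 f_i(u) - e(n_i))`.
#' Letter frequencies use raw counts over non-gap letters (no pseudocount).
#'
#' @param a a [tfbs_alignment()].
#' @return data.frame with columns `column`, `coverage`, `ic` and `n`.
#' @export
column_stats <- function(a) {
  mat <- alignment_codes(a)
  w <- a$width
  ## all 5 x w letter counts in one tabulate pass
  cnt <- matrix(tabulate(mat + 5L * (col(mat) - 1L), nbins = 5L * w), 5L, w)
  n <- colSums(cnt[1:4, , drop = FALSE])
  f <- sweep(cnt[1:4, , drop = FALSE], 2L, pmax(n, 1L), "/")
  ent <- -colSums(ifelse(f > 0, f * log2(f), 0))
  IC <- ifelse(n > 0L, pmax(0, 2 - ent - small_sample_correction(pmax(n, 1L))), 0)
  data.frame(column = seq_len(w), coverage = n / nrow(mat), ic = IC, n = n)
}

#' Small-sample correction for column information content
#'
#' The asymptotic sampling-error approximation `(s - 1) / (2 ln 2 n)` with
#' alphabet size `s = 4`, in bits.
#'
#' @param n number of (non-gap) letters observed in the column.
#' @return correction in bits.
#' @export
small_sample_correction <- function(n) 3 / (2 * log(2) * n)

#' Trim uninformative alignment ends
#'
#' Scanning from the left, removes columns up to (exclusive) the first
#' column `j` with `C_j > C_min` and `IC_j > IC_min`; then the same from the
#' right. The defaults reproduce the pre-PSSM trimming configuration
#' (`C_min = 0.4`, `IC_min = 0`). Idempotent.
#'
#' @param a a [tfbs_alignment()].
#' @param C_min coverage threshold (strict).
#' @param IC_min information-content threshold in bits (strict).
#' @return the trimmed [tfbs_alignment()].
#' @export
trim_alignment <- function(a, C_min = 0.4, IC_min = 0) {
  st <- column_stats(a)
  ok <- st$coverage > C_min & st$ic > IC_min
  if (!any(ok))
    stop(sprintf("no column passes C > %g and IC > %g; trimming would empty the alignment",
                 C_min, IC_min))
  keep_alignment_columns(a, min(which(ok)), max(which(ok)))
}

## subset alignment to columns from..to, dropping rows' letters outside;
## rows that become all-gap are kept (they carry no letters) only if legal
#' @keywords internal
keep_alignment_columns <- function(a, from, to) {
  seqs <- substr(a$seqs, from, to)
  names(seqs) <- a$ids
  ## a row may lose all its letters; such rows are dropped (they no longer
  ## constrain the model and would violate the padding invariant)
  keep <- nchar(strip_gaps(seqs)) > 0L
  tfbs_alignment(seqs[keep], strand = a$strand[keep], check = FALSE)
}

#' Majority consensus of an alignment
#'
#' @param a a [tfbs_alignment()].
#' @return single character string, the most frequent non-gap letter per
#'   column (first alphabetically on ties).
#' @export
consensus <- function(a) {
  mat <- alignment_codes(a)
  paste(vapply(seq_len(a$width), function(i) {
    cnt <- tabulate(mat[, i][mat[, i] != GAP_CODE], nbins = 4L)
    DNA_LETTERS[which.max(cnt)]
  }, character(1)), collapse = "")
}
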