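#' Clip peak sequences to a window around the signal peak
#'
#' Each peak sequence is clipped to `width` bases surrounding its
#' point-source (signal peak) position: the window
#' `[p - width/2, p + width/2)` shifted, if necessary, to stay inside the
#' sequence. Sequences already at most `width` long are returned whole.
#' A missing point source (`peak == -1`) falls back to the midpoint.
#'
#' @param peaks a peaks data.frame as returned by [read_narrowpeak()]
#'   (columns `seq` and `peak`, the 0-based point-source offset), or a
#'   plain named character vector of sequences (midpoint used as the point
#'   source).
#' @param width clip width in bases (default 100).
#' @return named character vector of clipped sequences.
#' @export
clip_to_peak <- function(peaks, width = 100L) {
  stopifnot(width >= 1L)
  if (is.character(peaks)) {
    seqs <- peaks
    off <- rep(-1L, length(seqs))
  } else {
    seqs <- stats::setNames(peaks$seq, peaks$name)
    off <- peaks$peak
  }
  len <- nchar(seqs)
  off <- ifelse(off < 0L, len %/% 2L, off)
  if (any(off >= len)) stop("signal peak offset outside the peak sequence")
  out <- character(length(seqs))
  for (i in seq_along(seqs)) {
    if (len[i] <= width) { out[i] <- seqs[i]; next }
    s0 <- off[i] - width %/% 2L
    s0 <- min(max(0L, s0), len[i] - width)
    out[i] <- substr(seqs[i], s0 + 1L, s0 + width)
  }
  stats::setNames(toupper(out), names(seqs))
}

#' Adaptively trim a peak alignment
#'
#' Two-phase end trimming used by the ChIP-seq variant. First, ends are
#' trimmed with thresholds set to the column means: columns before the
#' first (after the last) column with coverage and information content at
#' or above their respective means are removed. Second, the lower-IC end
#' column is removed repeatedly until at most `max_cols` columns remain
#' and both end columns have strictly positive IC.
#'
#' The mean-threshold comparison is inclusive (`>=`): peak alignments of
#' equal-length sequences have constant coverage, where a strict
#' comparison would reject every column.
#'
#' @param A a [tfbs_alignment()] (more than two rows for the means to be
#'   meaningful; smaller alignments are returned unchanged).
#' @param max_cols maximal number of columns kept (default 15).
#' @return the trimmed [tfbs_alignment()].
#' @export
adaptive_trim <- function(A, max_cols = 15L) {
  if (length(A) <= 2L) return(A)
  st <- column_stats(A)
  ok <- st$coverage >= mean(st$coverage) & st$ic >= mean(st$ic)
  if (!any(ok)) stop("adaptive trimming would empty the alignment")
  from <- min(which(ok)); to <- max(which(ok))
  ic <- st$ic
  repeat {
    w <- to - from + 1L
    if (w <= 1L) break
    if (w > max_cols) {
      if (ic[from] <= ic[to]) from <- from + 1L else to <- to - 1L
    } else if (ic[from] <= 0) {
      from <- from + 1L
    } else if (ic[to] <= 0) {
      to <- to - 1L
    } else break
  }
  if (from > to) stop("adaptive trimming would empty the alignment")
  keep_alignment_columns(A, from, to)
}

#' Iteratively refine a peak alignment
#'
#' Alternates between trimming the alignment, building a gap-aware PSSM
#' from the trimmed core, and re-placing every peak sequence (both strands,
#' augmented-window sliding) to form a new alignment. Stops when the
#' summed column IC of the trimmed core has not changed (absolute
#' tolerance `tol`) for 3 consecutive iterations, or after `max_iter`
#' iterations (with a warning flag).
#'
#' @param A the current peak alignment (a [tfbs_alignment()]).
#' @param peaks named character vector of the clipped peak sequences to
#'   re-place.
#' @param Ka scope of the alignment PSSM.
#' @param max_cols column cap passed to [adaptive_trim()].
#' @param max_iter hard iteration cap (default 50).
#' @param tol convergence tolerance on the summed IC.
#' @param pseudocount,pair_pseudocount,background frequency-model
#'   parameters; background defaults to pooled letters of `peaks`.
#' @return the final [tfbs_alignment()] (full peak rows), with attributes
#'   `trimmed` (its trimmed core), `ic` (summed IC of the core),
#'   `iterations` and `converged`.
#' @export
refine_alignment <- function(A, peaks, Ka = 0L, max_cols = 15L,
                             max_iter = 50L, tol = 1e-9,
                             pseudocount = 0.25, pair_pseudocount = 0.0625,
                             background = NULL) {
  peaks <- toupper(peaks)
  ids <- names(peaks)
  if (is.null(ids)) ids <- sprintf("peak_%d", seq_along(peaks))
  if (is.null(background)) {
    pooled <- tabulate(unlist(lapply(peaks, dna_encode)), nbins = 4L)
    background <- (pooled + pseudocount) / (sum(pooled) + 4 * pseudocount)
  }
  codes_fwd <- lapply(peaks, dna_encode)
  codes_rc <- lapply(codes_fwd, revcomp_codes)
  ic_prev <- NULL; stable <- 0L; iter <- 0L; converged <- FALSE
  Tr <- NULL
  repeat {
    iter <- iter + 1L
    Tr <- if (length(A) > 2L) adaptive_trim(A, max_cols = max_cols) else A
    ic_sum <- sum(column_stats(Tr)$ic)
    if (!is.null(ic_prev) && abs(ic_sum - ic_prev) < tol) stable <- stable + 1L
    else stable <- 0L
    ic_prev <- ic_sum
    if (stable >= 3L) { converged <- TRUE; break }
    if (iter > max_iter) break
    K_eff <- min(Ka, Tr$width - 1L)
    pssm <- build_pssm(estimate_frequency_model(
      Tr, K = K_eff, pseudocount = pseudocount,
      pair_pseudocount = pair_pseudocount, background = background))
    A <- assemble_placements(pssm, peaks, ids,
                             codes = list(fwd = codes_fwd, rc = codes_rc))
  }
  if (!converged)
    warning(sprintf("refinement stopped at the iteration cap (%d)", max_iter))
  attr(A, "trimmed") <- Tr
  attr(A, "ic") <- ic_prev
  attr(A, "iterations") <- iter
  attr(A, "converged") <- converged
  A
}

## place every sequence against the PSSM and assemble the placements into
## one rectangular alignment (common coordinate frame given by the PSSM)
#' @keywords internal
assemble_placements <- function(pssm, seqs, ids = names(seqs), codes = NULL) {
  l <- pssm$l
  pls <- if (is.null(codes)) lapply(seqs, function(s) place_site(s, pssm))
         else lapply(seq_along(seqs), function(i)
           place_codes(pssm, codes$fwd[[i]], codes$rc[[i]]))
  s_col <- vapply(pls, function(p) l - p$offset + 1L, 0L)
  strand <- vapply(pls, `[[`, "", "strand")
  oriented <- ifelse(strand == "-", reverse_complement(seqs), toupper(seqs))
  ls <- nchar(oriented)
  lo <- min(s_col); hi <- max(s_col + ls - 1L)
  rows <- paste0(strrep(GAP, s_col - lo), oriented,
                 strrep(GAP, hi - (s_col + ls - 1L)))
  names(rows) <- ids
  out <- tfbs_alignment(rows, strand = strand, check = FALSE)
  ## remove any all-gap columns (possible only in tiny degenerate inputs)
  mat <- alignment_codes(out)
  gapcols <- which(colSums(mat != GAP_CODE) == 0L)
  if (length(gapcols) > 0L) {
    keep <- setdiff(seq_len(out$width), gapcols)
    rows <- vapply(seq_along(out$seqs), function(i)
      paste(strsplit(out$seqs[i], "")[[1]][keep], collapse = ""), "")
    names(rows) <- out$ids
    out <- tfbs_alignment(rows, strand = out$strand, check = FALSE)
  }
  out
}

#' Align ChIP-seq peak sequences and extract the core motif
#'
#' The ChIP-seq variant of the progressive aligner. Peaks are sampled down
#' to `peak_sample` sequences and clipped to `width` bases around their
#' signal peaks. For every scope value in `Ka_range` and each of `n_seeds`
#' seed sequences (the shortest, plus `n_seeds - 1` randomly chosen ones),
#' a modified progressive alignment is built — the partial alignment is
#' adaptively trimmed before each placement and at most `tie_sample`
#' equally short candidates compete per step — and then iteratively
#' refined. The candidate whose trimmed core has the highest summed IC is
#' returned.
#'
#' @param peaks a peaks data.frame from [read_narrowpeak()] or a named
#'   character vector of peak sequences.
#' @param Ka_range integer vector of scope values to search (default 0:8).
#' @param n_seeds number of seed sequences per scope value (default 6).
#' @param tie_sample maximal number of equally short candidates competing
#'   per progressive step (default 5).
#' @param peak_sample maximal number of peaks aligned (default 300).
#' @param seed RNG seed governing peak sampling, extra-seed choice and
#'   tie-break sampling; required for reproducibility.
#' @param width clip width (default 100).
#' @param max_cols column cap for the trimmed core (default 15).
#' @param max_iter refinement iteration cap per candidate.
#' @param pseudocount,pair_pseudocount frequency-model pseudocounts.
#' @return the winning trimmed core [tfbs_alignment()] (at most `max_cols`
#'   columns, positive-IC ends), with attributes `Ka`, `seed_id`, `ic`,
#'   `full` (the untrimmed refined alignment) and `candidates` (a
#'   data.frame of all candidates' summed IC).
#' @export
lasagna_chip <- function(peaks, Ka_range = 0:8, n_seeds = 6L, tie_sample = 5L,
                         peak_sample = 300L, seed = 1L, width = 100L,
                         max_cols = 15L, max_iter = 50L,
                         pseudocount = 0.25, pair_pseudocount = 0.0625) {
  seqs <- clip_to_peak(peaks, width = width)
  if (length(seqs) == 0L) stop("no peaks supplied")
  if (is.null(names(seqs))) names(seqs) <- sprintf("peak_%d", seq_along(seqs))
  with_seed(seed, {
    if (length(seqs) > peak_sample)
      seqs <- seqs[sort(sample(length(seqs), peak_sample))]
    len <- nchar(seqs)
    seed_idx <- which.min(len)
    extra <- setdiff(seq_along(seqs), seed_idx)
    if (length(extra) > n_seeds - 1L)
      extra <- sort(sample(extra, n_seeds - 1L))
    seed_set <- c(seed_idx, extra)

    pooled <- tabulate(unlist(lapply(seqs, dna_encode)), nbins = 4L)
    background <- (pooled + pseudocount) / (sum(pooled) + 4 * pseudocount)

    best <- NULL; best_ic <- -Inf
    cand <- data.frame(Ka = integer(0), seed_id = character(0), ic = numeric(0))
    for (Ka in Ka_range) {
      for (si in seed_set) {
        A <- progressive_align(seqs, Ka = Ka, seed_index = si,
                               tie_sample = tie_sample, per_iter_trim = TRUE,
                               max_cols = max_cols,
                               pseudocount = pseudocount,
                               pair_pseudocount = pair_pseudocount,
                               background = background)
        R <- suppressWarnings(refine_alignment(
          A, seqs, Ka = Ka, max_cols = max_cols, max_iter = max_iter,
          pseudocount = pseudocount, pair_pseudocount = pair_pseudocount,
          background = background))
        ic <- attr(R, "ic")
        cand <- rbind(cand, data.frame(Ka = Ka, seed_id = names(seqs)[si],
                                       ic = ic, stringsAsFactors = FALSE))
        if (ic > best_ic) {
          best_ic <- ic
          best <- structure(attr(R, "trimmed"),
                            Ka = Ka, seed_id = names(seqs)[si], ic = ic,
                            full = R)
        }
      }
    }
    attr(best, "candidates") <- cand
    best
  })
}
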