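#' Find the best placement of a site against a PSSM, both strands
#'
#' The site is augmented with `l - 1` gap letters on each end and every
#' window is scored gap-aware on both the site and its reverse-complement;
#' the best (score, offset, strand) is returned. On an exact score tie the
#' forward strand is preferred, then the leftmost offset.
#'
#' @param site gap-free sequence.
#' @param pssm a [build_pssm()] result.
#' @return list with `score`, `offset` (1-based window index) and `strand`
#'   (`"+"` site as given, `"-"` its reverse-complement).
#' @export
place_site <- function(site, pssm) {
  codes <- dna_encode(site)
  place_codes(pssm, codes, revcomp_codes(codes))
}

#' @keywords internal
place_codes <- function(pssm, fwd_codes, rc_codes) {
  fwd <- sliding_score_codes(pssm, fwd_codes)
  rev <- sliding_score_codes(pssm, rc_codes)
  if (rev$score > fwd$score)
    list(score = rev$score, offset = rev$offset, strand = "-")
  else
    list(score = fwd$score, offset = fwd$offset, strand = "+")
}

#' Pick the next site to align
#'
#' Returns a shortest unaligned site; among equally short sites the one
#' whose best sliding score (either strand) against the current PSSM is
#' highest, remaining ties broken by input order. When more than
#' `tie_sample` sites share the shortest length, only a random subset of
#' `tie_sample` competes (used by the ChIP-seq variant; sample under a
#' caller-controlled RNG state).
#'
#' @param U named character vector of unaligned, gap-free sites.
#' @param pssm PSSM built from the current partial alignment.
#' @param tie_sample maximal number of equally short candidates scored.
#' @return the chosen site (length-1 named character vector).
#' @export
choose_next_site <- function(U, pssm, tie_sample = Inf) {
  idx <- choose_next_index(U, pssm, tie_sample)$index
  U[idx]
}

#' @keywords internal
choose_next_index <- function(U, pssm, tie_sample = Inf, codes = NULL) {
  stopifnot(length(U) > 0L)
  len <- nchar(U)
  cand <- which(len == min(len))
  if (length(cand) > tie_sample)
    cand <- sort(sample(cand, tie_sample))
  pls <- lapply(cand, function(i) {
    if (is.null(codes)) place_site(U[i], pssm)
    else place_codes(pssm, codes$fwd[[i]], codes$rc[[i]])
  })
  sc <- vapply(pls, `[[`, 0, "score")
  best <- which.max(sc)  # first (input-order) maximum
  list(index = cand[best], placement = pls[[best]])
}

#' Merge a placed site into an alignment
#'
#' The site (reverse-complemented first if the placement says so) is padded
#' with end gaps to sit at the placed window offset; existing rows are
#' end-padded as needed so the result is rectangular. Leading/trailing
#' all-gap columns are dropped.
#'
#' @param A a [tfbs_alignment()].
#' @param site the gap-free site, as input (not yet reverse-complemented).
#' @param placement a [place_site()] result obtained against the PSSM of
#'   `A`.
#' @param id site id for the new row.
#' @return the widened [tfbs_alignment()].
#' @export
merge_placement <- function(A, site, placement, id = "site") {
  l <- A$width
  s <- if (placement$strand == "-") reverse_complement(site) else toupper(site)
  ls <- nchar(s)
  s_col <- l - placement$offset + 1L       # alignment column of site position 1
  lo <- min(1L, s_col)
  hi <- max(l, s_col + ls - 1L)
  pad <- function(x, nl, nr) paste0(strrep(GAP, nl), x, strrep(GAP, nr))
  old <- if (lo == 1L && hi == l) A$seqs
         else paste0(strrep(GAP, 1L - lo), A$seqs, strrep(GAP, hi - l))
  seqs <- c(old, pad(s, s_col - lo, hi - (s_col + ls - 1L)))
  names(seqs) <- c(A$ids, id)
  ## no all-gap column can arise: existing columns keep their letters and
  ## any new edge column is covered by the merged site itself
  tfbs_alignment(seqs, strand = c(A$strand, placement$strand), check = FALSE)
}

## The progressive-alignment engine shared by lasagna_align() and the
## ChIP-seq variant. Sites are consumed shortest-first; each is placed on
## both strands against the PSSM of the current partial alignment and
## merged. `per_iter_trim` switches on the ChIP behaviour: the partial
## alignment is adaptively trimmed before each PSSM build once it has more
## than two rows, and at most `tie_sample` equally short candidates compete
## for the next slot.
#' @keywords internal
progressive_align <- function(sites, Ka = 0L, seed_index = NULL,
                              tie_sample = Inf, per_iter_trim = FALSE,
                              max_cols = 15L,
                              pseudocount = 0.25, pair_pseudocount = 0.0625,
                              background = NULL) {
  sites <- toupper(sites)
  n <- length(sites)
  if (n == 0L) stop("no input sites")
  if (any(grepl(GAP, sites, fixed = TRUE))) stop("input sites must be gap-free")
  ids <- names(sites)
  if (is.null(ids)) ids <- sprintf("site_%d", seq_len(n))
  len <- nchar(sites)
  if (any(len < 4L)) stop("binding sites shorter than 4 nucleotides are not accepted")
  Ka <- as.integer(Ka)
  if (Ka < 0L) stop("Ka must be non-negative")
  if (!per_iter_trim && Ka >= min(len))
    stop("Ka must be smaller than the shortest site length")

  if (is.null(background)) {
    pooled <- tabulate(unlist(lapply(sites, dna_encode)), nbins = 4L)
    background <- (pooled + pseudocount) / (sum(pooled) + 4 * pseudocount)
  }

  if (is.null(seed_index)) seed_index <- which.min(len)  # first shortest
  A <- tfbs_alignment(stats::setNames(sites[seed_index], ids[seed_index]),
                      strand = "+")
  pending <- setdiff(seq_len(n), seed_index)
  log <- vector("list", n)
  log[[1L]] <- list(step = 1L, id = ids[seed_index], length = len[seed_index],
                    score = NA_real_, offset = NA_integer_, strand = "+")

  codes_fwd <- lapply(sites, dna_encode)
  codes_rc <- lapply(codes_fwd, revcomp_codes)

  step <- 1L
  while (length(pending) > 0L) {
    step <- step + 1L
    if (per_iter_trim && length(A) > 2L)
      A <- adaptive_trim(A, max_cols = max_cols)
    K_eff <- min(Ka, A$width - 1L)
    freq <- estimate_frequency_model(A, K = K_eff, pseudocount = pseudocount,
                                     pair_pseudocount = pair_pseudocount,
                                     background = background)
    pssm <- build_pssm(freq)
    pick <- choose_next_index(sites[pending], pssm, tie_sample = tie_sample,
                              codes = list(fwd = codes_fwd[pending],
                                           rc = codes_rc[pending]))
    j <- pending[pick$index]
    A <- merge_placement(A, sites[j], pick$placement, id = ids[j])
    log[[step]] <- list(step = step, id = ids[j], length = len[j],
                        score = pick$placement$score,
                        offset = pick$placement$offset,
                        strand = pick$placement$strand)
    pending <- setdiff(pending, j)
  }
  attr(A, "log") <- do.call(rbind.data.frame, c(log, stringsAsFactors = FALSE))
  attr(A, "background") <- background
  A
}

#' Progressively align variable-length binding sites
#'
#' The length-aware progressive alignment: the shortest site seeds the
#' alignment, then sites are repeatedly drawn shortest-first, placed on
#' both strands against the gap-aware PSSM of the current partial
#' alignment, and merged with end-gap padding. The result is a gapless-
#' interior alignment containing every input site exactly once (as itself
#' or its reverse-complement). Deterministic given the input order.
#'
#' @param sites named character vector of gap-free sites (length >= 4
#'   each).
#' @param Ka scope of the alignment PSSM: pair scores for distances up to
#'   `Ka` are used while placing sites; must be smaller than the shortest
#'   site length.
#' @param trim optional `list(C_min=, IC_min=)`; when supplied the finished
#'   alignment is end-trimmed with [trim_alignment()]. Off by default —
#'   callers trim before building a search PSSM.
#' @param pseudocount,pair_pseudocount additive pseudocounts for the
#'   per-iteration frequency models.
#' @param background optional length-4 background distribution; defaults to
#'   pooled letter counts of the input sites.
#' @param seed_index optional index of the seed site (must be a shortest
#'   site for the length-aware ordering to be meaningful; any index is
#'   accepted, as the ChIP-seq variant seeds arbitrarily).
#' @return a [tfbs_alignment()]; attribute `"log"` holds the processing
#'   order and placements, attribute `"background"` the background used.
#' @examples
#' a <- lasagna_align(c(s1 = "TGACTCA", s2 = "ATGACTCAG", s3 = "TTGACTCATT"))
#' a
#' @export
lasagna_align <- function(sites, Ka = 0L, trim = NULL,
                          pseudocount = 0.25, pair_pseudocount = 0.0625,
                          background = NULL, seed_index = NULL) {
  A <- progressive_align(sites, Ka = Ka, seed_index = seed_index,
                         pseudocount = pseudocount,
                         pair_pseudocount = pair_pseudocount,
                         background = background)
  if (!is.null(trim)) {
    log <- attr(A, "log"); bg <- attr(A, "background")
    A <- trim_alignment(A, C_min = trim$C_min, IC_min = trim$IC_min)
    attr(A, "log") <- log; attr(A, "background") <- bg
  }
  A
}
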