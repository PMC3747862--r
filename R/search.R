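#' Scan a sequence for putative binding sites
#'
#' Every l-mer of `seq` (`l` = PSSM length) is scored gaplessly on both
#' strands and assigned the higher of the two strand scores. Windows at or
#' above `cutoff` (all windows when `cutoff = NULL`) are returned sorted by
#' descending score, ties by position.
#'
#' @param seq a single DNA string (gap-free).
#' @param pssm a [build_pssm()] result.
#' @param cutoff minimal reported score, or `NULL` for all windows.
#' @param seq_id sequence identifier carried into the result.
#' @return data.frame with columns `seq_id`, `start`, `end` (1-based
#'   closed), `strand` (the higher-scoring strand), and `score`. Empty
#'   (with a warning) when the sequence is shorter than the PSSM.
#' @export
scan_sequence <- function(seq, pssm, cutoff = NULL, seq_id = "seq") {
  codes <- dna_encode(seq)
  l <- pssm$l
  if (length(codes) < l) {
    warning("sequence shorter than the PSSM; no windows scored")
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  fwd <- scan_scores(pssm, codes)
  rev_sc <- rev(scan_scores(pssm, revcomp_codes(codes)))
  score <- pmax(fwd, rev_sc)
  strand <- ifelse(fwd >= rev_sc, "+", "-")  # forward preferred on ties
  start <- seq_along(score)
  keep <- if (is.null(cutoff)) rep(TRUE, length(score)) else score >= cutoff
  ord <- order(-score[keep], start[keep])
  data.frame(seq_id = seq_id, start = start[keep][ord],
             end = (start[keep][ord] + l - 1L), strand = strand[keep][ord],
             score = score[keep][ord], stringsAsFactors = FALSE)
}

#' Cutoff score from the constituting binding sites
#'
#' The prediction cutoff of the PSSM search: the minimal sliding score,
#' over the sites the PSSM was built from, of each site against the PSSM.
#' Rescanning any constituting site at this cutoff recovers it.
#'
#' @param pssm a [build_pssm()] result.
#' @param alignment the [tfbs_alignment()] the PSSM was built from (its
#'   gap-stripped rows are the constituting sites, in aligned orientation).
#' @return numeric cutoff score.
#' @export
min_site_cutoff <- function(pssm, alignment) {
  rows <- strip_gaps(alignment$seqs)
  min(vapply(rows, function(s) sliding_score(pssm, s)$score, 0))
}

#' Empirical null distribution of PSSM scores
#'
#' Simulates an i.i.d. random sequence under the background letter
#' distribution long enough to yield `n_windows` window scores (both
#' strands, the higher kept) and stores the sorted upper 5% tail. The
#' smallest assignable nonzero p-value is `1 / n_windows` (2.5e-5 at the
#' default).
#'
#' @param pssm a [build_pssm()] result.
#' @param background length-4 letter distribution of the null; defaults to
#'   the PSSM's background (estimated from the sites that built it).
#' @param n_windows number of null window scores (default 40000).
#' @param seed RNG seed for the simulated sequence.
#' @return an object of class `score_null`: sorted decreasing `tail`,
#'   `n_windows`, `threshold` (the 95th percentile score) and `seed`.
#' @export
empirical_score_distribution <- function(pssm, background = pssm$bg,
                                         n_windows = 40000L, seed = 1L) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  codes <- with_seed(seed, sample.int(4L, n_windows + pssm$l - 1L,
                                      replace = TRUE, prob = background))
  fwd <- scan_scores(pssm, codes)
  rev_sc <- rev(scan_scores(pssm, revcomp_codes(codes)))
  score <- pmax(fwd, rev_sc)
  k <- floor(0.05 * n_windows)
  tail <- sort(score, decreasing = TRUE)[seq_len(k)]
  structure(list(tail = tail, n_windows = as.integer(n_windows),
                 threshold = tail[k], seed = seed),
            class = "score_null")
}

#' @export
print.score_null <- function(x, ...) {
  cat(sprintf("Empirical score null: %d windows, upper-5%% tail of %d scores\n",
              x$n_windows, length(x$tail)))
  cat(sprintf("95th percentile score: %.4f; smallest nonzero p-value: %g\n",
              x$threshold, 1 / x$n_windows))
  invisible(x)
}

#' Empirical p-value of a PSSM score
#'
#' `p = #(null scores >= score) / n_windows`, computed over the stored
#' upper-5% tail. Scores below the 95th percentile are censored at 0.05
#' and print as the sentinel `"0.05+"`; a score above every stored null
#' score gets p = 0, meaning smaller than `1 / n_windows`.
#'
#' @param dist a [empirical_score_distribution()] result.
#' @param score numeric vector of scores (same PSSM).
#' @return numeric vector of class `lasagna_pvalue`; censored entries carry
#'   the value 0.05 and format as `"0.05+"`.
#' @export
empirical_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_null"))
  ## tail sorted decreasing; count #(tail >= s) by binary search on the
  ## ascending copy: #(asc < s) via findInterval(left.open)
  asc <- rev(dist$tail)
  cnt <- length(asc) - findInterval(score, asc, left.open = TRUE)
  p <- cnt / dist$n_windows
  censored <- score < dist$threshold
  p[censored] <- 0.05
  structure(p, censored = censored, class = "lasagna_pvalue")
}

#' @export
format.lasagna_pvalue <- function(x, ...) {
  out <- vapply(unclass(x), function(p) format(p, ...), "")
  out[attr(x, "censored")] <- "0.05+"
  out
}

#' @export
print.lasagna_pvalue <- function(x, ...) {
  print(format(x), quote = FALSE, ...)
  invisible(x)
}

#' @export
as.character.lasagna_pvalue <- function(x, ...) format(x)

#' @export
`[.lasagna_pvalue` <- function(x, i) {
  structure(unclass(x)[i], censored = attr(x, "censored")[i],
            class = "lasagna_pvalue")
}
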