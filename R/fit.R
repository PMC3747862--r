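#' Fit a binding-site motif model by length-aware progressive alignment
#'
#' The central fitting function: aligns a set of variable-length binding
#' sites with the progressive aligner, optionally trims the alignment
#' ends, estimates the frequency model and builds the pair-aware PSSM
#' (search scope `Ks`, defaulting to the alignment scope `Ka`), and
#' precomputes the constituting-site cutoff used for site prediction.
#'
#' @param sites named character vector of gap-free binding sites, or a
#'   FASTA path.
#' @param Ka alignment scope (pair distance modelled while aligning).
#' @param Ks search scope of the fitted PSSM (default `Ka`).
#' @param trim `list(C_min=, IC_min=)` end-trimming thresholds applied
#'   before the PSSM is built; `NULL` disables. Default `C_min = 0.4`,
#'   `IC_min = 0`.
#' @param pseudocount,pair_pseudocount additive pseudocounts.
#' @param background optional length-4 background distribution; defaults
#'   to pooled letter counts of the input sites.
#' @return an object of class `lasagna_fit`: the `alignment`, the
#'   (trimmed) frequency model `freq`, the `pssm`, the prediction `cutoff`
#'   (minimal constituting-site sliding score) and the `call`.
#' @examples
#' fit <- lasagna(c(a = "TGACTCA", b = "ATGACTCAG", c = "TTGACTCATT"))
#' fit
#' coef(fit)[, 1:5]
#' predict(fit, c(prom = "AAAATGACTCAGGG"))
#' @export
lasagna <- function(sites, Ka = 0L, Ks = Ka,
                    trim = list(C_min = 0.4, IC_min = 0),
                    pseudocount = 0.25, pair_pseudocount = 0.0625,
                    background = NULL) {
  cl <- match.call()
  if (is.character(sites) && length(sites) == 1L && file.exists(sites))
    sites <- read_fasta(sites)
  A <- lasagna_align(sites, Ka = Ka, pseudocount = pseudocount,
                     pair_pseudocount = pair_pseudocount,
                     background = background)
  bg <- attr(A, "background")
  At <- if (!is.null(trim))
    trim_alignment(A, C_min = trim$C_min, IC_min = trim$IC_min) else A
  Ks <- as.integer(Ks)
  K_eff <- min(Ks, At$width - 1L)
  freq <- estimate_frequency_model(At, K = K_eff, pseudocount = pseudocount,
                                   pair_pseudocount = pair_pseudocount,
                                   background = bg)
  pssm <- build_pssm(freq)
  structure(list(alignment = At, full_alignment = A, freq = freq,
                 pssm = pssm, Ka = as.integer(Ka), Ks = K_eff,
                 cutoff = min_site_cutoff(pssm, At),
                 background = bg, call = cl),
            class = "lasagna_fit")
}

#' @export
print.lasagna_fit <- function(x, ...) {
  cat(sprintf("Binding-site motif model (%d sites, %d columns, Ka = %d, Ks = %d)\n",
              length(x$alignment), x$alignment$width, x$Ka, x$Ks))
  cat(sprintf("consensus: %s   cutoff score: %.3f bits\n",
              consensus(x$alignment), x$cutoff))
  invisible(x)
}

#' @export
summary.lasagna_fit <- function(object, ...) {
  st <- column_stats(object$alignment)
  structure(list(fit = object, column_stats = st,
                 ic_total = sum(st$ic),
                 consensus = consensus(object$alignment)),
            class = "summary.lasagna_fit")
}

#' @export
print.summary.lasagna_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("total information content: %.2f bits\n", x$ic_total))
  cat("per-column coverage and IC:\n")
  print(transform(x$column_stats,
                  coverage = round(coverage, 3), ic = round(ic, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @describeIn lasagna single-letter score matrix `M_i(u)` of the fitted
#'   PSSM (4 x l, bits); pair-score matrices are in `object$pssm$Mpair`.
#' @param object,x a `lasagna_fit`.
#' @param ... passed on.
#' @export
coef.lasagna_fit <- function(object, ...) {
  m <- object$pssm$M
  dimnames(m) <- list(DNA_LETTERS, seq_len(ncol(m)))
  m
}

#' Predict binding sites in new sequences
#'
#' Scans each sequence with the fitted PSSM (both strands, higher score
#' kept). With `type = "hits"` returns windows at or above `cutoff`
#' (default: the model's constituting-site cutoff), with empirical
#' p-values when a null distribution is supplied or `pvalue = TRUE`.
#' With `type = "score"` returns each whole sequence's sliding score
#' (any-length candidate-site scoring).
#'
#' @param object a [lasagna()] fit.
#' @param newdata named character vector of sequences, or a FASTA path.
#' @param type `"hits"` or `"score"`.
#' @param cutoff score cutoff for hits; `NULL` uses `object$cutoff`;
#'   `NA` reports all windows.
#' @param pvalue attach empirical p-values (builds a 40000-window null on
#'   first use).
#' @param null a prebuilt [empirical_score_distribution()].
#' @param seed seed for the null simulation.
#' @param ... unused.
#' @return for `"hits"`: a data.frame of scan hits across sequences; for
#'   `"score"`: a named numeric vector of sliding scores.
#' @export
predict.lasagna_fit <- function(object, newdata, type = c("hits", "score"),
                                cutoff = NULL, pvalue = FALSE, null = NULL,
                                seed = 1L, ...) {
  type <- match.arg(type)
  if (is.character(newdata) && length(newdata) == 1L && file.exists(newdata))
    newdata <- read_fasta(newdata)
  if (is.null(names(newdata)))
    names(newdata) <- sprintf("seq_%d", seq_along(newdata))
  if (type == "score")
    return(vapply(newdata, function(s) sliding_score(object$pssm, s)$score, 0))
  if (is.null(cutoff)) cutoff <- object$cutoff
  if (is.na(cutoff)) cutoff <- NULL
  hits <- do.call(rbind, lapply(names(newdata), function(id)
    scan_sequence(newdata[[id]], object$pssm, cutoff = cutoff, seq_id = id)))
  if (pvalue || !is.null(null)) {
    if (is.null(null))
      null <- empirical_score_distribution(object$pssm, seed = seed)
    hits$p_value <- empirical_pvalue(null, hits$score)
  }
  hits
}

#' Simulate binding sites from a fitted motif model
#'
#' Draws letters column-wise from the fitted per-column frequencies
#' `f_i(u)` (one independent draw per column; gap columns do not occur in
#' a trimmed model).
#'
#' @param object a [lasagna()] fit.
#' @param nsim number of sites.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return character vector of simulated sites of the model's width.
#' @export
simulate.lasagna_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  f <- object$freq$f1
  with_seed(seed, vapply(seq_len(nsim), function(i)
    dna_decode(vapply(seq_len(ncol(f)), function(j)
      sample.int(4L, 1L, prob = f[, j]), 0L)), ""))
}

#' Plot the information-content profile of a fitted motif model
#'
#' Barplot of per-column IC (bits, small-sample corrected) with the
#' consensus letters as axis labels and column coverage overlaid.
#'
#' @param x a [lasagna()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lasagna_fit <- function(x, ...) {
  st <- column_stats(x$alignment)
  cons <- strsplit(consensus(x$alignment), "")[[1L]]
  bp <- graphics::barplot(st$ic, names.arg = cons, ylim = c(0, 2),
                          ylab = "information content (bits)",
                          xlab = "consensus", border = NA,
                          col = "steelblue", ...)
  graphics::lines(bp, st$coverage * 2, type = "b", pch = 16, col = "grey40")
  graphics::axis(4, at = c(0, 1, 2), labels = c("0", "0.5", "1"))
  graphics::mtext("coverage", side = 4, line = 2)
  invisible(st)
}

#' @export
residuals.lasagna_fit <- function(object, ...) {
  ## per-site deviation of the sliding score from the alignment-mean score
  sc <- vapply(strip_gaps(object$alignment$seqs),
               function(s) sliding_score(object$pssm, s)$score, 0)
  stats::setNames(sc - mean(sc), object$alignment$ids)
}
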