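#' Estimate letter and pair frequencies from an alignment
#'
#' Computes per-column letter probabilities `f_i(u)` from non-gap counts
#' plus an additive pseudocount, per-position-pair probabilities
#' `f_{i,j}(u,v)` for all `1 <= j - i <= K` from rows with non-gap letters
#' at both positions, and the background `f(u)` (supplied, or pooled from
#' the non-gap letters of the alignment). The pair background is the
#' independence product `f(u,v) = f(u) f(v)`, so pair scores later measure
#' dependence relative to independence.
#'
#' Position pairs with no gap-free supporting row fall back to the
#' background product (they carry no evidence and score zero).
#'
#' @param alignment a [tfbs_alignment()].
#' @param K scope: maximal pair distance to model (`0` = letters only).
#'   Must be smaller than the alignment width.
#' @param pseudocount additive pseudocount per letter (default 0.25).
#' @param pair_pseudocount additive pseudocount per letter pair
#'   (default 0.0625).
#' @param background optional length-4 letter distribution (A,C,G,T).
#' @return an object of class `freq_model`: `f1` (4 x l), `fpair` (list by
#'   distance k of 16 x (l-k) matrices, pair `(u,v)` at row `4(u-1)+v`),
#'   `bg`, `n` (non-gap count per column), `K`, `l`, and the pseudocounts.
#' @export
estimate_frequency_model <- function(alignment, K = 0L,
                                     pseudocount = 0.25,
                                     pair_pseudocount = 0.0625,
                                     background = NULL) {
  stopifnot(inherits(alignment, "tfbs_alignment"))
  l <- alignment$width
  K <- as.integer(K)
  if (K < 0L || K >= l) stop("scope K must satisfy 0 <= K < alignment width")
  if (pseudocount < 0 || pair_pseudocount < 0) stop("pseudocounts must be non-negative")
  mat <- alignment_codes(alignment)

  cnt <- matrix(tabulate(mat + 5L * (col(mat) - 1L), nbins = 5L * l),
                5L, l)[1:4, , drop = FALSE]
  n_i <- colSums(cnt)
  if (any(n_i == 0L))
    stop("alignment column with zero non-gap letters (invariant violation)")
  f1 <- sweep(cnt + pseudocount, 2L, n_i + 4 * pseudocount, "/")

  if (is.null(background)) {
    pooled <- rowSums(cnt)
    bg <- (pooled + pseudocount) / (sum(pooled) + 4 * pseudocount)
  } else {
    stopifnot(length(background) == 4L, all(background >= 0))
    bg <- background / sum(background)
  }

  fpair <- list()
  if (K >= 1L) for (k in seq_len(K)) {
    fk <- matrix(0, 16L, l - k)
    for (i in seq_len(l - k)) {
      u <- mat[, i]; v <- mat[, i + k]
      ok <- u != GAP_CODE & v != GAP_CODE
      cc <- tabulate((u[ok] - 1L) * 4L + v[ok], nbins = 16L)
      tot <- sum(cc) + 16 * pair_pseudocount
      fk[, i] <- if (tot > 0) (cc + pair_pseudocount) / tot
                 else as.vector(outer(bg, bg))  # no evidence: background product
    }
    fpair[[k]] <- fk
  }

  structure(list(f1 = f1, fpair = fpair, bg = bg, n = n_i, K = K, l = l,
                 pseudocount = pseudocount, pair_pseudocount = pair_pseudocount),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat(sprintf("Frequency model: %d columns, scope K = %d, pseudocount %g/%g\n",
              x$l, x$K, x$pseudocount, x$pair_pseudocount))
  cat("background f(u):", sprintf("%s=%.3f", DNA_LETTERS, x$bg), "\n")
  invisible(x)
}
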