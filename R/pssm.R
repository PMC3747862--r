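#' Build a pair-aware PSSM from a frequency model
#'
#' Single-letter scores are log-odds in bits, `M_i(u) = log2 f_i(u)/f(u)`;
#' pair scores `M_{i,j}(u,v) = log2 f_{i,j}(u,v) / (f(u) f(v))` are stored
#' for all pair distances `1 <= j - i <= K`. For the gap-aware alignment
#' variant, the per-column minima `min_x M_i(x)` (and per-pair minima) are
#' precomputed: a gap letter inside an augmented window contributes the
#' worst score its column can produce.
#'
#' @param freq a [estimate_frequency_model()] result.
#' @param K scope of the PSSM; defaults to (and must not exceed) the scope
#'   of the frequency model.
#' @return an object of class `lasagna_pssm` with score matrices `M`
#'   (4 x l), `Mpair` (list by distance), the gap minima, and gap-extended
#'   lookup tables used by the scanners.
#' @export
build_pssm <- function(freq, K = freq$K) {
  stopifnot(inherits(freq, "freq_model"))
  K <- as.integer(K)
  if (K > freq$K) stop("requested scope K exceeds the frequency model's scope")
  if (any(freq$f1 <= 0) || any(freq$bg <= 0))
    stop("zero probability encountered; use a positive pseudocount")
  l <- freq$l
  M <- log2(freq$f1 / freq$bg)
  gapmin <- apply(M, 2L, min)
  ## gap-extended table: 5th letter (gap) scores the column minimum
  Mg <- rbind(M, gapmin)

  Mpair <- list(); Mpairg <- list(); gapmin_pair <- list()
  bgp <- rep(freq$bg, each = 4L) * rep(freq$bg, times = 4L)  # row 4(u-1)+v
  if (K >= 1L) for (k in seq_len(K)) {
    if (any(freq$fpair[[k]] <= 0))
      stop("zero pair probability encountered; use a positive pair pseudocount")
    Mp <- log2(freq$fpair[[k]] / bgp)
    gm <- apply(Mp, 2L, min)
    ## 25-row gap-extended table over codes (u-1)*5 + v, u,v in 1..5
    Mpg <- matrix(rep(gm, each = 25L), 25L, ncol(Mp))
    for (u in 1:4) for (v in 1:4) Mpg[(u - 1L) * 5L + v, ] <- Mp[(u - 1L) * 4L + v, ]
    Mpair[[k]] <- Mp; Mpairg[[k]] <- Mpg; gapmin_pair[[k]] <- gm
  }

  structure(list(M = M, Mpair = Mpair, Mg = Mg, Mpairg = Mpairg,
                 gapmin = gapmin, gapmin_pair = gapmin_pair,
                 K = K, l = l, bg = freq$bg,
                 pseudocount = freq$pseudocount,
                 pair_pseudocount = freq$pair_pseudocount),
            class = "lasagna_pssm")
}

#' @export
print.lasagna_pssm <- function(x, ...) {
  cat(sprintf("Pair-aware PSSM: %d columns, scope K = %d (bits)\n", x$l, x$K))
  m <- round(x$M, 2); rownames(m) <- DNA_LETTERS; colnames(m) <- seq_len(x$l)
  print(m)
  invisible(x)
}

## ---- internal scanners -----------------------------------------------------

## Scores of every length-l window of `codes` (integer codes; gaps allowed
## only when gap_aware). Returns numeric vector of length(codes) - l + 1.
#' @keywords internal
scan_scores <- function(pssm, codes, gap_aware = FALSE) {
  l <- pssm$l
  n <- length(codes) - l + 1L
  if (n < 1L) return(numeric(0))
  if (gap_aware) {
    Mv <- as.vector(pssm$Mg); nl <- 5L; Mp <- pssm$Mpairg
  } else {
    if (any(codes == GAP_CODE)) stop("gap letter in a gapless scan")
    Mv <- as.vector(pssm$M); nl <- 4L; Mp <- pssm$Mpair
  }
  sc <- numeric(n)
  for (i in seq_len(l))
    sc <- sc + Mv[codes[i:(i + n - 1L)] + nl * (i - 1L)]
  K <- min(pssm$K, l - 1L)
  if (K >= 1L) {
    nc <- nl * nl
    for (k in seq_len(K)) {
      Mpv <- as.vector(Mp[[k]])
      for (i in seq_len(l - k)) {
        code <- (codes[i:(i + n - 1L)] - 1L) * nl + codes[(i + k):(i + k + n - 1L)]
        sc <- sc + Mpv[code + nc * (i - 1L)]
      }
    }
  }
  sc
}

#' Score one window against a PSSM
#'
#' The score of an l-mer `s` is the sum of its single-letter scores plus,
#' for every pair distance `k = 1..K`, the scores of all letter pairs at
#' that distance. With `gap_aware = TRUE` gap letters contribute the
#' precomputed column (pair) minima, the alignment variant of the score.
#'
#' @param pssm a [build_pssm()] result.
#' @param s character string of length `pssm$l`.
#' @param gap_aware allow gap letters, scored as column minima.
#' @return numeric score in bits.
#' @export
score_window <- function(pssm, s, gap_aware = FALSE) {
  codes <- dna_encode(s)
  if (length(codes) != pssm$l)
    stop(sprintf("window length %d does not match PSSM length %d",
                 length(codes), pssm$l))
  scan_scores(pssm, codes, gap_aware = gap_aware)
}

#' Slide a sequence of any length through a PSSM
#'
#' Implements the sliding score of an isolated candidate site: the sequence
#' is augmented with `l - 1` gap letters on each end and all
#' `l + l_s - 1` windows are scored gap-aware; the maximum and its window
#' offset are returned. Ties are broken by the leftmost window.
#'
#' @param pssm a [build_pssm()] result.
#' @param s character string (gap-free, any length >= 1).
#' @return list with `score`, `offset` (1-based window index, matching the
#'   sliding index `i` in `1..l + l_s - 1`), `window` (the aligned window,
#'   gaps included) and `n_windows`.
#' @export
sliding_score <- function(pssm, s) {
  codes <- dna_encode(s)
  if (length(codes) < 1L) stop("empty sequence")
  l <- pssm$l
  aug <- c(rep(GAP_CODE, l - 1L), codes, rep(GAP_CODE, l - 1L))
  sc <- scan_scores(pssm, aug, gap_aware = TRUE)
  off <- which.max(sc)  # leftmost maximum
  list(score = sc[off], offset = off,
       window = dna_decode(aug[off:(off + l - 1L)]),
       n_windows = length(sc))
}

## code-level sliding score (Eq.-3 augmentation), avoiding re-encoding in
## the aligner's inner loop
#' @keywords internal
sliding_score_codes <- function(pssm, codes) {
  l <- pssm$l
  aug <- c(rep(GAP_CODE, l - 1L), codes, rep(GAP_CODE, l - 1L))
  sc <- scan_scores(pssm, aug, gap_aware = TRUE)
  off <- which.max(sc)
  list(score = sc[off], offset = off)
}

## Eq.-3 sliding scores for every l-mer of a long gap-free sequence,
## vectorised across genomic start positions. For each relative placement
## of the PSSM against the augmented l-mer, the columns falling outside the
## l-mer contribute their precomputed gap minima; the inside contribution
## is a shifted-index cross-correlation over the whole sequence. Returns
## one score per l-mer start (length(codes) - lmer_len + 1 values).
#' @keywords internal
sliding_scores_genomic <- function(pssm, codes, lmer_len) {
  L <- pssm$l
  n <- length(codes) - lmer_len + 1L
  if (n < 1L) return(numeric(0))
  gm <- pssm$gapmin; cgm <- c(0, cumsum(gm)); tot <- cgm[L + 1L]
  K <- min(pssm$K, L - 1L)
  if (K >= 1L) {
    cgp <- lapply(pssm$gapmin_pair, function(v) c(0, cumsum(v)))
    totp <- vapply(pssm$gapmin_pair, sum, 0)
  }
  Mv <- as.vector(pssm$M)
  gseq <- seq_len(n)
  best <- rep(-Inf, n)
  for (i in seq_len(L + lmer_len - 1L)) {
    c_lo <- max(1L, L + 1L - i)
    c_hi <- min(L, L + lmer_len - i)
    base <- i - L - 1L  # letter for column c, start g: codes[g + base + c]
    sc <- rep(tot - (cgm[c_hi + 1L] - cgm[c_lo]), n)
    for (cc in c_lo:c_hi)
      sc <- sc + Mv[(cc - 1L) * 4L + codes[gseq + (base + cc)]]
    if (K >= 1L) for (k in seq_len(K)) {
      hi <- c_hi - k
      inside <- if (hi >= c_lo) cgp[[k]][hi + 1L] - cgp[[k]][c_lo] else 0
      sc <- sc + (totp[k] - inside)
      if (hi >= c_lo) {
        Mpv <- as.vector(pssm$Mpair[[k]])
        for (cc in c_lo:hi) {
          u <- codes[gseq + (base + cc)]
          v <- codes[gseq + (base + cc + k)]
          sc <- sc + Mpv[(cc - 1L) * 16L + (u - 1L) * 4L + v]
        }
      }
    }
    best <- pmax(best, sc)
  }
  best
}

## strand-aware per-l-mer sliding scores: max of the two strand scores for
## each l-mer of the forward sequence
#' @keywords internal
sliding_scores_both_strands <- function(pssm, codes, lmer_len) {
  fwd <- sliding_scores_genomic(pssm, codes, lmer_len)
  rev_sc <- sliding_scores_genomic(pssm, revcomp_codes(codes), lmer_len)
  pmax(fwd, rev(rev_sc))
}
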