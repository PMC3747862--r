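## Independent brute-force oracles and small fixture builders. These
## deliberately re-derive scores with plain loops so they share no code
## with the vectorised scanners they check.

LETTERS4 <- c("A", "C", "G", "T")

enc <- function(s) match(strsplit(s, "")[[1]], c(LETTERS4, "-"))

rc_string <- function(s) {
  x <- enc(s)
  paste(c(LETTERS4, "-")[rev(c(4:1, 5)[x])], collapse = "")
}

## direct evaluation of the pair-aware window score, gap letters scoring
## the precomputed column/pair minima
bf_score_window <- function(pssm, s) {
  x <- enc(s)
  stopifnot(length(x) == pssm$l)
  tot <- 0
  for (i in seq_along(x))
    tot <- tot + if (x[i] == 5) pssm$gapmin[i] else pssm$M[x[i], i]
  K <- min(pssm$K, length(x) - 1L)
  if (K >= 1) for (k in 1:K) for (i in 1:(length(x) - k)) {
    u <- x[i]; v <- x[i + k]
    tot <- tot + if (u == 5 || v == 5) pssm$gapmin_pair[[k]][i]
                 else pssm$Mpair[[k]][(u - 1) * 4 + v, i]
  }
  tot
}

## exhaustive enumeration of the augmented-sequence sliding score
bf_sliding <- function(pssm, s) {
  l <- pssm$l
  aug <- paste0(strrep("-", l - 1), s, strrep("-", l - 1))
  sc <- vapply(seq_len(l + nchar(s) - 1),
               function(i) bf_score_window(pssm, substr(aug, i, i + l - 1)),
               0)
  list(score = max(sc), offset = which.max(sc), scores = sc)
}

## independent letter/pair counter over alignment rows (pseudocount pc)
bf_frequencies <- function(rows, K, pc, ppc) {
  mats <- lapply(rows, enc)
  l <- length(mats[[1]])
  f1 <- matrix(NA_real_, 4, l)
  for (i in 1:l) {
    cnt <- numeric(4)
    for (m in mats) if (m[i] != 5) cnt[m[i]] <- cnt[m[i]] + 1
    f1[, i] <- (cnt + pc) / (sum(cnt) + 4 * pc)
  }
  fp <- list()
  if (K >= 1) for (k in 1:K) {
    fk <- matrix(NA_real_, 16, l - k)
    for (i in 1:(l - k)) {
      cnt <- numeric(16)
      for (m in mats) if (m[i] != 5 && m[i + k] != 5)
        cnt[(m[i] - 1) * 4 + m[i + k]] <- cnt[(m[i] - 1) * 4 + m[i + k]] + 1
      fk[, i] <- (cnt + ppc) / (sum(cnt) + 16 * ppc)
    }
    fp[[k]] <- fk
  }
  list(f1 = f1, fpair = fp)
}

rand_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(LETTERS4, n, replace = TRUE, prob = prob), collapse = "")
}

rand_sites <- function(n, lmin = 5, lmax = 12) {
  s <- vapply(seq_len(n),
              function(i) rand_seq(seq.int(lmin, lmax)[sample.int(lmax - lmin + 1L, 1)]), "")
  names(s) <- sprintf("r%02d", seq_len(n))
  s
}

## tiny PSSM straight from explicit frequencies (bg uniform)
pssm_from_probs <- function(cols, K = 0, rows = NULL) {
  ## cols: list of length-4 probability vectors
  a <- tfbs_alignment(c(x = paste(rep("A", length(cols)), collapse = "")))
  f <- estimate_frequency_model(a, K = 0, pseudocount = 0.25)
  f$f1 <- do.call(cbind, cols)
  f$bg <- rep(0.25, 4)
  build_pssm(f)
}
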