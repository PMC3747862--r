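test_that("reverse complement handles letters, gaps, and is an involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAAC"), "GTTT")
  expect_equal(reverse_complement("-AC"), "GT-")
  expect_error(reverse_complement("ACGN"), "invalid letter")
  set.seed(7)
  for (i in 1:20) {
    s <- rand_seq(sample(4:15, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("frequency estimation matches an independent counting oracle", {
  rows <- c(a = "ACGG", b = "ACG-", c = "-CGT", d = "AAGT")
  a <- tfbs_alignment(rows)
  f <- estimate_frequency_model(a, K = 2, pseudocount = 0.25,
                                pair_pseudocount = 0.0625)
  bf <- bf_frequencies(rows, K = 2, pc = 0.25, ppc = 0.0625)
  expect_equal(f$f1, bf$f1, tolerance = 1e-12)
  for (k in 1:2) expect_equal(f$fpair[[k]], bf$fpair[[k]], tolerance = 1e-12)

  ## trivial cases, pseudocount 0
  f0 <- estimate_frequency_model(tfbs_alignment(c("ACGT", "ATTA", "AGCC", "ACGG")),
                                 K = 0, pseudocount = 0)
  expect_equal(f0$f1[1, 1], 1.0)  # column 1 all A
  f1 <- estimate_frequency_model(tfbs_alignment(c("AC", "AC")), K = 1,
                                 pseudocount = 0, pair_pseudocount = 0)
  expect_equal(f1$fpair[[1]][(1 - 1) * 4 + 2, 1], 1.0)  # f_{1,2}(A,C) = 1
})

test_that("frequency models are normalised and positive with pseudocounts", {
  set.seed(11)
  for (i in 1:10) {
    a <- lasagna_align(rand_sites(6))
    f <- estimate_frequency_model(a, K = 2)
    expect_equal(colSums(f$f1), rep(1, f$l), tolerance = 1e-9)
    expect_true(all(f$f1 > 0))
    for (k in 1:2)
      expect_equal(colSums(f$fpair[[k]]), rep(1, f$l - k), tolerance = 1e-9)
    expect_equal(sum(f$bg), 1, tolerance = 1e-9)
  }
})

test_that("PSSM scores are log2 odds with precomputed gap minima", {
  ## f_i(u) = f(u) for all u -> scores all zero
  p <- pssm_from_probs(list(rep(0.25, 4), rep(0.25, 4)))
  expect_equal(p$M, matrix(0, 4, 2))
  ## degenerate column: log2(1/0.25) = 2 bits
  p2 <- pssm_from_probs(list(c(1, 0, 0, 0) * 0.997 + 0.001, rep(0.25, 4)))
  expect_equal(p2$M[1, 1], log2((0.998)/0.25), tolerance = 1e-9)
  ## gap minimum is the column minimum
  set.seed(3)
  a <- lasagna_align(rand_sites(5))
  pm <- build_pssm(estimate_frequency_model(a, K = 1))
  expect_equal(pm$gapmin, apply(pm$M, 2, min))
  expect_equal(pm$gapmin_pair[[1]], apply(pm$Mpair[[1]], 2, min))
  ## zero probability demands a pseudocount
  f0 <- estimate_frequency_model(tfbs_alignment(c("AAAA", "AAAA")), K = 0,
                                 pseudocount = 0)
  expect_error(build_pssm(f0), "pseudocount")
})

test_that("window scoring matches the formula term by term", {
  set.seed(21)
  a <- lasagna_align(rand_sites(6, 6, 6))
  pssm <- build_pssm(estimate_frequency_model(a, K = 0))
  w <- rand_seq(pssm$l)
  ## K = 0: classical additive PSSM score, no pair terms
  expect_equal(score_window(pssm, w),
               sum(vapply(seq_len(pssm$l),
                          function(i) pssm$M[enc(w)[i], i], 0)),
               tolerance = 1e-12)
  ## l = 3, K = 2: exactly (3-1) + (3-2) = 3 pair terms
  a3 <- tfbs_alignment(c("ACG", "ACT", "GCG", "TCG"))
  p3 <- build_pssm(estimate_frequency_model(a3, K = 2))
  w3 <- "ACG"; x <- enc(w3)
  single <- sum(p3$M[cbind(x, 1:3)])
  pairs <- p3$Mpair[[1]][(x[1] - 1) * 4 + x[2], 1] +
    p3$Mpair[[1]][(x[2] - 1) * 4 + x[3], 2] +
    p3$Mpair[[2]][(x[1] - 1) * 4 + x[3], 1]
  expect_equal(score_window(p3, w3), single + pairs, tolerance = 1e-12)
  ## gapless window: gap-aware and plain scores agree
  expect_equal(score_window(p3, w3, gap_aware = TRUE), score_window(p3, w3))
  ## length mismatch errors
  expect_error(score_window(p3, "ACGT"), "length")
})

test_that("sliding score equals exhaustive enumeration and counts windows", {
  set.seed(31)
  for (i in 1:25) {
    K <- sample(0:2, 1)
    a <- lasagna_align(rand_sites(5, 6, 9), Ka = K)
    pssm <- build_pssm(estimate_frequency_model(a, K = K))
    s <- rand_seq(12)
    got <- sliding_score(pssm, s)
    bf <- bf_sliding(pssm, s)
    expect_equal(got$score, bf$score, tolerance = 1e-9)
    expect_equal(got$offset, bf$offset)
    expect_equal(got$n_windows, pssm$l + 12 - 1)
    expect_true(all(got$score >= bf$scores))
  }
})

test_that("per-l-mer genomic sliding scores match per-window recomputation", {
  set.seed(41)
  for (K in 0:2) {
    a <- lasagna_align(rand_sites(6, 6, 8), Ka = K)
    pssm <- build_pssm(estimate_frequency_model(a, K = K))
    seq <- rand_seq(60)
    lmer <- 9
    got <- lasagna:::sliding_scores_genomic(pssm, lasagna:::dna_encode(seq), lmer)
    exp <- vapply(seq_len(60 - lmer + 1), function(g)
      bf_sliding(pssm, substr(seq, g, g + lmer - 1))$score, 0)
    expect_equal(got, exp, tolerance = 1e-9)
  }
})

test_that("strand duality: reversed-complemented model scores the mirror window", {
  set.seed(51)
  for (i in 1:5) {
    a <- lasagna_align(rand_sites(5, 7, 7))
    f <- estimate_frequency_model(a, K = 1)
    p <- build_pssm(f)
    ## build the column-reversed, complemented model
    frc <- f
    frc$f1 <- f$f1[4:1, rev(seq_len(f$l))]
    frc$bg <- f$bg[4:1]
    fp <- f$fpair[[1]]
    ## pair (u,v) at (i, i+1) maps to (comp v, comp u) at reversed columns
    fprc <- matrix(NA_real_, 16, ncol(fp))
    for (u in 1:4) for (v in 1:4)
      fprc[(5 - v - 1) * 4 + (5 - u), ] <- fp[(u - 1) * 4 + v, rev(seq_len(ncol(fp)))]
    frc$fpair[[1]] <- fprc
    prc <- build_pssm(frc)
    w <- rand_seq(f$l)
    expect_equal(score_window(p, w),
                 score_window(prc, reverse_complement(w)), tolerance = 1e-9)
  }
})

test_that("column statistics implement coverage and corrected IC", {
  ## equal counts of A,C,G,T at large n: IC clamps to 0
  a <- tfbs_alignment(rep(c("A", "C", "G", "T"), 50))
  st <- column_stats(a)
  expect_equal(st$ic, 0)
  expect_equal(st$coverage, 1)
  ## e-hat(4) = 3 / (2 ln 2 * 4)
  expect_equal(small_sample_correction(4), 3 / (2 * log(2) * 4))
  expect_equal(small_sample_correction(4), 0.541011, tolerance = 1e-6)
  ## bounds on random alignments
  set.seed(61)
  for (i in 1:10) {
    st <- column_stats(lasagna_align(rand_sites(6)))
    expect_true(all(st$ic >= 0 & st$ic <= 2))
    expect_true(all(st$coverage > 0 & st$coverage <= 1))
  }
  ## gap-aware coverage: gaps excluded from counts
  a2 <- tfbs_alignment(c("AC-", "-CA", "ACA"))
  st2 <- column_stats(a2)
  expect_equal(st2$coverage, c(2/3, 1, 2/3))
  expect_equal(st2$n, c(2L, 3L, 2L))
})
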