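test_that("a single site aligns to itself", {
  a <- lasagna_align(c(only = "ACGTAC"))
  expect_equal(a$seqs, "ACGTAC")
  expect_equal(a$width, 6L)
  expect_equal(a$ids, "only")
})

test_that("identical sites stack without gap columns on the forward strand", {
  a <- lasagna_align(stats::setNames(rep("TGACTCAG", 5), paste0("s", 1:5)))
  expect_equal(a$width, 8L)
  expect_true(all(a$seqs == "TGACTCAG"))
  expect_true(all(a$strand == "+"))
})

test_that("input validation mirrors the preconditions", {
  expect_error(lasagna_align(character(0)), "no input")
  expect_error(lasagna_align(c("ACG")), "shorter than 4")
  expect_error(lasagna_align(c("ACGT", "ACGTA"), Ka = 4), "Ka")
  expect_error(lasagna_align(c("AC-T", "ACGT")), "gap-free")
})

test_that("placement agrees with brute force over both strands", {
  set.seed(71)
  for (i in 1:10) {
    seed_site <- rand_seq(8)
    a <- tfbs_alignment(c(seed = seed_site))
    ## uniform background so matching the seed is always optimal (a
    ## site-derived background can legitimately favour the rarer letters
    ## of the reverse-complement)
    pssm <- build_pssm(estimate_frequency_model(a, K = 0,
                                                background = rep(0.25, 4)))
    ## the seed itself places exactly over itself, forward
    pl <- place_site(seed_site, pssm)
    expect_equal(pl$strand, "+")
    expect_equal(pl$offset, bf_sliding(pssm, seed_site)$offset)
    expect_equal(pl$offset, pssm$l)  # interior placement over the seed
    ## its reverse-complement is recognised on the reverse strand
    ## (unless palindromic, when forward is preferred)
    rc <- reverse_complement(seed_site)
    pl2 <- place_site(rc, pssm)
    expect_equal(pl2$score, pl$score, tolerance = 1e-9)
    if (rc != seed_site) expect_equal(pl2$strand, "-")
    ## per strand, exactly l + l_s - 1 windows are evaluated
    s <- rand_seq(11)
    expect_equal(sliding_score(pssm, s)$n_windows, pssm$l + 11 - 1)
  }
})

test_that("the next site is the shortest, best-scoring, earliest", {
  a <- tfbs_alignment(c(seed = "TGACTCAG"))
  pssm <- build_pssm(estimate_frequency_model(a, K = 0))
  ## unique shortest wins regardless of score
  U <- c(x = "AAAATTTTCC", y = "CCCC")
  expect_equal(names(choose_next_site(U, pssm)), "y")
  ## among equally short sites the consensus match wins
  U2 <- c(bad = "CCCCCCCC", good = "TGACTCAG")
  expect_equal(names(choose_next_site(U2, pssm)), "good")
  ## all-equal sites: first in input order
  U3 <- c(first = "GGGGG", second = "GGGGG", third = "GGGGG")
  expect_equal(names(choose_next_site(U3, pssm)), "first")
})

test_that("merging pads rows exactly and conserves sequences", {
  A <- tfbs_alignment(c(a = "ACGTAC"))
  pssm <- build_pssm(estimate_frequency_model(A, K = 0))
  ## interior placement: width unchanged
  pl <- list(score = 0, offset = 6L, strand = "+")  # site col 1
  m1 <- merge_placement(A, "TTTTTT", pl, id = "b")
  expect_equal(m1$width, 6L)
  expect_equal(m1$seqs[2], "TTTTTT")
  ## overhang left by 2: width grows by 2, old rows gain 2 leading gaps
  pl2 <- list(score = 0, offset = 8L, strand = "+")  # site col = 6-8+1 = -1
  m2 <- merge_placement(A, "TTTT", pl2, id = "c")
  expect_equal(m2$width, 8L)
  expect_equal(m2$seqs[1], "--ACGTAC")
  expect_equal(m2$seqs[2], "TTTT----")
  ## reverse-strand merge stores the reverse-complement
  pl3 <- list(score = 0, offset = 6L, strand = "-")
  m3 <- merge_placement(A, "AAATTT", pl3, id = "d")
  expect_equal(m3$seqs[2], "AAATTT")  # palindrome here; check strand flag
  expect_equal(m3$strand[2], "-")
})

test_that("alignment output is rectangular, covered, and conserves every site", {
  set.seed(81)
  for (i in 1:12) {
    sites <- rand_sites(sample(5:12, 1), 4, 14)
    Ka <- sample(0:2, 1)
    a <- lasagna_align(sites, Ka = Ka)
    expect_equal(length(a), length(sites))
    expect_true(all(nchar(a$seqs) == a$width))                      # rectangular
    mat <- lasagna:::alignment_codes(a)
    expect_true(all(colSums(mat != 5L) > 0))                        # no all-gap column
    got <- alignment_sites(a)                                       # strand round-trip
    expect_setequal(names(got), names(sites))
    expect_equal(got[names(sites)], sites)
    ## processing order is non-decreasing in site length
    log <- attr(a, "log")
    expect_true(all(diff(log$length) >= 0))
  }
})

test_that("end trimming removes exactly the uninformative flanks and is idempotent", {
  ## two leftmost columns with coverage 0.25 go; informative core stays
  rows <- c(a = "ACTGACTCAGTT", b = "--TGACTCAG--",
            c = "--TGACTCAG--", d = "--TGACTCAG--")
  a <- tfbs_alignment(rows)
  st <- column_stats(a)
  expect_equal(st$coverage[1:2], c(0.25, 0.25))
  tr <- trim_alignment(a, C_min = 0.4, IC_min = 0)
  expect_equal(tr$width, 8L)
  expect_equal(tr$seqs[2], "TGACTCAG")
  ## idempotent
  tr2 <- trim_alignment(tr, C_min = 0.4, IC_min = 0)
  expect_equal(tr2$seqs, tr$seqs)
  ## all columns passing: unchanged
  b <- tfbs_alignment(c("TGACTCAG", "TGACTCAG", "TGACTAAG"))
  expect_equal(trim_alignment(b)$seqs, b$seqs)
  ## nothing passing: informative error naming both thresholds
  u <- tfbs_alignment(rep(c("AAAA", "CCCC", "GGGG", "TTTT"), 8))
  expect_error(trim_alignment(u, C_min = 0.4, IC_min = 1.9), "IC > 1.9")
})

test_that("planted cores are recovered at a common alignment offset", {
  set.seed(91)
  recov <- vapply(1:3, function(r) {
    pwm <- make_pwm(8, 1.5, seed = 500 + r)
    ss <- sample_site_set(pwm, n = 30, flank_range = c(0, 6),
                          revcomp_prob = 0.2, seed = 600 + r)
    a <- lasagna_align(ss$sites, Ka = 0)
    alignment_core_recovery(a, ss$truth)
  }, 0)
  expect_true(all(recov >= 0.9))
})
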