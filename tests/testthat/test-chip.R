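test_that("peak clipping centres on the signal peak and clamps at bounds", {
  ## already short: returned whole
  s100 <- rand_seq(100)
  expect_equal(unname(clip_to_peak(stats::setNames(s100, "p"))), s100)
  ## 500 bp, point source at offset 250: 0-based offsets 200..299
  set.seed(1)
  s500 <- rand_seq(500)
  pk <- data.frame(name = "p1", peak = 250L, seq = s500)
  expect_equal(unname(clip_to_peak(pk)), substr(s500, 201, 300))
  ## point source at 10: clamped to offsets 0..99
  pk2 <- data.frame(name = "p2", peak = 10L, seq = s500)
  expect_equal(unname(clip_to_peak(pk2)), substr(s500, 1, 100))
  ## -1 point source: midpoint fallback
  pk3 <- data.frame(name = "p3", peak = -1L, seq = s500)
  expect_equal(unname(clip_to_peak(pk3)), substr(s500, 201, 300))
})

test_that("adaptive trimming caps width and enforces positive-IC ends", {
  set.seed(2)
  ## a 30-column peak-like alignment shrinks to at most 15 columns
  pwm <- make_pwm(8, 1.8, seed = 3)
  ss <- sample_site_set(pwm, n = 40, flank_range = c(9, 13), seed = 4)
  A <- lasagna_align(ss$sites, Ka = 0)
  expect_gt(A$width, 15)
  tr <- adaptive_trim(A, max_cols = 15)
  expect_lte(tr$width, 15)
  st <- column_stats(tr)
  expect_gt(st$ic[1], 0)
  expect_gt(st$ic[tr$width], 0)
  ## an alignment whose end columns carry no information loses them:
  ## flanks of pure 25/25/25/25 columns at full coverage
  base <- c("ACGT", "CGTA", "GTAC", "TACG")
  rows <- paste0(rep(base, 5), "TGACTCAG", rep(rev(base), 5))
  tr2 <- adaptive_trim(tfbs_alignment(rows), max_cols = 15)
  st2 <- column_stats(tr2)
  expect_gt(st2$ic[1], 0)
  expect_gt(st2$ic[tr2$width], 0)
  ## small alignments (<= 2 rows) pass through untouched
  small <- tfbs_alignment(c("ACGTACGT", "ACGTACGT"))
  expect_equal(adaptive_trim(small)$seqs, small$seqs)
})

test_that("refinement converges under the unchanged-IC rule", {
  set.seed(5)
  pwm <- make_pwm(8, 1.7, seed = 6)
  ps <- sample_peak_set(pwm, n = 40, peak_len_range = c(100, 150),
                        jitter = 10, seed = 7)
  seqs <- clip_to_peak(ps$peaks)
  A <- lasagna:::progressive_align(seqs, Ka = 0, tie_sample = 5,
                                   per_iter_trim = TRUE)
  R <- refine_alignment(A, seqs, Ka = 0)
  expect_true(attr(R, "converged"))
  expect_gte(attr(R, "ic"), 0)
  tr <- attr(R, "trimmed")
  expect_lte(tr$width, 15)
  ## refinement does not lose information relative to the initial alignment
  expect_gte(attr(R, "ic") + 1e-6,
             sum(column_stats(adaptive_trim(A, 15))$ic) * 0.9)
  ## a single sequence converges immediately to itself
  one <- seqs[1]
  R1 <- refine_alignment(tfbs_alignment(one), one, Ka = 0)
  expect_equal(strip_ws <- gsub("-", "", R1$seqs), unname(one))
})

test_that("the ChIP pipeline is seed-deterministic and finds the planted core", {
  pwm <- make_pwm(8, 1.6, seed = 8)
  cons <- paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)], collapse = "")
  ps <- sample_peak_set(pwm, n = 60, peak_len_range = c(100, 200),
                        jitter = 20, seed = 9)
  A1 <- lasagna_chip(ps$peaks, Ka_range = 0:1, n_seeds = 3, seed = 10)
  A2 <- lasagna_chip(ps$peaks, Ka_range = 0:1, n_seeds = 3, seed = 10)
  expect_identical(A1$seqs, A2$seqs)
  expect_identical(attr(A1, "Ka"), attr(A2, "Ka"))
  ## consensus contains the planted 8-mer or its reverse-complement
  got <- consensus(A1)
  expect_true(grepl(cons, got, fixed = TRUE) ||
              grepl(reverse_complement(cons), got, fixed = TRUE))
  ## candidate selection is argmax over summed IC
  cand <- attr(A1, "candidates")
  expect_equal(nrow(cand), 2 * 3)
  expect_true(all(cand$ic <= attr(A1, "ic") + 1e-9))
  ## structural contract
  expect_lte(A1$width, 15)
  st <- column_stats(A1)
  expect_gt(st$ic[1], 0); expect_gt(st$ic[A1$width], 0)
})

test_that("equal-length peaks are handled (all sites exactly 100 bp)", {
  pwm <- make_pwm(8, 1.6, seed = 11)
  ps <- sample_peak_set(pwm, n = 30, peak_len_range = c(100, 100),
                        jitter = 5, seed = 12)
  seqs <- clip_to_peak(ps$peaks)
  expect_true(all(nchar(seqs) == 100))
  A <- lasagna_chip(ps$peaks, Ka_range = 0, n_seeds = 2, seed = 13)
  expect_lte(A$width, 15)
  expect_equal(length(A), 30)
})
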