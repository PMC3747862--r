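test_that("the Markov background is stochastic, seeded, and learnable", {
  set.seed(31)
  train <- vapply(1:5, function(i) rand_seq(500, prob = c(0.4, 0.1, 0.1, 0.4)), "")
  chain <- train_markov_background(train)
  expect_equal(unname(rowSums(chain$trans)), rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(chain$init), 1, tolerance = 1e-12)
  ## simulated length and determinism
  s <- simulate_markov(chain, length = 2000, seed = 32)
  expect_equal(nchar(s), 2000L)
  expect_identical(s, simulate_markov(chain, length = 2000, seed = 32))
  ## law of large numbers: long-run dinucleotide frequencies match the chain
  long <- simulate_markov(chain, length = 1e6, seed = 33)
  x <- match(strsplit(long, "")[[1]], c("A", "C", "G", "T"))
  tab <- matrix(tabulate((x[-length(x)] - 1) * 4 + x[-1], 16), 4, 4, byrow = TRUE)
  emp <- tab / rowSums(tab)
  expect_true(max(abs(emp - chain$trans)) < 0.01)
})

test_that("planting substitutes the site at a recoverable interval", {
  set.seed(34)
  bg <- rand_seq(2000)
  site <- "TGACTCAGTT"
  pl <- plant_site(bg, site, seed = 35)
  expect_equal(nchar(pl$seq), 2000L)
  expect_equal(substr(pl$seq, pl$start, pl$end), site)
  ## fixed position honoured
  pl2 <- plant_site(bg, site, position = 100)
  expect_equal(pl2$start, 100L)
  ## planted positions are uniform across seeded draws
  pos <- vapply(1:2000, function(i) plant_site(bg, site, seed = i)$start, 0L)
  breaks <- seq(1, 2000 - nchar(site) + 2, length.out = 11)
  chi <- stats::chisq.test(table(cut(pos, breaks)))
  expect_gt(chi$p.value, 0.01)
})

test_that("fold assignment balances sizes and partitions the sites", {
  f10 <- cv_split(10, 10, seed = 36)
  expect_equal(sort(unique(f10)), 1:10)
  expect_true(all(table(f10) == 1))
  f23 <- cv_split(23, 10, seed = 37)
  sz <- as.vector(table(f23))
  expect_equal(sort(sz), c(rep(2, 7), rep(3, 3)))   # floor(2.3) and floor(2.3)+1
  expect_equal(length(f23), 23L)
  expect_error(cv_split(5, 10), "at least")
})

test_that("hit definitions follow the printed overlap rules", {
  ## fixed-length: l = 8, overlap 5 is a hit, overlap 4 is not
  expect_true(is_hit_fixed(1, 8, 4, 11, l = 8))     # overlap 5 > 4
  expect_false(is_hit_fixed(1, 8, 5, 12, l = 8))    # overlap 4
  expect_true(is_hit_fixed(3, 10, 3, 10, l = 8))    # identical
  ## variable-length: short predictions must be embedded
  expect_true(is_hit_variable(4, 6, 1, 10))         # l=3 inside l_s=10
  expect_false(is_hit_variable(9, 11, 1, 10))       # 2-base edge overlap
  expect_true(is_hit_variable(1, 10, 1, 10))        # l = l_s identical
  expect_true(is_hit_variable(2, 9, 1, 10))         # l=8 > 5: overlap 8 > 5
})

test_that("ranks count ties against the site and match a sorting oracle", {
  expect_equal(rank_of_site(5, c(1, 2, 3)), 1L)
  expect_equal(rank_of_site(5, c(5, 5, 5, 1)), 4L)  # 3 exact ties -> rank 4
  set.seed(38)
  for (i in 1:20) {
    ns <- stats::rnorm(50)
    t <- stats::rnorm(1)
    expect_equal(rank_of_site(t, ns), 1L + sum(sort(ns, decreasing = TRUE) >= t))
  }
})

test_that("ROC/AUC reduce to known identities and the Mann-Whitney statistic", {
  ## perfect separation
  expect_equal(roc_auc(rep(1L, 20), 100)$auc, 1.0)
  ## uniform ranks: AUC near 1/2
  set.seed(39)
  ranks <- sample.int(1000, 10000, replace = TRUE)
  expect_equal(roc_auc(ranks, 1000)$auc, 0.5, tolerance = 0.02)
  ## one common non-site set: AUC equals the Mann-Whitney U statistic
  for (i in 1:5) {
    pos <- stats::rnorm(30, mean = 0.5)
    neg <- stats::rnorm(200)
    ranks <- vapply(pos, rank_of_site, 0L, nonsite_scores = neg)
    u <- stats::wilcox.test(pos, neg)$statistic
    expect_equal(roc_auc(ranks, length(neg))$auc,
                 unname(u) / (length(pos) * length(neg)), tolerance = 1e-12)
  }
  ## AUC is invariant under strictly monotone score transforms
  pos <- stats::rnorm(20); neg <- stats::rnorm(50)
  r1 <- vapply(pos, rank_of_site, 0L, nonsite_scores = neg)
  r2 <- vapply(exp(pos), rank_of_site, 0L, nonsite_scores = exp(neg))
  expect_identical(r1, r2)
})

test_that("precision and F-beta follow the printed formulas", {
  ## no false positives: precision 1
  expect_equal(precision_recall_fbeta(10, 0.8, 0)$precision, 1)
  ## precision = recall = x implies F_beta = x
  for (x in c(0.2, 0.5, 0.9)) {
    pf <- 10 * x * (1 - x) / x   # p_F making precision equal x
    res <- precision_recall_fbeta(10, x, pf)
    expect_equal(res$precision, x, tolerance = 1e-12)
    expect_equal(res$f_beta, x, tolerance = 1e-12)
  }
  ## direct evaluation: precision 1, recall 0.5, beta 0.5
  expect_equal(precision_recall_fbeta(10, 0.5, 0)$f_beta, 0.625 / 0.75,
               tolerance = 1e-12)
  expect_error(precision_recall_fbeta(10, 0, 0), "undefined")
})

test_that("cross-validation discriminates a strong planted motif", {
  pwm <- make_pwm(8, 1.6, seed = 40)
  ss <- sample_site_set(pwm, n = 30, seed = 41)
  cv <- cv_evaluate(ss$sites, Ks = 0, seed = 42)
  expect_gt(cv$auc, 0.95)
  expect_true(all(cv$ranks >= 1))
  ## determinism under fixed seeds
  cv2 <- cv_evaluate(ss$sites, Ks = 0, seed = 42)
  expect_identical(cv$ranks, cv2$ranks)
  ## every scored window lands in exactly one of H and N
  expect_true(all(cv$n_nonsites + 1 <=
                  2000 - nchar(ss$sites)[names(ss$sites)] + 1))
})

test_that("the scope grid search never falls below the K = 0 operating point", {
  pwm <- make_pwm(7, 1.5, seed = 43)
  ss <- sample_site_set(pwm, n = 20, flank_range = c(0, 3), seed = 44)
  cv <- cv_evaluate(ss$sites, Ks = c(0L, 1L), seed = 45)
  expect_gte(cv$auc, cv$auc_by_K$auc[cv$auc_by_K$K == 0])
  expect_true(cv$Ks %in% c(0L, 1L))
})
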