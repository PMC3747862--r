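#' Train a first-order Markov background model
#'
#' Transition probabilities from dinucleotide counts (with a pseudocount)
#' over a set of training sequences; the initial distribution is the
#' pooled mononucleotide frequency.
#'
#' @param seqs character vector of DNA sequences (gap-free).
#' @param pseudocount additive pseudocount per transition cell.
#' @return an object of class `markov_chain` with `trans` (4 x 4
#'   row-stochastic matrix), `init` (length 4) and `order = 1`.
#' @export
train_markov_background <- function(seqs, pseudocount = 1) {
  stopifnot(length(seqs) >= 1L)
  cnt <- matrix(pseudocount, 4L, 4L, dimnames = list(DNA_LETTERS, DNA_LETTERS))
  mono <- rep(pseudocount, 4L)
  for (s in seqs) {
    codes <- dna_encode(s)
    if (any(codes == GAP_CODE)) stop("background training sequences must be gap-free")
    mono <- mono + tabulate(codes, nbins = 4L)
    if (length(codes) >= 2L) {
      pair <- tabulate((codes[-length(codes)] - 1L) * 4L + codes[-1L], nbins = 16L)
      cnt <- cnt + matrix(pair, 4L, 4L, byrow = TRUE)
    }
  }
  structure(list(trans = cnt / rowSums(cnt), init = mono / sum(mono),
                 order = 1L), class = "markov_chain")
}

#' Uniform i.i.d. background as a degenerate Markov chain
#' @return a `markov_chain` with uniform transitions.
#' @export
uniform_background <- function() {
  structure(list(trans = matrix(0.25, 4L, 4L,
                                dimnames = list(DNA_LETTERS, DNA_LETTERS)),
                 init = rep(0.25, 4L), order = 1L),
            class = "markov_chain")
}

#' Simulate a sequence from a Markov background
#'
#' @param chain a [train_markov_background()] result.
#' @param length number of bases (default 2000, the planting length used
#'   throughout the cross-validation protocol).
#' @param seed optional RNG seed (deterministic given the seed).
#' @return a DNA string.
#' @export
simulate_markov <- function(chain, length = 2000L, seed = NULL) {
  stopifnot(inherits(chain, "markov_chain"), length >= 1L)
  with_seed(seed, {
    codes <- integer(length)
    codes[1L] <- sample.int(4L, 1L, prob = chain$init)
    ## vectorised inverse-CDF walk: one uniform per step
    cum <- t(apply(chain$trans, 1L, cumsum))
    u <- stats::runif(length - 1L)
    for (i in seq_len(length - 1L))
      codes[i + 1L] <- findInterval(u[i], cum[codes[i], ], left.open = TRUE) + 1L
    dna_decode(codes)
  })
}

#' Plant a binding site in a background sequence
#'
#' Substitutes `site` at a uniformly random (or given) position of
#' `background` and returns the sequence plus the true interval.
#'
#' @param background DNA string.
#' @param site DNA string, `nchar(site) <= nchar(background)`.
#' @param position optional 1-based start; random uniform when `NULL`.
#' @param seed optional RNG seed for the position draw.
#' @return list with `seq`, `start`, `end` (1-based closed).
#' @export
plant_site <- function(background, site, position = NULL, seed = NULL) {
  lb <- nchar(background); ls <- nchar(site)
  stopifnot(ls <= lb)
  pos <- if (!is.null(position)) as.integer(position)
         else with_seed(seed, sample.int(lb - ls + 1L, 1L))
  stopifnot(pos >= 1L, pos + ls - 1L <= lb)
  seq <- paste0(substr(background, 1L, pos - 1L), toupper(site),
                substr(background, pos + ls, lb))
  list(seq = seq, start = pos, end = pos + ls - 1L)
}

#' Seeded cross-validation fold assignment
#'
#' Random partition of `n` items into `nu` folds whose sizes are
#' `floor(n/nu)` or `floor(n/nu) + 1`.
#'
#' @param n number of items.
#' @param nu number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold labels `1..nu`.
#' @export
cv_split <- function(n, nu = 10L, seed = 1L) {
  if (n < nu) stop(sprintf("need at least %d items for %d folds", nu, nu))
  sizes <- rep(n %/% nu, nu)
  extra <- n %% nu
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, sample(rep.int(seq_len(nu), sizes)))
}

#' Hit test for fixed-length window predictions
#'
#' A scored l-mer window is a hit if it shares more than `floor(l/2)`
#' bases with the true site, `l` being the window length.
#'
#' @param window_start,window_end predicted window (1-based closed).
#' @param true_start,true_end true site interval.
#' @param l window length.
#' @return logical (vectorised over windows).
#' @export
is_hit_fixed <- function(window_start, window_end, true_start, true_end,
                         l = window_end - window_start + 1L) {
  ov <- pmin(window_end, true_end) - pmax(window_start, true_start) + 1L
  ov > l %/% 2L
}

#' Hit test for variable-length predictions
#'
#' A predicted site of length `l` hits a true site of length `l_s` if the
#' overlap exceeds `floor(l_s/2)` bases; when that is impossible
#' (`l <= floor(l_s/2)`) the prediction must be embedded in the true site.
#'
#' @param pred_start,pred_end predicted interval (1-based closed).
#' @param true_start,true_end true site interval.
#' @return logical (vectorised).
#' @export
is_hit_variable <- function(pred_start, pred_end, true_start, true_end) {
  l <- pred_end - pred_start + 1L
  ls <- true_end - true_start + 1L
  ov <- pmin(pred_end, true_end) - pmax(pred_start, true_start) + 1L
  ifelse(l > ls %/% 2L, ov > ls %/% 2L,
         pred_start >= true_start & pred_end <= true_end)
}

#' Rank of a test site among non-site scores
#'
#' `1 +` the number of non-site scores greater than or equal to the test
#' site's score (ties count against the site).
#'
#' @param t_score score of the test site.
#' @param nonsite_scores numeric vector of non-site window scores.
#' @return integer rank (>= 1).
#' @export
rank_of_site <- function(t_score, nonsite_scores) {
  1L + sum(nonsite_scores >= t_score)
}

#' Pooled ROC curve and AUC from per-site ranks
#'
#' Each test site contributes the false-positive rate at which it is
#' recovered, `(rank - 1) / n_nonsites`; the ROC staircase pools these
#' across sites and the AUC is the area under the staircase (trapezoid on
#' its vertices, which is exact for a step function).
#'
#' @param ranks integer vector of per-site ranks.
#' @param n_nonsites per-site non-site counts (recycled).
#' @return list with `auc` and `points` (data.frame `fpr`, `tpr`).
#' @export
roc_auc <- function(ranks, n_nonsites) {
  n <- length(ranks)
  stopifnot(n >= 1L)
  fpr_at <- sort((ranks - 1) / rep_len(n_nonsites, n))
  ## staircase vertices: (fpr, tpr) jumps at each site's recovery fpr
  pts <- data.frame(fpr = c(0, rep(fpr_at, each = 2L), 1),
                    tpr = c(0, rep((seq_len(n) - 1L) / n, each = 2L)[-1L],
                            1, 1))
  auc <- mean(1 - fpr_at)
  list(auc = auc, points = pts)
}

#' Precision and F-beta from recall and false-positive count
#'
#' With `n` true sites and recall `r`, the number recovered is
#' `p_T = n r`; precision is `p_T / (p_T + p_F)` and
#' `F_beta = (1 + beta^2) precision * recall / (beta^2 precision + recall)`.
#' `beta = 0.5` weights precision twice as much as recall.
#'
#' @param n number of true sites.
#' @param r recall.
#' @param p_F number of false positives.
#' @param beta weighting (default 0.5).
#' @return list with `precision` and `f_beta`.
#' @export
precision_recall_fbeta <- function(n, r, p_F, beta = 0.5) {
  p_T <- n * r
  if (p_T + p_F == 0) stop("no predictions: precision is undefined")
  precision <- p_T / (p_T + p_F)
  f <- if (precision + r == 0) 0
       else (1 + beta^2) * precision * r / (beta^2 * precision + r)
  list(precision = precision, f_beta = f)
}

#' Cross-validated search performance of the aligner's PSSMs
#'
#' The evaluation protocol for one TF: sites are split into `nu` seeded
#' folds; per fold, the training sites are aligned (`Ka = Ks`), trimmed
#' (`C_min = 0.4`, `IC_min = 0`), and turned into a PSSM; each held-out
#' site is planted at a random position in a fresh 2000-base background
#' simulated from a first-order Markov chain and every l-mer of that
#' sequence (`l` = test-site length) is given the higher of its two strand
#' sliding scores against the PSSM. Windows overlapping the planted site
#' by more than `floor(l/2)` bases form the hit set; the site's score is
#' the best hit score and its rank counts the non-site windows scoring at
#' least as high. Ranks pool into a ROC curve and AUC.
#'
#' When `Ks = "auto"`, the scope is grid-searched over
#' `0..min(10, l_min - 1)` on identical folds and planted sequences and
#' the AUC-maximising value is returned.
#'
#' @param sites named character vector of one TF's binding sites (>= `nu`).
#' @param Ks scope (single integer), `"auto"`, or an integer vector to
#'   grid-search.
#' @param nu number of folds (default 10).
#' @param background a `markov_chain` (default: uniform).
#' @param seed RNG seed governing folds and planted backgrounds.
#' @param bg_length planting background length (default 2000).
#' @param C_min,IC_min pre-PSSM trimming thresholds. Should trimming
#'   reject every column (possible for information-free training sets),
#'   the untrimmed alignment is used, with a warning.
#' @param pseudocount,pair_pseudocount frequency-model pseudocounts.
#' @return object of class `lasagna_cv`: per-site `ranks`, `n_nonsites`,
#'   `scores`, `fold`, the pooled `auc` and `roc` points, the chosen `Ks`
#'   and (for grids) `auc_by_K`.
#' @export
cv_evaluate <- function(sites, Ks = 0L, nu = 10L, background = NULL,
                        seed = 1L, bg_length = 2000L,
                        C_min = 0.4, IC_min = 0,
                        pseudocount = 0.25, pair_pseudocount = 0.0625) {
  n <- length(sites)
  if (n < nu) stop(sprintf("a TF needs at least %d sites for %d-fold CV", nu, nu))
  if (is.null(background)) background <- uniform_background()
  stopifnot(inherits(background, "markov_chain"))
  lmin <- min(nchar(sites))
  if (identical(Ks, "auto")) Ks <- 0:min(10L, lmin - 1L)
  Ks <- as.integer(Ks)
  stopifnot(all(Ks >= 0L), all(Ks < lmin))

  fold <- cv_split(n, nu, seed = derive_seed(seed, 1))
  ## planted backgrounds are fixed across K so the grid compares like with
  ## like: one simulated sequence and planting position per test site
  planted <- lapply(seq_len(n), function(i) {
    bg <- simulate_markov(background, length = bg_length,
                          seed = derive_seed(seed, 2, i))
    plant_site(bg, sites[i], seed = derive_seed(seed, 3, i))
  })

  eval_K <- function(K) {
    ranks <- integer(n); nnon <- integer(n); tscore <- numeric(n)
    for (f in seq_len(nu)) {
      train <- sites[fold != f]
      A <- lasagna_align(train, Ka = K, pseudocount = pseudocount,
                         pair_pseudocount = pair_pseudocount)
      bg <- attr(A, "background")   # pooled letters of all training sites
      ## an information-free training set can fail every column; score
      ## with the untrimmed alignment rather than aborting the whole CV
      A <- tryCatch(trim_alignment(A, C_min = C_min, IC_min = IC_min),
                    error = function(e) {
                      warning("trimming rejected every column; using the untrimmed alignment")
                      A
                    })
      K_eff <- min(K, A$width - 1L)
      pssm <- build_pssm(estimate_frequency_model(
        A, K = K_eff, pseudocount = pseudocount,
        pair_pseudocount = pair_pseudocount, background = bg))
      for (i in which(fold == f)) {
        pl <- planted[[i]]
        l <- nchar(sites[i])
        codes <- dna_encode(pl$seq)
        sc <- sliding_scores_both_strands(pssm, codes, l)
        w_start <- seq_along(sc)
        hit <- is_hit_fixed(w_start, w_start + l - 1L, pl$start, pl$end, l = l)
        tscore[i] <- max(sc[hit])
        nnon[i] <- sum(!hit)
        ranks[i] <- rank_of_site(tscore[i], sc[!hit])
      }
    }
    list(ranks = ranks, n_nonsites = nnon, scores = tscore)
  }

  if (length(Ks) == 1L) {
    res <- eval_K(Ks)
    roc <- roc_auc(res$ranks, res$n_nonsites)
    out <- list(ranks = res$ranks, n_nonsites = res$n_nonsites,
                scores = res$scores, fold = fold, auc = roc$auc,
                roc = roc$points, Ks = Ks, auc_by_K = NULL)
  } else {
    per <- lapply(Ks, eval_K)
    aucs <- vapply(per, function(r) roc_auc(r$ranks, r$n_nonsites)$auc, 0)
    bi <- which.max(aucs)
    roc <- roc_auc(per[[bi]]$ranks, per[[bi]]$n_nonsites)
    out <- list(ranks = per[[bi]]$ranks, n_nonsites = per[[bi]]$n_nonsites,
                scores = per[[bi]]$scores, fold = fold, auc = roc$auc,
                roc = roc$points, Ks = Ks[bi],
                auc_by_K = data.frame(K = Ks, auc = aucs))
  }
  class(out) <- "lasagna_cv"
  out
}

#' @export
print.lasagna_cv <- function(x, ...) {
  cat(sprintf("%d-site cross-validated PSSM search: AUC = %.4f (Ks = %d)\n",
              length(x$ranks), x$auc, x$Ks))
  if (!is.null(x$auc_by_K)) {
    cat("scope grid:\n")
    print(x$auc_by_K, row.names = FALSE)
  }
  invisible(x)
}
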