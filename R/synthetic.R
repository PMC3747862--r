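#' Generate a random PWM with a target per-column information content
#'
#' Each column starts from a Dirichlet(1,1,1,1) draw and is tempered
#' (`p^beta`, renormalised) with `beta` solved so the column's information
#' content `2 + sum p log2 p` matches `ic_per_column`. Targets of 0 and 2
#' give exactly uniform and degenerate columns.
#'
#' @param length number of columns.
#' @param ic_per_column target IC per column in bits, in `[0, 2]`.
#' @param seed RNG seed.
#' @return a 4 x `length` column-stochastic matrix (rows A,C,G,T) of class
#'   `matrix`.
#' @export
make_pwm <- function(length, ic_per_column = 1.5, seed = 1L) {
  if (ic_per_column > 2 || ic_per_column < 0)
    stop("per-column information content must lie in [0, 2] bits")
  col_ic <- function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0))
  with_seed(seed, {
    pwm <- matrix(0, 4L, length, dimnames = list(DNA_LETTERS, NULL))
    for (j in seq_len(length)) {
      p0 <- stats::rexp(4L); p0 <- p0 / sum(p0)
      if (ic_per_column == 0) { pwm[, j] <- rep(0.25, 4L); next }
      if (ic_per_column == 2) { pwm[which.max(p0), j] <- 1; next }
      ## scale by the maximum before powering so large exponents cannot
      ## underflow every entry at once
      p0 <- p0 / max(p0)
      temper <- function(beta) { q <- p0^beta; q / sum(q) }
      hi <- 1
      while (col_ic(temper(hi)) < ic_per_column && hi < 1e4) hi <- hi * 2
      beta <- stats::uniroot(function(b) col_ic(temper(b)) - ic_per_column,
                             c(0, hi), tol = 1e-10)$root
      pwm[, j] <- temper(beta)
    }
    pwm
  })
}

## one core draw from the pwm, as a code vector
sample_core <- function(pwm) {
  vapply(seq_len(ncol(pwm)), function(j)
    sample.int(4L, 1L, prob = pwm[, j]), 0L)
}

#' Sample a planted-motif binding-site set with ground truth
#'
#' Emulates database binding-site entries: a conserved core drawn from
#' `pwm`, flanked on each side by i.i.d. background bases of random
#' length, the whole site reverse-complemented with probability
#' `revcomp_prob`. Ground truth (core interval within each site, strand,
#' flank lengths) is recorded so alignment recovery and search AUC can be
#' measured without external data.
#'
#' @param pwm a [make_pwm()] matrix.
#' @param n number of sites.
#' @param flank_range length-2 integer range of per-side flank lengths.
#' @param revcomp_prob probability a site is stored reverse-complemented.
#' @param background length-4 flank letter distribution (default uniform).
#' @param seed RNG seed; the output is a pure function of seed and
#'   parameters.
#' @return list of class `synthetic_sites`: `sites` (named character),
#'   `truth` (data.frame `id`, `core_start`, `core_end`, `strand`), `pwm`,
#'   `seed`.
#' @export
sample_site_set <- function(pwm, n = 30L, flank_range = c(0L, 6L),
                            revcomp_prob = 0.2,
                            background = rep(0.25, 4L), seed = 1L) {
  with_seed(seed, {
    w <- ncol(pwm)
    sites <- character(n)
    truth <- data.frame(id = sprintf("site_%03d", seq_len(n)),
                        core_start = integer(n), core_end = integer(n),
                        strand = character(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      fl <- sample_range(flank_range[1L], flank_range[2L], 2L)
      core <- sample_core(pwm)
      left <- if (fl[1L] > 0) sample.int(4L, fl[1L], TRUE, prob = background) else integer(0)
      right <- if (fl[2L] > 0) sample.int(4L, fl[2L], TRUE, prob = background) else integer(0)
      codes <- c(left, core, right)
      cs <- fl[1L] + 1L; ce <- fl[1L] + w
      strand <- "+"
      if (stats::runif(1) < revcomp_prob) {
        ls <- length(codes)
        codes <- revcomp_codes(codes)
        cs2 <- ls - ce + 1L; ce <- ls - cs + 1L; cs <- cs2
        strand <- "-"
      }
      sites[i] <- dna_decode(codes)
      truth$core_start[i] <- cs; truth$core_end[i] <- ce
      truth$strand[i] <- strand
    }
    names(sites) <- truth$id
    structure(list(sites = sites, truth = truth, pwm = pwm, seed = seed),
              class = "synthetic_sites")
  })
}

#' Sample a site set whose core has strong adjacent-pair dependence
#'
#' Generates cores from a first-order dependency chain: the first core
#' letter is drawn from a weakly informative column distribution, and each
#' subsequent letter copies a fixed per-position permutation of its left
#' neighbour with probability `coupling`, otherwise draws from its own
#' column distribution. Marginal column frequencies stay weakly
#' informative (`marginal_ic` bits) while adjacent positions carry strong
#' mutual information — the regime where pair scores (scope K >= 1) see
#' structure that single-letter scores cannot.
#'
#' @param core_len core width.
#' @param n number of sites.
#' @param coupling probability a core letter is the permuted copy of its
#'   left neighbour (default 0.9).
#' @param marginal_ic per-column IC of the column distributions in bits
#'   (default 0.3; kept low so the signal is in the pairs).
#' @param flank_range,revcomp_prob,background as in [sample_site_set()].
#' @param seed RNG seed.
#' @return list of class `synthetic_sites` (as [sample_site_set()]); the
#'   `pwm` element holds the column distributions, `perms` the coupling
#'   permutations.
#' @export
sample_dependent_site_set <- function(core_len = 8L, n = 30L, coupling = 0.9,
                                      marginal_ic = 0.3,
                                      flank_range = c(0L, 6L),
                                      revcomp_prob = 0.2,
                                      background = rep(0.25, 4L), seed = 1L) {
  pwm <- make_pwm(core_len, marginal_ic, seed = derive_seed(seed, 91))
  with_seed(seed, {
    perms <- lapply(seq_len(core_len - 1L), function(j) sample(4L))
    sites <- character(n)
    truth <- data.frame(id = sprintf("site_%03d", seq_len(n)),
                        core_start = integer(n), core_end = integer(n),
                        strand = character(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      core <- integer(core_len)
      core[1L] <- sample.int(4L, 1L, prob = pwm[, 1L])
      for (j in 2:core_len)
        core[j] <- if (stats::runif(1) < coupling) perms[[j - 1L]][core[j - 1L]]
                   else sample.int(4L, 1L, prob = pwm[, j])
      fl <- sample_range(flank_range[1L], flank_range[2L], 2L)
      left <- if (fl[1L] > 0) sample.int(4L, fl[1L], TRUE, prob = background) else integer(0)
      right <- if (fl[2L] > 0) sample.int(4L, fl[2L], TRUE, prob = background) else integer(0)
      codes <- c(left, core, right)
      cs <- fl[1L] + 1L; ce <- fl[1L] + core_len
      strand <- "+"
      if (stats::runif(1) < revcomp_prob) {
        ls <- length(codes)
        codes <- revcomp_codes(codes)
        cs2 <- ls - ce + 1L; ce <- ls - cs + 1L; cs <- cs2
        strand <- "-"
      }
      sites[i] <- dna_decode(codes)
      truth$core_start[i] <- cs; truth$core_end[i] <- ce
      truth$strand[i] <- strand
    }
    names(sites) <- truth$id
    structure(list(sites = sites, truth = truth, pwm = pwm, perms = perms,
                   seed = seed),
              class = "synthetic_sites")
  })
}

#' Shuffle each site's letters (motif-destroying negative control)
#'
#' @param sites named character vector.
#' @param seed RNG seed.
#' @return named character vector of per-site letter permutations.
#' @export
shuffle_sites <- function(sites, seed = 1L) {
  with_seed(seed, {
    out <- vapply(sites, function(s) dna_decode(sample(dna_encode(s))), "")
    names(out) <- names(sites)
    out
  })
}

#' Sample a planted-motif ChIP-seq peak set with ground truth
#'
#' Each peak is a background sequence of random length carrying one motif
#' instance (random strand); the recorded point source sits within
#' `jitter` bases of the motif midpoint, emulating the offset between a
#' called signal peak and the actual binding site.
#'
#' @param pwm a [make_pwm()] matrix.
#' @param n number of peaks.
#' @param peak_len_range length-2 range of peak lengths.
#' @param jitter maximal distance (bases) between motif midpoint and the
#'   recorded point source.
#' @param background length-4 letter distribution.
#' @param seed RNG seed.
#' @return list of class `synthetic_peaks`: `peaks` (a narrowPeak-shaped
#'   data.frame with a `seq` column; each peak is its own contig), `truth`
#'   (data.frame `id`, `motif_start`, `motif_end`, `strand`, 1-based
#'   within the peak sequence), `pwm`, `seed`.
#' @export
sample_peak_set <- function(pwm, n = 300L, peak_len_range = c(100L, 400L),
                            jitter = 30L, background = rep(0.25, 4L),
                            seed = 1L) {
  with_seed(seed, {
    w <- ncol(pwm)
    stopifnot(peak_len_range[1L] >= w)
    ids <- sprintf("peak_%04d", seq_len(n))
    seqs <- character(n)
    ms <- integer(n); me <- integer(n); strand <- character(n)
    point <- integer(n); lens <- integer(n)
    for (i in seq_len(n)) {
      len <- sample_range(peak_len_range[1L], peak_len_range[2L])
      codes <- sample.int(4L, len, TRUE, prob = background)
      start <- sample.int(len - w + 1L, 1L)
      core <- sample_core(pwm)
      strand[i] <- if (stats::runif(1) < 0.5) "-" else "+"
      if (strand[i] == "-") core <- revcomp_codes(core)
      codes[start:(start + w - 1L)] <- core
      mid <- start + w %/% 2L
      p <- mid + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      point[i] <- min(max(1L, p), len)
      seqs[i] <- dna_decode(codes)
      ms[i] <- start; me[i] <- start + w - 1L; lens[i] <- len
    }
    peaks <- data.frame(chrom = ids, start = 0L, end = lens, name = ids,
                        score = 0L, strand = ".", signalValue = 1,
                        pValue = -1, qValue = -1, peak = point - 1L,
                        seq = seqs, stringsAsFactors = FALSE)
    truth <- data.frame(id = ids, motif_start = ms, motif_end = me,
                        strand = strand, stringsAsFactors = FALSE)
    structure(list(peaks = peaks, truth = truth, pwm = pwm, seed = seed),
              class = "synthetic_peaks")
  })
}

#' Fraction of sites aligned at the planted core position
#'
#' Maps every aligned row's planted core interval (from the generator's
#' ground truth) into alignment columns, accounting for both the
#' generator's strand and the aligner's strand choice, and reports the
#' fraction of sites whose core lands on the modal core columns in the
#' modal orientation.
#'
#' @param alignment a [tfbs_alignment()] of the generated sites.
#' @param truth the `truth` data.frame of [sample_site_set()].
#' @return fraction in `[0, 1]`.
#' @export
alignment_core_recovery <- function(alignment, truth) {
  idx <- match(alignment$ids, truth$id)
  stopifnot(!anyNA(idx))
  lead_gaps <- nchar(alignment$seqs) - nchar(sub("^-+", "", alignment$seqs))
  site_len <- nchar(strip_gaps(alignment$seqs))
  cs <- truth$core_start[idx]; ce <- truth$core_end[idx]
  flipped <- alignment$strand == "-"   # row stored as revcomp of input site
  cs2 <- ifelse(flipped, site_len - ce + 1L, cs)
  ## stored row carries the pwm-forward core iff generator strand and the
  ## aligner's flip cancel out
  pwm_fwd <- (truth$strand[idx] == "+") != flipped
  core_col <- lead_gaps + cs2
  key <- paste(core_col, ifelse(pwm_fwd, "fwd", "rev"))
  mean(key == names(which.max(table(key))))
}
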