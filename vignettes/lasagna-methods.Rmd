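---
title: "Length-aware alignment of transcription factor binding sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-aware alignment of transcription factor binding sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lasagna)
```

## The problem

Experimentally curated binding sites of a transcription factor (TF) are
short DNA segments of *variable length*: a conserved core plus a few
irrelevant bases on one or both sides, deposited in databases in whatever
extent the original experiment reported. Before a position-specific
scoring matrix (PSSM) can be estimated, the sites must be aligned without
internal gaps — protein–DNA contacts do not tolerate insertions inside
the core — and general-purpose multiple aligners handle this poorly
because they have no notion of "a core embedded in junk of unknown
extent".

This package implements a length-aware progressive strategy built on a
simple observation: if every site contains the full core, then the
*shortest* site carries the least junk. The shortest site therefore seeds
the alignment, and the remaining sites are added shortest-first, each
placed against the profile of the sites aligned so far.

## The scoring model

For an alignment of width $l$, the score of letter $u$ at column $i$ is
the log-odds $M_i(u) = \log_2 f_i(u)/f(u)$, where $f_i(u)$ is the column
letter probability and $f(u)$ the background. The model additionally
scores *pairs* of positions up to a distance $K$ (the **scope**):
$M_{i,j}(u,v) = \log_2 f_{i,j}(u,v)/f(u,v)$ for $1 \le j - i \le K$. The
score of an $l$-mer $s$ is

$$\mathrm{PSSM}_K(s) \;=\; \sum_{i=1}^{l} M_i(s_i) \;+\;
  \sum_{k=1}^{K} \sum_{i=1}^{l-k} M_{i,i+k}(s_i, s_{i+k}),$$

with no pair terms at $K = 0$ (the classical additive PSSM). During
alignment a gap-aware variant is used: a gap letter inside a window
contributes the *minimum* score of its column (or pair), so overhanging
placements are penalised but not forbidden.

A candidate site $s$ of arbitrary length $l_s$ is scored by augmenting it
with $l-1$ gap letters on each end and taking the maximum over all
$l + l_s - 1$ windows (the sliding score). This is how test sites of any
length are compared against a fixed-width model.

Choices the model leaves open, and what this package does:

* **Log base.** Base 2 (bits) everywhere. The base rescales all scores
  and affects no ranking or argmax.
* **Pseudocounts.** Additive, 0.25 per letter and 0.0625 per letter pair,
  applied at frequency estimation. Log-odds require strictly positive
  probabilities; these values add one quarter of a uniform observation.
* **Pair background.** The independence product
  $f(u,v) = f(u)\,f(v)$, so pair scores measure dependence *relative to
  independence*: a pair column whose letters are independent scores the
  same as under $K = 0$.
* **Background $f(u)$.** Pooled letter counts of the aligned rows (in
  aligned orientation), unless the caller supplies a distribution.
* **Gaps in estimation.** Gap letters never enter counts; a pair
  contributes only when both positions are non-gap. Position pairs with
  no gap-free supporting row fall back to the background product and
  score zero.
* **Tie-breaks.** Equal window scores resolve to the leftmost window and
  the forward strand. Determinism matters more than the (arbitrary)
  choice itself.

## The progressive aligner

`lasagna_align()` seeds with the first shortest site, then repeats:
build the gap-aware PSSM of the partial alignment; among the shortest
unaligned sites pick the one whose best sliding score is highest (input
order on exact ties); place it on both strands (forward preferred on
ties); merge with end-gap padding. Every input site ends up in the
output exactly once, as itself or its reverse-complement — tests enforce
this conservation property on random inputs.

The PSSM is rebuilt from scratch after every merge. Incremental updates
would be marginally faster but the alignment sizes involved (tens to a
few hundred rows) make the simpler full rebuild preferable.

Column quality is summarised by the coverage $C_i$ (fraction of non-gap
letters) and the information content
$IC_i = \max(0,\, 2 + \sum_u f_i(u)\log_2 f_i(u) - \hat e(n_i))$ in
bits, where $\hat e(n) = 3/(2 \ln 2\, n)$ is the asymptotic small-sample
correction for an alphabet of four letters and $n_i$ non-gap
observations. `trim_alignment()` removes end columns up to the first
column with $C_i > C_{\min}$ and $IC_i > IC_{\min}$ (defaults 0.4 and 0,
the configuration used before PSSM construction throughout the
evaluation framework); trimming is idempotent.

## The ChIP-seq variant

ChIP-seq peaks are long (hundreds of bases) and carry the binding site
near, not at, the called signal peak. `lasagna_chip()` therefore:

1. clips every peak to 100 bp centred on its point source (window
   shifted to stay within bounds; a missing point source falls back to
   the midpoint);
2. runs the progressive alignment with two modifications: once the
   partial alignment has more than two rows it is *adaptively trimmed*
   before each placement — thresholds set to the column means, then the
   lower-IC end column removed until at most 15 columns remain and both
   ends have positive IC — and at most 5 equally short candidates
   compete per step (peaks are mostly all 100 bp, so ties are huge);
3. refines the result by repeatedly trimming, rebuilding the PSSM, and
   re-placing *every* clipped peak, until the summed IC of the trimmed
   core is unchanged (|Δ| < 1e-9) for 3 consecutive iterations, with a
   hard cap of 50 iterations;
4. repeats all of the above for 6 seed choices (the shortest peak plus 5
   random ones — a shortest peak sequence may miss the core entirely) and
   for every scope $K_a$ from 0 to 8, returning the candidate whose
   trimmed core has the highest summed IC.

Two points where the procedure is underdetermined and this package had
to choose: the adaptive-trim mean-threshold comparison is *inclusive*
(`>=`) because clipped peak sets of equal length have constant coverage,
where a strict comparison would reject every column; and all sampled
peaks (not only those currently aligned) are re-placed during
refinement. The sampling of peaks (300 by default), the 5 tie-break
candidates and the 5 extra seeds are drawn from a caller-supplied RNG
seed, making the whole search reproducible.

## Scanning and empirical p-values

`scan_sequence()` scores every $l$-mer of a sequence gaplessly on both
strands and keeps the higher score. The prediction cutoff of a fitted
model is the minimal sliding score of its own constituting sites, so
every training site is recovered at the default cutoff.

P-values are estimated empirically because pair scores break the
independence assumptions behind exact PSSM p-value algorithms: a random
sequence is simulated i.i.d. from the model's background until 40000
window scores are available (both strands, higher kept) and the upper 5%
tail is stored. A score at or above the 95th percentile gets
$p = \#\{\text{null} \ge \text{score}\}/40000$; anything below is
censored and reported as the sentinel `0.05+`; a score above every null
score reports 0, meaning $p < 2.5\times10^{-5}$ — the resolution
implied by 40000 windows, which is why 40000 is the default.

## The evaluation framework

Alignment quality is measured by what the alignment is for: the search
performance of its PSSM. For one TF with $n$ sites, `cv_evaluate()` runs
$\nu$-fold cross-validation ($\nu = 10$): per fold, the training sites
are aligned ($K_a = K_s$), trimmed, and turned into a PSSM; each held-out
site is planted at a uniformly random position in a fresh 2000-base
sequence simulated from a first-order Markov chain, and every $l$-mer of
that sequence ($l$ = test-site length) receives the higher of its two
strand-wise sliding scores. Windows sharing more than
$\lfloor l/2\rfloor$ bases with the planted site are *hits*; the site's
score is the best hit score and its rank is one plus the number of
non-hit windows scoring at least as high. The $n$ pooled ranks yield a
ROC curve and its AUC. With `Ks = "auto"` the scope is grid-searched
over $0..\min(10, l_{\min}-1)$ on identical folds and planted sequences.

A caveat worth stating plainly: this rank statistic is *not* centred at
AUC 0.5 under a no-signal null. The test-site score is a maximum over
its ~$l$-window hit neighbourhood, and each non-site score is itself a
sliding maximum over overlapping placements, so even for
motif-destroyed (per-site shuffled) inputs the expected AUC sits well
above 0.5 — around 0.86 under the synthetic conditions used in the test
suite, against ~0.99 for intact planted motifs. The statistic orders
methods and motifs usefully, but its absolute value under the null is
biased by construction; shuffled-control AUCs should be compared against
this empirical null level, not against 0.5.

## What the synthetic data emulate — and what they do not

`sample_site_set()` emulates database entries for one TF: a core drawn
column-independently from a generated PWM (target IC per column, default
1.5 bits — a strong but not degenerate eukaryotic motif), flanked by 0–6
uniform background bases per side, 20% of sites reverse-complemented.
`sample_peak_set()` emulates called peaks: 100–400 bp of background with
one planted instance whose midpoint sits within a jitter (default
≤30 bases) of the recorded point source, mirroring the observation that
the true site usually lies within 50 bp of the call.
`sample_dependent_site_set()` generates cores whose adjacent letters are
coupled through fixed permutations (coupling 0.9) while marginal column
IC stays low (0.3 bits) — the regime in which pair scores carry the
signal that single-letter scores cannot see, used to exercise the scope
grid.

All generators are pure functions of their seed, and truth sidecars
(core interval, strand) suffice to compute recovery and AUC without any
external data. What they deliberately do *not* model: two-part motifs
with variable spacers (the gapless model cannot represent them), GC
composition bias between sites and genomic background, overlapping or
missing motif instances in peaks (the one-per-sequence assumption is
baked in), and sequencing artefacts. Passing tests on these fixtures
show the machinery is correct under the stated generative model, not
that every real peak set will yield a clean motif.

## Numerical and scale choices

* Intervals are 1-based and closed inside R (the Bioconductor
  convention); BED/narrowPeak files are written and read 0-based
  half-open, conversion happening only at the file boundary.
* Refinement convergence uses an absolute tolerance of 1e-9 on summed
  IC — IC sums are O(10) bits, so this is effectively exact equality —
  plus the iteration cap of 50.
* The test suite and the acceptance script size their studies as: 50
  planted site sets (30 sites each) for recovery and CV, 3
  pair-dependent sets for the scope grid, 2 peak sets of 300 peaks for
  the ChIP pipeline. These sizes give stable means (the CV AUC means
  move by <0.01 across seed choices) while keeping a full run in
  minutes.
* `make_pwm()` tempers a Dirichlet draw ($p^\beta$, renormalised, root
  solved for $\beta$) to hit the per-column IC target exactly; the draw
  is scaled by its maximum before powering so large exponents cannot
  underflow.

## Known limitations

Gapless alignment cannot represent two-block motifs with variable
spacers; the aligner will lock onto the most prevalent spacer length.
One motif instance per peak is assumed; peaks bound through a partner TF
or containing multiple instances dilute the profile. The empirical
p-value floor (2.5e-5 at the default 40000 windows) is too coarse for
genome-wide scans at stringent thresholds; raise `n_windows` when that
matters. And the cross-validation AUC, as discussed above, has a
construction-driven offset under the null that must be kept in mind when
reading absolute values.
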