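#' Read binding sites or an aligned FASTA file
#'
#' Sequences are case-folded to uppercase and validated against the
#' `A,C,G,T` alphabet; the gap letter `-` is permitted only with
#' `aligned = TRUE`. IUPAC ambiguity codes (including `N`) are rejected
#' with the offending record and position, or dropped record-wise with
#' `drop_ambiguous = TRUE`.
#'
#' @param path FASTA file.
#' @param aligned permit gap letters (aligned FASTA).
#' @param drop_ambiguous drop records with out-of-alphabet letters instead
#'   of erroring.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE, drop_ambiguous = FALSE) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  pat <- if (aligned) "[^ACGT-]" else "[^ACGT]"
  bad <- regexpr(pat, seqs)
  if (any(bad > 0L)) {
    if (drop_ambiguous) {
      seqs <- seqs[bad < 0L]
    } else {
      i <- which(bad > 0L)[1L]
      stop(sprintf("record '%s': invalid letter '%s' at position %d (alphabet is A,C,G,T%s)",
                   names(seqs)[i], substr(seqs[i], bad[i], bad[i]), bad[i],
                   if (aligned) ",-" else ""), call. = FALSE)
    }
  }
  seqs
}

#' Write sequences or an alignment to FASTA
#'
#' @param seqs named character vector or a [tfbs_alignment()] (written
#'   with its gap padding).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "tfbs_alignment"))
    seqs <- stats::setNames(seqs$seqs, seqs$ids)
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read an ENCODE narrowPeak (BED6+4) file
#'
#' Delegates to `rtracklayer` after validating the 10-column shape.
#' Column 10, the 0-based point-source offset from `start`, populates
#' `peak`; a `-1` point source falls back to the interval midpoint. Peak
#' sequences are attached from `fasta` when given: records whose names
#' match peak names are used directly, otherwise the file is treated as a
#' genome and `[start, end)` is extracted from the matching chromosome.
#'
#' @param path narrowPeak file.
#' @param fasta optional FASTA of peak sequences or chromosomes.
#' @return data.frame with the ten narrowPeak columns (`chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `signalValue`, `pValue`, `qValue`,
#'   `peak`; file convention: 0-based half-open intervals, `peak` relative
#'   to `start`) plus `seq` when sequences were attached.
#' @export
read_narrowpeak <- function(path, fasta = NULL) {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^(#|track|browser)", first) & nzchar(first)]
  ncols <- lengths(strsplit(first, "\t"))
  if (any(ncols != 10L))
    stop(sprintf("narrowPeak requires exactly 10 tab-separated columns (found %d)",
                 ncols[which(ncols != 10L)[1L]]))
  gr <- rtracklayer::import(path, format = "narrowPeak")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,           # back to 0-based file coords
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else sprintf("peak_%d", seq_along(gr)),
    score = if (!is.null(gr$score)) as.integer(gr$score) else 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    signalValue = gr$signalValue, pValue = gr$pValue, qValue = gr$qValue,
    peak = gr$peak, stringsAsFactors = FALSE)
  df$peak <- ifelse(df$peak < 0L, (df$end - df$start) %/% 2L, df$peak)
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    if (all(df$name %in% names(seqs))) {
      df$seq <- unname(seqs[df$name])
      stopifnot(all(nchar(df$seq) == df$end - df$start))
    } else if (all(df$chrom %in% names(seqs))) {
      df$seq <- substr(seqs[df$chrom], df$start + 1L, df$end)
    } else {
      stop("FASTA names match neither peak names nor chromosome names")
    }
  }
  df
}

#' Write peaks as narrowPeak
#'
#' @param peaks a peaks data.frame (as from [read_narrowpeak()] or
#'   [sample_peak_set()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write scan hits as BED6+2
#'
#' Standard BED columns (0-based half-open coordinates, name = TF, score =
#' PSSM score, strand) plus the PSSM score and the p-value as extra
#' columns; the censored sentinel `"0.05+"` is written verbatim.
#'
#' @param hits a [scan_sequence()] data.frame (1-based closed `start`,
#'   `end`), optionally with a `p_value` column (`lasagna_pvalue` or
#'   character).
#' @param path output file.
#' @param name feature name (default the TF/PSSM label `"site"`).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = "site") {
  pv <- if ("p_value" %in% names(hits)) {
    if (inherits(hits$p_value, "lasagna_pvalue")) format(hits$p_value)
    else as.character(hits$p_value)
  } else rep(".", nrow(hits))
  df <- data.frame(chrom = hits$seq_id,
                   start = hits$start - 1L,          # 0-based half-open
                   end = hits$end,
                   name = name,
                   score = sprintf("%.6g", hits$score),
                   strand = hits$strand,
                   score2 = sprintf("%.10g", hits$score),
                   p_value = pv, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6+2 hits file written by [write_hits_bed()]
#'
#' @param path BED file.
#' @return data.frame with `seq_id`, `start`, `end` (1-based closed),
#'   `strand`, `score` and `p_value` (character; `"0.05+"` preserved).
#' @export
read_hits_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "score2", "p_value"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character",
                                         "numeric", "character"))
  data.frame(seq_id = df$chrom, start = df$start + 1L, end = df$end,
             strand = df$strand, score = df$score2, p_value = df$p_value,
             stringsAsFactors = FALSE)
}

#' Write a PSSM to a plain-text matrix file
#'
#' A documented text dialect: `#`-prefixed header lines (name, scope `K`,
#' length, background, pseudocounts), a 4 x l tab-separated single-score
#' block (rows A,C,G,T), and one 16 x (l-k) pair-score block per distance
#' `k <= K` (rows AA, AC, ..., TT). Scores round-trip to at least 1e-12.
#'
#' @param pssm a [build_pssm()] result.
#' @param path output file.
#' @param name motif/TF label stored in the header.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path, name = "motif") {
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(c(
    sprintf("# name\t%s", name),
    sprintf("# K\t%d", pssm$K),
    sprintf("# length\t%d", pssm$l),
    sprintf("# background\t%s", paste(fmt(pssm$bg), collapse = "\t")),
    sprintf("# pseudocount\t%s\t%s", fmt(pssm$pseudocount),
            fmt(pssm$pair_pseudocount)),
    "# single"), con)
  for (u in 1:4)
    writeLines(paste(c(DNA_LETTERS[u], fmt(pssm$M[u, ])), collapse = "\t"), con)
  if (pssm$K >= 1L) for (k in seq_len(pssm$K)) {
    writeLines(sprintf("# pair\t%d", k), con)
    for (u in 1:4) for (v in 1:4)
      writeLines(paste(c(paste0(DNA_LETTERS[u], DNA_LETTERS[v]),
                         fmt(pssm$Mpair[[k]][(u - 1L) * 4L + v, ])),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PSSM matrix file written by [write_pssm()]
#'
#' @param path matrix file.
#' @return a `lasagna_pssm`; attribute `"name"` carries the stored label.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(sprintf("^# %s\t", key), lines, value = TRUE)[1L]
    strsplit(sub(sprintf("^# %s\t", key), "", ln), "\t")[[1L]]
  }
  name <- hdr("name")
  K <- as.integer(hdr("K"))
  l <- as.integer(hdr("length"))
  bg <- as.numeric(hdr("background"))
  pc <- as.numeric(hdr("pseudocount"))
  body <- lines[!grepl("^#", lines)]
  parse_block <- function(rows_expected, block) {
    m <- do.call(rbind, lapply(block, function(ln)
      as.numeric(strsplit(ln, "\t")[[1L]][-1L])))
    stopifnot(nrow(m) == rows_expected)
    m
  }
  M <- parse_block(4L, body[1:4])
  body <- body[-(1:4)]
  Mpair <- list()
  if (K >= 1L) for (k in seq_len(K)) {
    Mpair[[k]] <- parse_block(16L, body[1:16])
    body <- body[-(1:16)]
  }
  gapmin <- apply(M, 2L, min)
  Mg <- rbind(M, gapmin)
  Mpairg <- list(); gapmin_pair <- list()
  if (K >= 1L) for (k in seq_len(K)) {
    gm <- apply(Mpair[[k]], 2L, min)
    Mpg <- matrix(rep(gm, each = 25L), 25L, ncol(Mpair[[k]]))
    for (u in 1:4) for (v in 1:4)
      Mpg[(u - 1L) * 5L + v, ] <- Mpair[[k]][(u - 1L) * 4L + v, ]
    Mpairg[[k]] <- Mpg; gapmin_pair[[k]] <- gm
  }
  structure(list(M = M, Mpair = Mpair, Mg = Mg, Mpairg = Mpairg,
                 gapmin = gapmin, gapmin_pair = gapmin_pair,
                 K = K, l = l, bg = bg,
                 pseudocount = pc[1L], pair_pseudocount = pc[2L]),
            class = "lasagna_pssm", name = name)
}

#' Export the single-letter block in MEME minimal format
#'
#' Writes the K = 0 letter-probability view of a frequency model as a MEME
#' minimal motif file (pair scores have no MEME representation).
#'
#' @param freq a [estimate_frequency_model()] result.
#' @param path output file.
#' @param name motif name.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(freq, path, name = "motif") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_LETTERS, freq$bg), collapse = " "),
               "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       freq$l, max(freq$n))), con)
  for (i in seq_len(freq$l))
    writeLines(paste(sprintf("%.6f", freq$f1[, i]), collapse = "  "), con)
  invisible(path)
}

#' Write a truth sidecar TSV for synthetic data
#' @param truth a truth data.frame from a generator.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
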