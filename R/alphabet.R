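#' @keywords internal
"_PACKAGE"

## DNA alphabet used throughout: A,C,G,T encoded 1:4, the gap letter "-"
## encoded 5. Input binding sites must be gap-free; gaps appear only as
## end-padding introduced by the aligner.

DNA_LETTERS <- c("A", "C", "G", "T")
GAP <- "-"
GAP_CODE <- 5L

.encode_map <- {
  m <- rep(NA_integer_, 256)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("a")] <- 1L
  m[utf8ToInt("C")] <- 2L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("g")] <- 3L
  m[utf8ToInt("T")] <- 4L; m[utf8ToInt("t")] <- 4L
  m[utf8ToInt("-")] <- GAP_CODE
  m
}

## complement in code space: A<->T, C<->G, gap -> gap
.comp_code <- c(4L, 3L, 2L, 1L, 5L)

#' Encode a DNA string as integer codes
#'
#' A, C, G, T map to 1:4 and the gap letter `-` to 5. Case-insensitive.
#'
#' @param x a single character string over `{A,C,G,T,-}`.
#' @return integer vector of codes.
#' @keywords internal
dna_encode <- function(x) {
  codes <- .encode_map[utf8ToInt(x)]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf("invalid letter '%s' at position %d (alphabet is A,C,G,T,-)",
                 substr(x, bad, bad), bad), call. = FALSE)
  }
  codes
}

#' @keywords internal
dna_decode <- function(codes) {
  paste(c(DNA_LETTERS, GAP)[codes], collapse = "")
}

#' Reverse-complement a DNA sequence
#'
#' Letters are complemented (A<->T, C<->G) and the order reversed; the gap
#' letter maps to itself. The operation is an involution.
#'
#' @param seq character vector of sequences over `{A,C,G,T,-}`
#'   (case-insensitive; output is uppercase).
#' @return character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("ACGT")   # palindrome: "ACGT"
#' reverse_complement("-AC")    # "GT-"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) dna_decode(rev(.comp_code[dna_encode(s)])),
         character(1), USE.NAMES = FALSE)
}

#' @keywords internal
revcomp_codes <- function(codes) rev(.comp_code[codes])

#' @keywords internal
strip_gaps <- function(seq) gsub(GAP, "", seq, fixed = TRUE)

## run `expr` under a temporary RNG state seeded with `seed`; restores the
## caller's RNG afterwards so seeded helpers do not perturb global streams
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## uniform draw from lo:hi that is safe when lo == hi (base sample()
## treats a scalar first argument as 1:x)
sample_range <- function(lo, hi, n = 1L) {
  pool <- seq.int(lo, hi)
  pool[sample.int(length(pool), n, replace = TRUE)]
}

## deterministic derived seeds for independent sub-streams
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  x <- 0
  for (p in parts) x <- (x * 1000003 + as.numeric(p) + 12345) %% 2147483629
  as.integer(x) + 1L
}
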