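## 4-bit encoding of the 15 IUPAC nucleotide codes: A=1, C=2, G=4, T=8,
## ambiguity codes are bitwise ORs of their base sets.
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

.BIT_SYMBOL <- local({
  s <- character(15L)
  s[.IUPAC_BITS] <- names(.IUPAC_BITS)
  s
})

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

## complement of a 4-bit code: swap A<->T and C<->G bit planes
.COMP_BITS <- local({
  v <- integer(15L)
  for (b in 1:15) {
    v[b] <- bitwOr(
      bitwOr(if (bitwAnd(b, 1L)) 8L else 0L, if (bitwAnd(b, 8L)) 1L else 0L),
      bitwOr(if (bitwAnd(b, 2L)) 4L else 0L, if (bitwAnd(b, 4L)) 2L else 0L)
    )
  }
  v
})

.invalidAlphabetError <- function(chars, positions) {
  stop(errorCondition(
    sprintf(
      "invalid IUPAC symbol%s %s at position%s %s",
      if (length(chars) > 1L) "s" else "",
      paste0("'", chars, "'", collapse = ", "),
      if (length(chars) > 1L) "s" else "",
      paste(positions, collapse = ", ")
    ),
    class = c("pcAlphabetError", "error", "condition")
  ))
}

## Normalize one sequence string to an integer bit vector.
## Case-insensitive; U is accepted and read as T.
.iupacInts <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1L]]
  chars[chars == "U"] <- "T"
  bits <- .IUPAC_BITS[chars]
  bad <- which(is.na(bits))
  if (length(bad)) .invalidAlphabetError(chars[bad], bad)
  unname(bits)
}

.intsToIupac <- function(bits) paste(.BIT_SYMBOL[bits], collapse = "")

#' Expand an IUPAC code to its base set
#'
#' Each of the 15 IUPAC nucleotide codes denotes a nonempty subset of
#' `{A, C, G, T}`; this returns that subset.
#'
#' @param symbol A single IUPAC character (case-insensitive; `U` is read
#'   as `T`).
#' @return Character vector of canonical bases, in `A < C < G < T` order.
#' @examples
#' expandCode("Y")  # C, T
#' expandCode("N")
#' @export
expandCode <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L)
    stop("'symbol' must be a single character")
  bit <- .iupacInts(symbol)
  names(.BASE_BITS)[bitwAnd(bit, .BASE_BITS) > 0L]
}

#' Encode a base set as an IUPAC code
#'
#' Inverse of [expandCode()]: maps a nonempty subset of `{A, C, G, T}` to
#' the unique IUPAC symbol with that expansion.
#'
#' @param bases Character vector of canonical bases (duplicates allowed).
#' @return A single IUPAC symbol.
#' @examples
#' encodeBases(c("A", "G"))  # "R"
#' @export
encodeBases <- function(bases) {
  if (length(bases) == 0L)
    stop("'bases' must be a nonempty set of canonical bases")
  bases <- toupper(bases)
  bases[bases == "U"] <- "T"
  bits <- .BASE_BITS[bases]
  if (anyNA(bits)) .invalidAlphabetError(bases[is.na(bits)][1L], which(is.na(bits))[1L])
  .BIT_SYMBOL[Reduce(bitwOr, bits)]
}

#' Degenerate base matching
#'
#' Two IUPAC codes match when their expanded base sets intersect — the
#' standard in-silico PCR convention, symmetric in primer and template,
#' so templates carrying ambiguity codes (including `N`) are handled.
#'
#' @param a,b Character vectors of single IUPAC symbols (recycled to a
#'   common length).
#' @return Logical vector.
#' @examples
#' codesMatch("Y", "T")  # TRUE
#' codesMatch("R", "Y")  # FALSE
#' @export
codesMatch <- function(a, b) {
  ia <- .IUPAC_BITS[sub("U", "T", toupper(a), fixed = TRUE)]
  ib <- .IUPAC_BITS[sub("U", "T", toupper(b), fixed = TRUE)]
  if (anyNA(ia)) .invalidAlphabetError(a[is.na(ia)][1L], which(is.na(ia))[1L])
  if (anyNA(ib)) .invalidAlphabetError(b[is.na(ib)][1L], which(is.na(ib))[1L])
  unname(bitwAnd(ia, ib) > 0L)
}

#' Count degenerate positions in an IUPAC sequence
#'
#' A position is degenerate when its code expands to more than one base.
#' This is the quantity limited during window extraction and candidate
#' filtering (at most two degeneracies per oligo under the defaults).
#'
#' @param sequence Character vector of IUPAC strings.
#' @return Integer vector of degenerate-position counts.
#' @examples
#' degeneracyCount("GTTTAGGGYGTGGACTACCCGGGTATCT")  # 1
#' @export
degeneracyCount <- function(sequence) {
  vapply(sequence, function(s) {
    bits <- .iupacInts(s)
    sum(!(bits %in% .BASE_BITS))
  }, integer(1L), USE.NAMES = FALSE)
}

#' Reverse complement over the IUPAC alphabet
#'
#' Reverses the sequence and replaces each code by the code of the
#' complemented base set (e.g. `R = {A,G}` becomes `Y = {C,T}`).
#'
#' @param sequence Character vector of IUPAC strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverseComplementIupac("AAY")  # "RTT"
#' @export
reverseComplementIupac <- function(sequence) {
  vapply(sequence, function(s) {
    bits <- .iupacInts(s)
    .intsToIupac(rev(.COMP_BITS[bits]))
  }, character(1L), USE.NAMES = FALSE)
}

## Fraction of positions whose code is N (used to pre-filter N-rich
## templates before coverage computation; default cap 0.05).
.nFraction <- function(sequence) {
  bits <- .iupacInts(sequence)
  if (!length(bits)) return(0)
  mean(bits == 15L)
}
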