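## The 15 nonempty subsets of {A,C,G,T}, as a logical matrix ordered by
## cardinality, used to pick the minimal-cardinality set reaching the
## consensus threshold.
.SUBSET_MATRIX <- local({
  m <- matrix(FALSE, 15L, 4L, dimnames = list(character(15L), c("A", "C", "G", "T")))
  for (b in 1:15) {
    m[b, ] <- bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L
    rownames(m)[b] <- .BIT_SYMBOL[b]
  }
  m
})

## Coerce the accepted alignment representations to an uppercase character
## matrix (rows = sequences). '.' is normalized to '-', U to T.
.alignmentMatrix <- function(alignment) {
  if (is(alignment, "DNAMultipleAlignment") || is(alignment, "DNAStringSet") ||
      is(alignment, "BStringSet"))
    alignment <- as.character(alignment)
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      .formatError(sprintf(
        "alignment rows have unequal lengths (offending record: %s)",
        if (!is.null(names(alignment))) names(alignment)[which(lens != lens[1L])[1L]]
        else which(lens != lens[1L])[1L]))
    m <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
    rownames(m) <- names(alignment)
  } else stop("unsupported alignment representation")
  m[m == "."] <- "-"
  m[m == "U"] <- "T"
  m
}

## Weighted base counts for every column at once: ambiguity codes either
## contribute 1/|base set| to each of their bases, or are dropped.
.columnBaseCounts <- function(m, ambiguityWeights = TRUE) {
  counts <- matrix(0, 4L, ncol(m), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (sym in setdiff(unique(as.vector(m)), "-")) {
    bits <- .IUPAC_BITS[sym]
    if (is.na(bits)) {
      bad <- which(m == sym, arr.ind = TRUE)[1L, ]
      .invalidAlphabetError(sym, sprintf("row %d column %d", bad[1L], bad[2L]))
    }
    bases <- .SUBSET_MATRIX[sym, ]
    if (!ambiguityWeights && sum(bases) > 1L) next
    w <- as.numeric(bases) / sum(bases)
    counts <- counts + outer(w, colSums(m == sym))
  }
  counts
}

#' Non-gap base frequencies of one alignment column
#'
#' Gaps are excluded from the denominator (indels are ignored when the
#' consensus is computed). Ambiguity codes in the rows contribute
#' fractionally, `1/|base set|` to each of their bases, unless
#' `ambiguityWeights = FALSE` in which case they are dropped from the
#' column count.
#'
#' @param alignment Equal-length character vector of aligned sequences, a
#'   character matrix, a `DNAStringSet`, or a `DNAMultipleAlignment`.
#' @param column 1-based column index.
#' @param ambiguityWeights Fractional handling of ambiguity codes (default
#'   `TRUE`).
#' @return Named numeric vector of frequencies over A, C, G, T summing
#'   to 1.
#' @examples
#' columnFrequencies(c("AR", "AA"), 2)  # A 0.75, G 0.25
#' @export
columnFrequencies <- function(alignment, column, ambiguityWeights = TRUE) {
  m <- .alignmentMatrix(alignment)
  if (column < 1L || column > ncol(m))
    stop(sprintf("column %d out of range [1, %d]", column, ncol(m)))
  counts <- .columnBaseCounts(m[, column, drop = FALSE], ambiguityWeights)[, 1L]
  total <- sum(counts)
  if (total == 0)
    stop(sprintf("column %d has no non-gap residues", column))
  counts / total
}

## Core of the threshold encoding, vectorized over columns of a 4 x n
## frequency matrix. mode "minimal": smallest base set with cumulative
## frequency >= threshold (ties: higher cumulative frequency, then
## lexicographically smallest IUPAC symbol). mode "inclusion": every base
## with frequency >= 1 - threshold (at least the single most frequent base).
.consensusSymbols <- function(freqs, threshold, mode = c("minimal", "inclusion")) {
  mode <- match.arg(mode)
  eps <- 1e-9
  if (mode == "inclusion") {
    return(vapply(seq_len(ncol(freqs)), function(j) {
      f <- freqs[, j]
      keep <- f >= (1 - threshold) - eps
      if (!any(keep)) keep <- f == max(f)
      encodeBases(names(f)[keep])
    }, character(1L)))
  }
  cum <- .SUBSET_MATRIX %*% freqs            # 15 x n cumulative frequencies
  card <- rowSums(.SUBSET_MATRIX)
  syms <- rownames(.SUBSET_MATRIX)
  vapply(seq_len(ncol(freqs)), function(j) {
    ok <- which(cum[, j] >= threshold - eps)
    k <- min(card[ok])
    ok <- ok[card[ok] == k]
    ok <- ok[cum[ok, j] >= max(cum[ok, j]) - eps]
    sort(syms[ok])[1L]
  }, character(1L))
}

#' Threshold-encode a frequency map as an IUPAC code
#'
#' Returns the IUPAC symbol of the minimal-cardinality base set whose
#' cumulative frequency reaches the threshold; among equal-cardinality
#' candidates the set with the highest cumulative frequency wins, then the
#' lexicographically smallest symbol. With `mode = "inclusion"` the code
#' instead covers every base whose individual frequency is at least
#' `1 - threshold`.
#'
#' @param freqs Named numeric frequencies over (a subset of) A, C, G, T,
#'   summing to 1.
#' @param threshold Consensus threshold in (0.5, 1], default 0.90.
#' @param mode `"minimal"` (default) or `"inclusion"`.
#' @return A single IUPAC symbol.
#' @examples
#' consensusCode(c(A = 0.5, G = 0.45, T = 0.05), 0.90)  # "R"
#' consensusCode(c(A = 0.89, C = 0.11), 0.90)           # "M"
#' @export
consensusCode <- function(freqs, threshold = 0.90, mode = c("minimal", "inclusion")) {
  if (length(freqs) == 0L || all(is.na(freqs)))
    stop("'freqs' must be a nonempty frequency map")
  if (threshold <= 0.5 || threshold > 1)
    stop("'threshold' must lie in (0.5, 1]")
  f <- stats::setNames(numeric(4L), c("A", "C", "G", "T"))
  nm <- toupper(names(freqs))
  if (is.null(names(freqs)) || !all(nm %in% names(f)))
    stop("'freqs' must be named by canonical bases A, C, G, T")
  f[nm] <- freqs
  if (abs(sum(f) - 1) > 1e-6) stop("'freqs' must sum to 1")
  .consensusSymbols(matrix(f, 4L, 1L, dimnames = list(names(f), NULL)),
                    threshold, match.arg(mode))
}

#' Build a threshold IUPAC consensus from a multiple alignment
#'
#' Computes per-column non-gap base frequencies (indels are ignored in the
#' counting) and encodes each retained column with [consensusCode()].
#' All-gap columns, and columns whose gap fraction exceeds
#' `maxGapFraction`, are dropped; the surviving columns are recorded in
#' the profile's `columnMap`.
#'
#' @inheritParams columnFrequencies
#' @param threshold Consensus threshold, default 0.90 (a "90% consensus").
#' @param maxGapFraction Columns with a gap fraction above this are
#'   treated as alignment artifacts and dropped (default 0.5).
#' @param mode Threshold encoding mode, see [consensusCode()].
#' @return A [ConsensusProfile-class] object.
#' @examples
#' aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGT", s3 = "ACGAACGT")
#' consensusSeq(buildConsensus(aln, threshold = 0.9))
#' @export
buildConsensus <- function(alignment, threshold = 0.90, maxGapFraction = 0.5,
                           ambiguityWeights = TRUE,
                           mode = c("minimal", "inclusion")) {
  mode <- match.arg(mode)
  if (threshold <= 0.5 || threshold > 1)
    stop("'threshold' must lie in (0.5, 1]")
  m <- .alignmentMatrix(alignment)
  if (nrow(m) < 2L)
    stop("an alignment needs at least 2 rows")
  counts <- .columnBaseCounts(m, ambiguityWeights)
  gapFrac <- colMeans(m == "-")
  nonGap <- colSums(counts)
  keep <- which(nonGap > 0 & gapFrac <= maxGapFraction)
  freqs <- sweep(counts[, keep, drop = FALSE], 2L, nonGap[keep], "/")
  consensus <- if (length(keep))
    paste(.consensusSymbols(freqs, threshold, mode), collapse = "") else ""
  new("ConsensusProfile", consensus = consensus, frequencies = freqs,
      threshold = threshold, columnMap = as.integer(keep),
      nSequences = nrow(m))
}
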