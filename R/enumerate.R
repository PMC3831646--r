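#' @importFrom IRanges IRanges reduce start end
NULL

## 0/1 degeneracy indicator per position of an IUPAC string
.degenFlags <- function(sequence) {
  bits <- .iupacInts(sequence)
  as.integer(!(bits %in% c(1L, 2L, 4L, 8L)))
}

#' Find low-degeneracy sliding windows on a consensus
#'
#' Slides a fixed-length window along the consensus and keeps every start
#' whose window contains at most `maxDegeneracies` degenerate positions
#' (defaults 15 nt and 2, i.e. "fewer than three degeneracies").
#'
#' @param consensus IUPAC consensus string (or a
#'   [ConsensusProfile-class]).
#' @param windowLength Window length in nt, default 15.
#' @param maxDegeneracies Maximum degenerate positions per window,
#'   default 2.
#' @return Ascending integer vector of 1-based window start positions;
#'   empty when the consensus is shorter than the window.
#' @export
findValidWindows <- function(consensus, windowLength = 15L, maxDegeneracies = 2L) {
  if (is(consensus, "ConsensusProfile")) consensus <- consensusSeq(consensus)
  windowLength <- as.integer(windowLength)
  if (windowLength < 1L) stop("'windowLength' must be >= 1")
  if (maxDegeneracies < 0L) stop("'maxDegeneracies' must be >= 0")
  n <- nchar(consensus)
  if (n < windowLength) return(integer(0L))
  flags <- .degenFlags(consensus)
  cs <- c(0L, cumsum(flags))
  starts <- seq_len(n - windowLength + 1L)
  counts <- cs[starts + windowLength] - cs[starts]
  starts[counts <= maxDegeneracies]
}

#' Merge overlapping windows into domains
#'
#' Overlapping or abutting valid windows are recombined into maximal
#' contiguous domains (an interval union), the conserved regions from
#' which candidate primers are extracted.
#'
#' @param starts Ascending 1-based window start positions, as returned by
#'   [findValidWindows()].
#' @param windowLength Window length the starts refer to.
#' @return `data.frame` with columns `start`, `end` (1-based inclusive),
#'   sorted and disjoint.
#' @export
mergeWindows <- function(starts, windowLength = 15L) {
  if (length(starts) == 0L)
    return(data.frame(start = integer(0L), end = integer(0L)))
  r <- reduce(IRanges(start = as.integer(starts), width = as.integer(windowLength)))
  data.frame(start = start(r), end = end(r))
}

#' Extract conserved domains from a consensus
#'
#' Convenience wrapper: [findValidWindows()] then [mergeWindows()], with
#' the domain subsequences attached.
#'
#' @inheritParams findValidWindows
#' @return `data.frame` with columns `start`, `end`, `sequence`.
#' @export
primerDomains <- function(consensus, windowLength = 15L, maxDegeneracies = 2L) {
  if (is(consensus, "ConsensusProfile")) consensus <- consensusSeq(consensus)
  d <- mergeWindows(findValidWindows(consensus, windowLength, maxDegeneracies),
                    windowLength)
  d$sequence <- substring(consensus, d$start, d$end)
  d
}

#' Enumerate candidate primers from conserved domains
#'
#' Every substring of every domain with length in `[minLength, maxLength]`
#' and at most `maxDegeneracies` degenerate positions becomes a candidate.
#' The degeneracy filter is re-applied per candidate: a long candidate can
#' span more degenerate context than any single window. Reverse-orientation
#' candidates are emitted as the reverse complement of the consensus
#' substring (the primer as it would be synthesised), with coordinates
#' kept on the consensus. Candidates are deduplicated by
#' (sequence, start, orientation).
#'
#' @param domains `data.frame` from [primerDomains()]/[mergeWindows()]
#'   with columns `start`, `end` (and optionally `sequence`).
#' @param consensus The consensus string the domain coordinates refer to;
#'   may be omitted when `domains$sequence` is present.
#' @param minLength,maxLength Candidate length bounds, defaults 20 and 30.
#' @param maxDegeneracies Maximum degenerate positions per candidate,
#'   default 2.
#' @param orientation `"forward"`, `"reverse"` or `"both"`.
#' @return `data.frame` with columns `id`, `sequence`, `start`, `end`,
#'   `length`, `degeneracy`, `orientation`.
#' @examples
#' dom <- data.frame(start = 1, end = 30,
#'                   sequence = paste(rep("ACGTA", 6), collapse = ""))
#' nrow(enumeratePrimers(dom))  # 66 forward candidates
#' @export
enumeratePrimers <- function(domains, consensus = NULL, minLength = 20L,
                             maxLength = 30L, maxDegeneracies = 2L,
                             orientation = c("forward", "reverse", "both")) {
  orientation <- match.arg(orientation)
  minLength <- as.integer(minLength); maxLength <- as.integer(maxLength)
  if (minLength > maxLength) stop("'minLength' must not exceed 'maxLength'")
  out <- list()
  for (i in seq_len(nrow(domains))) {
    dStart <- domains$start[i]
    dSeq <- if (!is.null(domains$sequence)) domains$sequence[i]
            else substring(consensus, dStart, domains$end[i])
    dLen <- nchar(dSeq)
    if (dLen < minLength) next
    flags <- .degenFlags(dSeq)
    cs <- c(0L, cumsum(flags))
    for (L in minLength:min(maxLength, dLen)) {
      offs <- seq_len(dLen - L + 1L)
      deg <- cs[offs + L] - cs[offs]
      offs <- offs[deg <= maxDegeneracies]
      if (!length(offs)) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substring(dSeq, offs, offs + L - 1L),
        start = dStart + offs - 1L,
        length = L,
        degeneracy = deg[match(offs, seq_len(dLen - L + 1L))]
      )
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(0L), sequence = character(0L),
                      start = integer(0L), end = integer(0L),
                      length = integer(0L), degeneracy = integer(0L),
                      orientation = character(0L)))
  }
  cand <- do.call(rbind, out)
  cand$end <- cand$start + cand$length - 1L
  cand <- cand[!duplicated(cand[, c("sequence", "start")]), , drop = FALSE]
  orient <- function(df, o) {
    if (o == "reverse") df$sequence <- reverseComplementIupac(df$sequence)
    df$orientation <- o
    df$id <- sprintf("cand_%d_%d_%s", df$start, df$length, o)
    df[, c("id", "sequence", "start", "end", "length", "degeneracy", "orientation")]
  }
  res <- switch(orientation,
    forward = orient(cand, "forward"),
    reverse = orient(cand, "reverse"),
    both = rbind(orient(cand, "forward"), orient(cand, "reverse"))
  )
  res <- res[order(res$start, res$length, res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}
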