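## ---------------------------------------------------------------------------
## Mismatch-tolerant ungapped scanner
##
## Primer and template are compared position by position with degenerate
## matching (base sets intersect => match). Ungapped: the scanner counts
## substitutions only, never indels.
## ---------------------------------------------------------------------------

.asSequenceString <- function(x) {
  if (is(x, "DegeneratePrimer")) return(primerSequence(x))
  if (is(x, "XString") || is(x, "XStringSet")) return(as.character(x))
  as.character(x)
}

## Mismatch count of `primerInts` laid at every start of `templateInts`.
## Vectorized over offsets, looping only over primer positions.
.mismatchProfile <- function(primerInts, templateInts) {
  L <- length(primerInts)
  T_ <- length(templateInts)
  if (L > T_) return(integer(0L))
  nOff <- T_ - L + 1L
  mm <- integer(nOff)
  for (j in seq_len(L)) {
    mm <- mm + as.integer(bitwAnd(primerInts[j], templateInts[j:(j + nOff - 1L)]) == 0L)
  }
  mm
}

#' Mismatch profile of a primer along a template
#'
#' Counts degenerate-aware mismatches of the primer laid ungapped at every
#' possible start of the template's plus strand. For `strand = "minus"`
#' the binding of the primer to the minus strand is evaluated, i.e. the
#' primer's reverse complement is slid along the plus strand; positions
#' always refer to the plus strand.
#'
#' @param primer A [DegeneratePrimer-class] or IUPAC string.
#' @param template Template sequence (character or `DNAString`).
#' @param strand `"plus"` or `"minus"`.
#' @return Integer vector of mismatch counts, element `i` for the binding
#'   site starting at plus-strand position `i`; length 0 when the primer
#'   is longer than the template.
#' @export
scanPrimer <- function(primer, template, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  p <- .asSequenceString(primer)
  if (strand == "minus") p <- reverseComplementIupac(p)
  .mismatchProfile(.iupacInts(p), .iupacInts(.asSequenceString(template)))
}

#' Best primer placement on a template
#'
#' Minimum mismatch count over all ungapped placements, with ties broken
#' by the smallest plus-strand position. A primer longer than the template
#' yields `min_mismatches = Inf`.
#'
#' @inheritParams scanPrimer
#' @return List with `min_mismatches`, `best_position` (1-based
#'   plus-strand start, `NA` when no placement exists) and `strand`.
#' @export
minMismatches <- function(primer, template, strand = c("plus", "minus")) {
  strand <- match.arg(strand)
  mm <- scanPrimer(primer, template, strand)
  if (!length(mm)) {
    return(list(min_mismatches = Inf, best_position = NA_integer_, strand = strand))
  }
  best <- which.min(mm)
  list(min_mismatches = mm[best], best_position = best, strand = strand)
}

## All binding sites with <= maxMm mismatches for one primer/strand.
.sites <- function(primer, template, strand, maxMm) {
  mm <- scanPrimer(primer, template, strand)
  pos <- which(mm <= maxMm)
  data.frame(start = pos, mm = mm[pos])
}

## Feasible (forward site, reverse site) combinations for a pair on one
## template: forward on plus strand, reverse on minus strand, forward site
## entirely upstream of the reverse site, product length within bounds.
.pairCombos <- function(pair, template, maxMm) {
  tpl <- .asSequenceString(template)
  fwd <- .sites(forwardPrimer(pair), tpl, "plus", maxMm)
  rev <- .sites(reversePrimer(pair), tpl, "minus", maxMm)
  lf <- nchar(primerSequence(forwardPrimer(pair)))
  lr <- nchar(primerSequence(reversePrimer(pair)))
  bounds <- ampliconBounds(pair)
  combos <- NULL
  anyOriented <- FALSE
  if (nrow(fwd) && nrow(rev)) {
    g <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    fStart <- fwd$start[g$f]; rStart <- rev$start[g$r]
    fEnd <- fStart + lf - 1L
    rEnd <- rStart + lr - 1L
    oriented <- rStart > fEnd
    anyOriented <- any(oriented)
    len <- rEnd - fStart + 1L
    ok <- oriented & len >= bounds[["min"]] & len <= bounds[["max"]]
    combos <- data.frame(
      fwd_start = fStart[ok], fwd_end = fEnd[ok], fwd_mm = fwd$mm[g$f][ok],
      rev_start = rStart[ok], rev_end = rEnd[ok], rev_mm = rev$mm[g$r][ok],
      length = len[ok]
    )
  }
  list(combos = combos, n_fwd = nrow(fwd), n_rev = nrow(rev),
       any_oriented = anyOriented)
}

#' Does a primer pair recognize a template?
#'
#' A template is recognized at mismatch allowance `maxMm` when the forward
#' primer binds the plus strand and the reverse primer the minus strand,
#' the forward site lies entirely upstream of the reverse site, the
#' implied product length respects the pair's bounds and the mismatch
#' allowance holds — per primer by default (each primer `<= maxMm`), or
#' summed across the pair with `allowance = "summed"`.
#'
#' @param pair A [PrimerPair-class].
#' @param template Template sequence.
#' @param maxMm Mismatch allowance, default 3.
#' @param allowance `"per-primer"` (default) or `"summed"`.
#' @return List with `recognized` (logical), `reason` (`"ok"`, `"no_fwd"`,
#'   `"no_rev"`, `"orientation"` or `"length"`) and, when recognized, the
#'   best site details (`fwd_start`, `rev_end`, `fwd_mm`, `rev_mm`,
#'   `product_length`; minimal total mismatches, then leftmost).
#' @export
pairRecognizes <- function(pair, template, maxMm = 3L,
                           allowance = c("per-primer", "summed")) {
  allowance <- match.arg(allowance)
  perPrimerCap <- if (allowance == "per-primer") maxMm else maxMm
  res <- .pairCombos(pair, template, perPrimerCap)
  combos <- res$combos
  if (!is.null(combos) && nrow(combos) && allowance == "summed")
    combos <- combos[combos$fwd_mm + combos$rev_mm <= maxMm, , drop = FALSE]
  if (!is.null(combos) && nrow(combos)) {
    o <- order(combos$fwd_mm + combos$rev_mm, combos$fwd_start, combos$rev_end)
    b <- combos[o[1L], ]
    return(list(recognized = TRUE, reason = "ok",
                fwd_start = b$fwd_start, rev_end = b$rev_end,
                fwd_mm = b$fwd_mm, rev_mm = b$rev_mm,
                product_length = b$length))
  }
  reason <- if (res$n_fwd == 0L) "no_fwd"
    else if (res$n_rev == 0L) "no_rev"
    else if (!res$any_oriented) "orientation"
    else "length"
  list(recognized = FALSE, reason = reason,
       fwd_start = NA_integer_, rev_end = NA_integer_,
       fwd_mm = NA_integer_, rev_mm = NA_integer_,
       product_length = NA_integer_)
}

## Minimal allowance at which a pair recognizes a template: the smallest k
## such that pairRecognizes(..., k) is TRUE, computed from the feasible
## combos at the scan cap. Inf when never recognized within the cap.
.pairMinLevel <- function(pair, template, maxMm, allowance = "per-primer") {
  combos <- .pairCombos(pair, template, maxMm)$combos
  if (is.null(combos) || !nrow(combos)) return(Inf)
  if (allowance == "summed") min(combos$fwd_mm + combos$rev_mm)
  else min(pmax(combos$fwd_mm, combos$rev_mm))
}

#' Per-taxon coverage of a primer pair at several mismatch allowances
#'
#' The coverage/specificity engine: for every taxon at `rank` with at least one
#' sequence, the percentage of its database sequences recognized by the
#' pair at each allowance in `mmLevels`. Coverage is non-decreasing in
#' the allowance within each row. With `detailTaxon`, rows for that
#' taxon's genera are inserted after its own row (the layout used to
#' detail a target phylum by genus). Sequences whose fraction of `N`
#' exceeds `maxNFraction` are excluded (N matches every primer code, so
#' N-rich records inflate coverage).
#'
#' @inheritParams pairRecognizes
#' @param db A [ReferenceDatabase-class].
#' @param rank Rank at which to tabulate, default `"phylum"`.
#' @param mmLevels Mismatch allowances, default `0:2`.
#' @param maxNFraction N-content cap per template, default 0.05.
#' @param detailTaxon Optional taxon at `rank` to detail by genus.
#' @return `data.frame` with columns `taxon`, `rank`, `n` and one
#'   `cov_<k>` column per allowance (percentages, full precision).
#' @export
coverageTable <- function(pair, db, rank = "phylum", mmLevels = 0:2,
                          allowance = c("per-primer", "summed"),
                          maxNFraction = 0.05, detailTaxon = NULL) {
  allowance <- match.arg(allowance)
  if (length(db) == 0L) stop("'db' is empty")
  rank <- match.arg(rank, .RANKS)
  seqs <- as.character(refSequences(db))
  keep <- vapply(seqs, .nFraction, numeric(1L)) <= maxNFraction
  seqs <- seqs[keep]
  lin <- lineageTable(db)[keep, , drop = FALSE]
  cap <- max(mmLevels)
  levels_ <- vapply(seqs, function(s)
    .pairMinLevel(pair, s, cap, allowance), numeric(1L))

  rowFor <- function(taxon, atRank, idx) {
    cov <- vapply(mmLevels, function(k) 100 * mean(levels_[idx] <= k), numeric(1L))
    out <- data.frame(taxon = taxon, rank = atRank, n = length(idx))
    out[paste0("cov_", mmLevels)] <- as.list(cov)
    out
  }
  rowsAt <- function(atRank, within = NULL) {
    labels <- lin[[atRank]]
    sel <- if (is.null(within)) !is.na(labels)
           else !is.na(labels) & !is.na(lin[[rank]]) & lin[[rank]] == within
    taxa <- sort(unique(labels[sel]))
    do.call(rbind, lapply(taxa, function(tx)
      rowFor(tx, atRank, which(sel & labels == tx))))
  }
  res <- rowsAt(rank)
  if (!is.null(detailTaxon) && rank != "genus") {
    detail <- rowsAt("genus", within = detailTaxon)
    i <- match(detailTaxon, res$taxon)
    if (is.na(i)) stop(sprintf("taxon '%s' not present at rank '%s'", detailTaxon, rank))
    res <- rbind(res[i, ], detail,
                 res[setdiff(seq_len(nrow(res)), i), , drop = FALSE])
  }
  rownames(res) <- NULL
  res
}
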