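## ---------------------------------------------------------------------------
## In-silico PCR and primer-pair selection
## ---------------------------------------------------------------------------

## Primer-derived terminus with degenerate positions resolved against the
## template where they match; non-matching positions keep the primer symbol.
.resolveTerminus <- function(primerStr, templateRegion) {
  p <- strsplit(primerStr, "", fixed = TRUE)[[1L]]
  t <- strsplit(templateRegion, "", fixed = TRUE)[[1L]]
  hit <- codesMatch(p, t) & t %in% c("A", "C", "G", "T")
  p[hit] <- t[hit]
  paste(p, collapse = "")
}

#' Predict PCR products of a primer pair on a template
#'
#' Enumerates every (forward site, reverse site) combination with at most
#' `maxMm` mismatches per primer that satisfies orientation (forward site
#' entirely upstream of the reverse site) and the pair's product-length
#' bounds. The product length is the 1-based inclusive span from the
#' first forward-primer base to the last base of the reverse binding
#' site. Product sequences carry primer-derived termini, as in real PCR:
#' the forward primer verbatim at the 5' end and the reverse complement
#' of the reverse primer at the 3' end (IUPAC codes preserved unless
#' `resolveTermini = TRUE`, which substitutes the template base wherever
#' it matches the primer code).
#'
#' @inheritParams pairRecognizes
#' @param resolveTermini Resolve degenerate terminus positions to the
#'   template base where they match (default `FALSE`).
#' @return `data.frame` with columns `start`, `end`, `length`, `fwd_mm`,
#'   `rev_mm`, `product`; zero rows when nothing amplifies.
#' @examples
#' tpl <- paste0(strrep("A", 10), "ACGTACGTACGTACGTACGT",
#'               strrep("G", 60), "TTTTACCCGGGTTTTACCCA", strrep("C", 10))
#' pair <- primerPair("ACGTACGTACGTACGTACGT",
#'                    reverseComplementIupac("TTTTACCCGGGTTTTACCCA"))
#' predictAmplicons(pair, tpl)
#' @export
predictAmplicons <- function(pair, template, maxMm = 3L, resolveTermini = FALSE) {
  tpl <- .asSequenceString(template)
  combos <- .pairCombos(pair, tpl, maxMm)$combos
  empty <- data.frame(start = integer(0L), end = integer(0L),
                      length = integer(0L), fwd_mm = integer(0L),
                      rev_mm = integer(0L), product = character(0L))
  if (is.null(combos) || !nrow(combos)) return(empty)
  fwdSeq <- primerSequence(forwardPrimer(pair))
  revRc <- reverseComplementIupac(primerSequence(reversePrimer(pair)))
  combos$product <- vapply(seq_len(nrow(combos)), function(i) {
    b <- combos[i, ]
    head_ <- if (resolveTermini)
      .resolveTerminus(fwdSeq, substring(tpl, b$fwd_start, b$fwd_end)) else fwdSeq
    tail_ <- if (resolveTermini)
      .resolveTerminus(revRc, substring(tpl, b$rev_start, b$rev_end)) else revRc
    middle <- if (b$rev_start > b$fwd_end + 1L)
      substring(tpl, b$fwd_end + 1L, b$rev_start - 1L) else ""
    paste0(head_, middle, tail_)
  }, character(1L))
  out <- combos[order(combos$fwd_start, combos$rev_end),
                c("fwd_start", "rev_end", "length", "fwd_mm", "rev_mm", "product")]
  names(out)[1:2] <- c("start", "end")
  rownames(out) <- NULL
  out
}

#' Simulate nested PCR
#'
#' Runs the outer pair on the template, then the inner pair on every
#' outer product — the two-round protocol used to pull a rare clade out
#' of a complex community amplicon pool. Inner products keep the index
#' of the outer product they came from.
#'
#' @param outer,inner [PrimerPair-class] objects for the first and second
#'   round.
#' @param template Template sequence.
#' @param maxMmOuter,maxMmInner Mismatch allowances per round.
#' @param resolveTermini Passed to [predictAmplicons()].
#' @return `data.frame` as from [predictAmplicons()] plus an
#'   `outer_product` column; coordinates refer to the outer product.
#' @export
nestedPcr <- function(outer, inner, template, maxMmOuter = 3L, maxMmInner = 3L,
                      resolveTermini = FALSE) {
  round1 <- predictAmplicons(outer, template, maxMmOuter, resolveTermini)
  res <- lapply(seq_len(nrow(round1)), function(i) {
    r2 <- predictAmplicons(inner, round1$product[i], maxMmInner, resolveTermini)
    if (nrow(r2)) r2$outer_product <- i
    r2
  })
  res <- res[vapply(res, nrow, integer(1L)) > 0L]
  if (!length(res)) {
    out <- predictAmplicons(inner, "A", 0L)  # empty template => empty frame
    out$outer_product <- integer(0L)
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Deterministic stride subsample of indices (no RNG: screening must not
## perturb seeded pipelines).
.strideSample <- function(n, k) {
  if (n <= k) return(seq_len(n))
  unique(round(seq(1L, n, length.out = k)))
}

## Minimum-over-placements mismatch count of each probe against each
## template, probes given as consensus substrings.
.probeMinMm <- function(probeInts, templateInts) {
  vapply(templateInts, function(tt) {
    vapply(probeInts, function(pp) {
      prof <- .mismatchProfile(pp, tt)
      if (length(prof)) min(prof) else Inf
    }, numeric(1L))
  }, numeric(length(probeInts)))
}

## Minimal recognition level of a pair on one template from precomputed
## per-primer site tables.
.minLevelFromSites <- function(fwd, rev, lf, lr, bounds, allowance) {
  if (!nrow(fwd) || !nrow(rev)) return(Inf)
  g <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  fStart <- fwd$start[g$f]; rStart <- rev$start[g$r]
  len <- rStart + lr - 1L - fStart + 1L
  ok <- rStart > fStart + lf - 1L & len >= bounds[1L] & len <= bounds[2L]
  if (!any(ok)) return(Inf)
  if (allowance == "summed") min(fwd$mm[g$f][ok] + rev$mm[g$r][ok])
  else min(pmax(fwd$mm[g$f][ok], rev$mm[g$r][ok]))
}

#' Select primer pairs by coverage and specificity
#'
#' Scores every feasible forward/reverse candidate combination by
#' `score = coverage_in(mmSel) - lambda * coverage_out(mmSpec)` — wide
#' coverage of the target clade at a tight allowance, penalized by any
#' recognition outside it at a laxer allowance — and ranks pairs by
#' descending score, then fewer total degeneracies, then shorter total
#' length. Pair coverage uses the full recognition semantics
#' (orientation, product-length bounds, per-primer or summed allowance).
#'
#' Because scoring every candidate against every database sequence is the
#' expensive step, candidates are first screened individually on a
#' deterministic stride subsample of the database (`screenIn`/`screenOut`
#' sequences) and only the `keepPerSide` best per orientation enter exact
#' pair scoring; pairs whose consensus coordinates already violate the
#' product-length bounds are pruned before scoring.
#'
#' @param forwardCands,reverseCands Candidate `data.frame`s from
#'   [enumeratePrimers()] (orientations `"forward"` and `"reverse"`).
#' @param db A [ReferenceDatabase-class].
#' @param targetTaxon Taxon defining the in-group.
#' @param targetRank Rank of `targetTaxon`, default `"phylum"`.
#' @param mmSel Allowance at which in-group coverage is scored, default 1.
#' @param mmSpec Allowance at which out-group coverage is penalized,
#'   default 2.
#' @param lambda Specificity penalty weight, default 1.
#' @param minAmplicon,maxAmplicon Product-length bounds for scored pairs.
#' @param allowance `"per-primer"` (default) or `"summed"`.
#' @param keepPerSide Candidates per orientation entering exact pair
#'   scoring, default 25.
#' @param screenIn,screenOut Screening subsample sizes, defaults 30/60.
#' @return `data.frame` of scored pairs, best first: candidate ids,
#'   sequences and consensus coordinates of both primers, `coverage_in`,
#'   `coverage_out`, `score`, `total_degeneracy`, `total_length`. Zero
#'   rows (with a diagnostic attribute `"reason"`) when no pair is
#'   feasible.
#' @export
selectPrimerPairs <- function(forwardCands, reverseCands, db, targetTaxon,
                              targetRank = "phylum", mmSel = 1L, mmSpec = 2L,
                              lambda = 1, minAmplicon = 50L, maxAmplicon = 2000L,
                              allowance = c("per-primer", "summed"),
                              keepPerSide = 25L, screenIn = 30L, screenOut = 60L) {
  allowance <- match.arg(allowance)
  if (!nrow(forwardCands) || !nrow(reverseCands))
    stop("candidate lists must be nonempty")
  targetRank <- match.arg(targetRank, .RANKS)
  labels <- taxaAt(db, targetRank)
  if (!any(!is.na(labels) & labels == targetTaxon))
    stop(sprintf("target taxon '%s' not present at rank '%s'", targetTaxon, targetRank))
  inIdx <- which(!is.na(labels) & labels == targetTaxon)
  outIdx <- setdiff(seq_along(labels), inIdx)
  seqs <- as.character(refSequences(db))
  tplInts <- lapply(seqs, .iupacInts)
  cap <- max(mmSel, mmSpec)

  ## ---- stage 1: per-candidate screen on a stride subsample -------------
  screen <- function(cands) {
    ## the plus-strand probe of a reverse candidate is the consensus
    ## substring itself, i.e. the reverse complement of its primer sequence
    probes <- ifelse(cands$orientation == "reverse",
                     reverseComplementIupac(cands$sequence), cands$sequence)
    probeInts <- lapply(probes, .iupacInts)
    sIn <- inIdx[.strideSample(length(inIdx), screenIn)]
    sOut <- if (length(outIdx)) outIdx[.strideSample(length(outIdx), screenOut)]
            else integer(0L)
    mmIn <- .probeMinMm(probeInts, tplInts[sIn])
    covIn <- rowMeans(matrix(mmIn, nrow = length(probeInts)) <= mmSel)
    covOut <- if (length(sOut)) {
      mmOut <- .probeMinMm(probeInts, tplInts[sOut])
      rowMeans(matrix(mmOut, nrow = length(probeInts)) <= mmSpec)
    } else rep(0, length(probeInts))
    o <- order(-(covIn - lambda * covOut), cands$degeneracy, -cands$length)
    cands[o[seq_len(min(keepPerSide, nrow(cands)))], , drop = FALSE]
  }
  fwdKeep <- screen(forwardCands)
  revKeep <- screen(reverseCands)

  ## ---- stage 2: exact pair scoring on the full database ----------------
  siteTables <- function(cands, strand) {
    lapply(cands$sequence, function(s) {
      p <- degeneratePrimer("cand", s)
      lapply(seqs, function(t) .sites(p, t, strand, cap))
    })
  }
  fwdSites <- siteTables(fwdKeep, "plus")
  revSites <- siteTables(revKeep, "minus")
  bounds <- c(as.integer(minAmplicon), as.integer(maxAmplicon))

  rows <- list()
  for (i in seq_len(nrow(fwdKeep))) {
    for (j in seq_len(nrow(revKeep))) {
      ## prune by consensus coordinates when both carry them
      span <- revKeep$end[j] - fwdKeep$start[i] + 1L
      if (!is.na(span) && (revKeep$start[j] <= fwdKeep$end[i] ||
                           span < bounds[1L] || span > bounds[2L])) next
      lf <- fwdKeep$length[i]; lr <- revKeep$length[j]
      lev <- vapply(seq_along(seqs), function(s)
        .minLevelFromSites(fwdSites[[i]][[s]], revSites[[j]][[s]],
                           lf, lr, bounds, allowance), numeric(1L))
      covIn <- 100 * mean(lev[inIdx] <= mmSel)
      covOut <- if (length(outIdx)) 100 * mean(lev[outIdx] <= mmSpec) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_id = fwdKeep$id[i], fwd_sequence = fwdKeep$sequence[i],
        fwd_start = fwdKeep$start[i], fwd_end = fwdKeep$end[i],
        rev_id = revKeep$id[j], rev_sequence = revKeep$sequence[j],
        rev_start = revKeep$start[j], rev_end = revKeep$end[j],
        coverage_in = covIn, coverage_out = covOut,
        score = covIn - lambda * covOut,
        total_degeneracy = fwdKeep$degeneracy[i] + revKeep$degeneracy[j],
        total_length = lf + lr
      )
    }
  }
  if (!length(rows)) {
    out <- data.frame()
    attr(out, "reason") <- "no candidate pair satisfies the amplicon bounds"
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$total_degeneracy, out$total_length,
                   out$fwd_start, out$rev_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design clade-specific primer pairs from an alignment and a database
#'
#' The end-to-end design pipeline: build the threshold IUPAC consensus of
#' the target-clade alignment, extract low-degeneracy windows and merge
#' them into domains, enumerate all 20-30 nt candidates with at most two
#' degeneracies, and rank forward/reverse pairs by coverage of the target
#' taxon and specificity against the rest of the database.
#'
#' @param alignment Multiple alignment of the target clade (any form
#'   accepted by [buildConsensus()]).
#' @param db A [ReferenceDatabase-class] to screen against.
#' @param targetTaxon,targetRank The clade the primers must cover.
#' @param threshold Consensus threshold, default 0.90.
#' @param windowLength,maxDegeneracies Window parameters (15 nt, 2).
#' @param minLength,maxLength Candidate length bounds (20, 30).
#' @param ... Further arguments to [selectPrimerPairs()].
#' @return List with `profile` (the [ConsensusProfile-class]), `domains`,
#'   `candidates` and `pairs` (ranked `data.frame`).
#' @export
designPrimerPairs <- function(alignment, db, targetTaxon, targetRank = "phylum",
                              threshold = 0.90, windowLength = 15L,
                              maxDegeneracies = 2L, minLength = 20L,
                              maxLength = 30L, ...) {
  profile <- buildConsensus(alignment, threshold = threshold)
  domains <- primerDomains(profile, windowLength, maxDegeneracies)
  cands <- enumeratePrimers(domains, consensusSeq(profile), minLength,
                            maxLength, maxDegeneracies, orientation = "both")
  fwd <- cands[cands$orientation == "forward", , drop = FALSE]
  rev <- cands[cands$orientation == "reverse", , drop = FALSE]
  pairs <- if (nrow(fwd) && nrow(rev))
    selectPrimerPairs(fwd, rev, db, targetTaxon, targetRank, ...)
  else data.frame()
  list(profile = profile, domains = domains, candidates = cands, pairs = pairs)
}
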