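#' @importFrom Biostrings DNAString pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject
NULL

## Percent identity of two aligned (gapped) strings over the columns that
## remain after stripping terminal-gap columns; internal gaps count as
## mismatch columns.
.identityFromAligned <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  na <- which(ca != "-"); nb <- which(cb != "-")
  from <- max(na[1L], nb[1L])
  to <- min(na[length(na)], nb[length(nb)])
  if (to < from) return(0)
  100 * mean(ca[from:to] == cb[from:to])
}

.nwParams <- function(match = 1, mismatch = -1, gapOpen = 2, gapExtend = 1) {
  list(substitutionMatrix = nucleotideSubstitutionMatrix(match, mismatch,
                                                         baseOnly = FALSE),
       gapOpening = gapOpen, gapExtension = gapExtend)
}

#' Global alignment similarity of two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap opening
#' -2, gap extension -1 by default) with percent identity computed as
#' identities over alignment columns after stripping terminal-gap
#' columns.
#'
#' @param a,b Nucleotide sequences (character or `DNAString`).
#' @param match,mismatch,gapOpen,gapExtend Scoring parameters; `gapOpen`
#'   and `gapExtend` are costs (positive values).
#' @return List with `aligned_a`, `aligned_b` (gapped strings),
#'   `identity_pct` and `score`.
#' @examples
#' globalSimilarity("ACGTACGTAC", "ACGAACGTAC")$identity_pct  # 90
#' @export
globalSimilarity <- function(a, b, match = 1, mismatch = -1, gapOpen = 2,
                             gapExtend = 1) {
  a <- .asSequenceString(a); b <- .asSequenceString(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  pars <- .nwParams(match, mismatch, gapOpen, gapExtend)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = pars$substitutionMatrix,
                           gapOpening = pars$gapOpening,
                           gapExtension = pars$gapExtension)
  pa <- as.character(alignedPattern(aln))
  sa <- as.character(alignedSubject(aln))
  list(aligned_a = pa, aligned_b = sa,
       identity_pct = .identityFromAligned(pa, sa),
       score = as.numeric(Biostrings::score(aln)))
}

## Identities of one query against a set of references in a single
## vectorized pairwiseAlignment call. PID1 (identities over aligned
## columns plus internal gaps) equals the terminal-gap-stripped identity
## used throughout.
.identityVsSet <- function(query, refs, pars) {
  aln <- pairwiseAlignment(refs, DNAString(query), type = "global",
                           substitutionMatrix = pars$substitutionMatrix,
                           gapOpening = pars$gapOpening,
                           gapExtension = pars$gapExtension)
  Biostrings::pid(aln, type = "PID1")
}

#' Retrieve the most similar reference sequences
#'
#' Globally aligns the query against every database sequence and returns
#' up to `k` hits with identity at or above the cutoff, in descending
#' identity (ties broken by reference id for determinism). Queries are
#' orientation-normalized first: both strands are aligned and the better
#' one kept per reference.
#'
#' @param query Query sequence.
#' @param db A [ReferenceDatabase-class].
#' @param k Maximum number of hits, default 20.
#' @param cutoffPct Identity cutoff in percent, default 80.
#' @param orient Try both query orientations (default `TRUE`).
#' @param ... Scoring parameters passed to the aligner (see
#'   [globalSimilarity()]).
#' @return `data.frame` with columns `ref_id`, `identity_pct`, `lineage`
#'   (semicolon-joined); zero rows when nothing reaches the cutoff.
#' @export
topHits <- function(query, db, k = 20L, cutoffPct = 80, orient = TRUE, ...) {
  if (length(db) == 0L) stop("reference database is empty")
  query <- .asSequenceString(query)
  if (!nzchar(query)) stop("query must be nonempty")
  pars <- .nwParams(...)
  refs <- refSequences(db)
  ident <- .identityVsSet(query, refs, pars)
  if (orient) {
    identRc <- .identityVsSet(reverseComplementIupac(query), refs, pars)
    ident <- pmax(ident, identRc)
  }
  lin <- lineageTable(db)
  lineage <- apply(lin, 1L, function(r) paste(r[!is.na(r)], collapse = ";"))
  hits <- data.frame(ref_id = names(refs), identity_pct = ident,
                     lineage = unname(lineage))
  hits <- hits[hits$identity_pct >= cutoffPct, , drop = FALSE]
  hits <- hits[order(-hits$identity_pct, hits$ref_id), , drop = FALSE]
  hits <- utils::head(hits, k)
  rownames(hits) <- NULL
  hits
}

.splitLineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    out <- rep(NA_character_, length(.RANKS))
    out[seq_len(min(length(p), length(.RANKS)))] <- p[seq_len(min(length(p), length(.RANKS)))]
    out
  }, character(length(.RANKS))))
}

#' Step-wise consensus taxonomy from a hit list
#'
#' Starting at `startPct` the threshold is lowered step-wise until at
#' least one hit reaches it (or `floorPct` is passed, in which case the
#' query stays unassigned). Among the hits at the selected threshold the
#' assignment is the deepest rank — Domain > Phylum > Class > Order >
#' Family > Genus — at which *all* of them agree; hits whose lineage
#' lacks a rank cap the achievable depth.
#'
#' @param hits `data.frame` from [topHits()] (columns `ref_id`,
#'   `identity_pct`, `lineage`); may have zero rows.
#' @param startPct,floorPct,step Threshold descent parameters (99, 80, 1).
#' @return List with `rank`, `name`, `threshold`, `status`
#'   (`"assigned"`/`"unassigned"`) and `lineage` (the agreed prefix).
#' @export
consensusTaxonomy <- function(hits, startPct = 99, floorPct = 80, step = 1) {
  unassigned <- list(rank = NA_character_, name = NA_character_,
                     threshold = NA_real_, status = "unassigned",
                     lineage = NA_character_)
  if (is.null(hits) || nrow(hits) == 0L) return(unassigned)
  for (t in seq(startPct, floorPct, by = -abs(step))) {
    sel <- hits$identity_pct >= t
    if (!any(sel)) next
    ranks <- .splitLineage(hits$lineage[sel])
    depth <- 0L
    for (d in seq_len(ncol(ranks))) {
      vals <- ranks[, d]
      if (any(is.na(vals)) || length(unique(vals)) != 1L) break
      depth <- d
    }
    if (depth == 0L) return(unassigned)
    return(list(rank = .RANKS[depth], name = ranks[1L, depth],
                threshold = t, status = "assigned",
                lineage = paste(ranks[1L, seq_len(depth)], collapse = ";")))
  }
  unassigned
}

#' Classify query sequences against a reference database
#'
#' Convenience wrapper: [topHits()] then [consensusTaxonomy()] for each
#' query.
#'
#' @param queries Named character vector or `DNAStringSet` of queries.
#' @inheritParams topHits
#' @inheritParams consensusTaxonomy
#' @return `data.frame` with one row per query: `query_id`, `rank`,
#'   `name`, `threshold`, `best_identity`, `status`.
#' @export
classifySequences <- function(queries, db, k = 20L, cutoffPct = 80,
                              startPct = 99, floorPct = 80, step = 1,
                              orient = TRUE) {
  qs <- if (is(queries, "XStringSet")) as.character(queries) else queries
  ids <- names(qs)
  if (is.null(ids)) ids <- sprintf("query_%d", seq_along(qs))
  rows <- lapply(seq_along(qs), function(i) {
    hits <- topHits(qs[[i]], db, k = k, cutoffPct = cutoffPct, orient = orient)
    tax <- consensusTaxonomy(hits, startPct, floorPct, step)
    data.frame(query_id = ids[i], rank = tax$rank, name = tax$name,
               threshold = tax$threshold,
               best_identity = if (nrow(hits)) max(hits$identity_pct) else NA_real_,
               status = tax$status)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Average-linkage OTU clustering
## ---------------------------------------------------------------------------

#' Pairwise percent-identity matrix
#'
#' Global-alignment identities ([globalSimilarity()]) for every pair of
#' sequences; the input to OTU clustering.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param ... Scoring parameters (see [globalSimilarity()]).
#' @return Symmetric numeric matrix of identities in percent, 100 on the
#'   diagonal.
#' @export
pairwiseIdentityMatrix <- function(seqs, ...) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_len(n))
  pars <- .nwParams(...)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  refSet <- Biostrings::DNAStringSet(seqs)
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    ident <- .identityVsSet(seqs[[i]], refSet[idx], pars)
    m[i, idx] <- ident
    m[idx, i] <- ident
  }
  m
}

## Average-linkage agglomeration on a distance matrix, merging while the
## closest pair is within maxDist. Ties are broken by the pair of
## clusters whose (lexicographically smallest) member labels sort first,
## giving deterministic partitions.
.averageLinkagePartition <- function(D, maxDist, labels) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n), function(i) labels[i])
  sizes <- rep(1L, n)
  keys <- labels
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      cand <- c(D[i, j], sort(c(keys[i], keys[j])))
      if (is.null(best) ||
          D[i, j] < best$d - 1e-12 ||
          (abs(D[i, j] - best$d) <= 1e-12 &&
           paste(cand[2:3], collapse = "\r") < paste(best$key, collapse = "\r"))) {
        best <- list(i = i, j = j, d = D[i, j], key = cand[2:3])
      }
    }
    if (best$d > maxDist + 1e-12) break
    i <- best$i; j <- best$j
    merged <- c(clusters[[i]], clusters[[j]])
    wi <- sizes[i]; wj <- sizes[j]
    newRow <- (wi * D[i, ] + wj * D[j, ]) / (wi + wj)
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newRow[keep]),
               c(newRow[keep], 0))
    clusters <- c(clusters[keep], list(merged))
    sizes <- c(sizes[keep], wi + wj)
    keys <- c(keys[keep], min(merged))
  }
  clusters[order(vapply(clusters, min, character(1L)))]
}

#' Cluster sequences into OTUs by average linkage
#'
#' Computes the pairwise global-alignment identity matrix (distance =
#' 100 - identity), agglomerates by average linkage and stops when the
#' next merge distance would exceed `100 - cutoffPct`. At the usual 97%
#' cutoff, sequences within 3% average distance end up in the same OTU.
#' Equal-distance merges are resolved towards the clusters with the
#' lexicographically smallest member ids, so partitions are
#' deterministic.
#'
#' @param x Named character vector / `DNAStringSet` of sequences, or a
#'   precomputed symmetric percent-identity matrix (e.g. from
#'   [pairwiseIdentityMatrix()], reusable across cutoffs).
#' @param cutoffPct Similarity cutoff in percent, default 97.
#' @param ... Scoring parameters when `x` holds sequences.
#' @return An [OTUPartition-class].
#' @export
clusterOTUs <- function(x, cutoffPct = 97, ...) {
  if (is.matrix(x) && is.numeric(x)) {
    m <- x
    if (is.null(rownames(m))) rownames(m) <- colnames(m) <- sprintf("seq_%d", seq_len(nrow(m)))
  } else {
    if (is(x, "XStringSet")) x <- as.character(x)
    if (length(x) == 0L) stop("at least one sequence is required")
    m <- pairwiseIdentityMatrix(x, ...)
  }
  labels <- rownames(m)
  clusters <- .averageLinkagePartition(100 - m, 100 - cutoffPct, labels)
  new("OTUPartition", cutoff = cutoffPct, clusters = clusters,
      linkage = "average")
}

## ---------------------------------------------------------------------------
## Rarefaction
## ---------------------------------------------------------------------------

#' Rarefaction of an OTU partition
#'
#' Expected number of OTUs in a random subsample of `n` sequences drawn
#' without replacement. The analytic method uses the hypergeometric
#' expectation `E[S_n] = sum_i (1 - choose(N - N_i, n)/choose(N, n))`;
#' the Monte-Carlo method averages observed OTU counts over seeded
#' subsamples.
#'
#' @param x An [OTUPartition-class] or an integer vector of OTU sizes.
#' @param sampleSizes Subsample sizes; default `1:N`.
#' @param method `"analytic"` (default) or `"monte_carlo"`.
#' @param replicates Monte-Carlo replicates, default 1000.
#' @param seed Optional RNG seed for the Monte-Carlo method.
#' @return `data.frame` with columns `sample_size` and `expected_otus`;
#'   attributes `method`, `replicates`, `seed`.
#' @examples
#' rarefaction(c(3, 2, 1), sampleSizes = c(1, 3, 6))
#' @export
rarefaction <- function(x, sampleSizes = NULL,
                        method = c("analytic", "monte_carlo"),
                        replicates = 1000L, seed = NULL) {
  method <- match.arg(method)
  sizes <- if (is(x, "OTUPartition")) otuSizes(x) else as.integer(x)
  if (any(sizes < 1L)) stop("OTU sizes must be positive")
  N <- sum(sizes)
  if (is.null(sampleSizes)) sampleSizes <- seq_len(N)
  sampleSizes <- as.integer(sampleSizes)
  if (any(sampleSizes < 1L) || any(sampleSizes > N))
    stop(sprintf("sample sizes must lie in [1, %d]", N))
  expected <- if (method == "analytic") {
    vapply(sampleSizes, function(n)
      sum(1 - exp(lchoose(N - sizes, n) - lchoose(N, n))), numeric(1L))
  } else {
    if (!is.null(seed)) set.seed(seed)
    pop <- rep.int(seq_along(sizes), sizes)
    vapply(sampleSizes, function(n)
      mean(vapply(seq_len(replicates), function(r)
        length(unique(sample(pop, n))), numeric(1L))), numeric(1L))
  }
  out <- data.frame(sample_size = sampleSizes, expected_otus = expected)
  attr(out, "method") <- method
  attr(out, "replicates") <- if (method == "monte_carlo") replicates else NA_integer_
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else seed
  out
}
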