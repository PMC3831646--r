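#' @importFrom Biostrings DNAStringSet
NULL

## Fixed rank order used everywhere a lineage is walked.
.RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

## ---------------------------------------------------------------------------
## DegeneratePrimer
## ---------------------------------------------------------------------------

#' DegeneratePrimer: an oligonucleotide over the IUPAC alphabet
#'
#' Holds a named primer written 5'→3', optionally with 1-based inclusive
#' coordinates on a reference (the convention behind names such as
#' "f-326-350"). Degeneracy is the number of positions whose IUPAC code
#' expands to more than one base.
#'
#' @slot name Primer name.
#' @slot sequence IUPAC string, 5'→3', uppercase.
#' @slot refStart,refEnd Optional 1-based inclusive reference coordinates
#'   (`NA` when unknown).
#' @export
setClass("DegeneratePrimer",
  slots = c(
    name = "character",
    sequence = "character",
    refStart = "integer",
    refEnd = "integer"
  )
)

setValidity("DegeneratePrimer", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "sequence must be a single nonempty string")
  else {
    ok <- tryCatch({ .iupacInts(object@sequence); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
  }
  if (!is.na(object@refStart) && !is.na(object@refEnd) &&
      length(object@sequence) == 1L && nzchar(object@sequence) &&
      object@refEnd - object@refStart + 1L != nchar(object@sequence))
    msg <- c(msg, "refEnd - refStart + 1 must equal the sequence length")
  if (length(msg)) msg else TRUE
})

#' Construct a DegeneratePrimer
#'
#' @param name Primer name.
#' @param sequence IUPAC string (case-insensitive; `U` read as `T`).
#' @param refStart,refEnd Optional 1-based inclusive reference coordinates.
#' @return A [DegeneratePrimer-class] object.
#' @examples
#' degeneratePrimer("Deino-r-758-785", "GTTTAGGGYGTGGACTACCCGGGTATCT",
#'                  refStart = 758, refEnd = 785)
#' @export
degeneratePrimer <- function(name, sequence, refStart = NA_integer_,
                             refEnd = NA_integer_) {
  sequence <- .intsToIupac(.iupacInts(sequence))
  new("DegeneratePrimer", name = as.character(name), sequence = sequence,
      refStart = as.integer(refStart), refEnd = as.integer(refEnd))
}

#' @describeIn degeneratePrimer primer name accessor
#' @param x A `DegeneratePrimer`.
#' @export
setMethod("primerName", "DegeneratePrimer", function(x) x@name)

#' @describeIn degeneratePrimer primer sequence accessor
#' @export
setMethod("primerSequence", "DegeneratePrimer", function(x) x@sequence)

setMethod("show", "DegeneratePrimer", function(object) {
  coords <- if (!is.na(object@refStart))
    sprintf(" [%d-%d]", object@refStart, object@refEnd) else ""
  cat(sprintf("DegeneratePrimer %s%s\n  5'-%s-3' (%d nt, %d degeneracies)\n",
              object@name, coords, object@sequence, nchar(object@sequence),
              degeneracyCount(object@sequence)))
})

## ---------------------------------------------------------------------------
## PrimerPair
## ---------------------------------------------------------------------------

#' PrimerPair: a forward/reverse primer pair with amplicon bounds
#'
#' @slot forward,reverse [DegeneratePrimer-class] objects. The reverse
#'   primer is written 5'→3' on the minus strand, as primers are ordered.
#' @slot minAmplicon,maxAmplicon Accepted product-length bounds in nt
#'   (1-based inclusive span from the first forward-primer base to the
#'   last base of the reverse binding site).
#' @export
setClass("PrimerPair",
  slots = c(
    forward = "DegeneratePrimer",
    reverse = "DegeneratePrimer",
    minAmplicon = "integer",
    maxAmplicon = "integer"
  )
)

setValidity("PrimerPair", function(object) {
  if (object@minAmplicon < 1L || object@maxAmplicon < object@minAmplicon)
    "amplicon bounds must satisfy 1 <= minAmplicon <= maxAmplicon"
  else TRUE
})

#' Construct a PrimerPair
#'
#' @param forward,reverse [DegeneratePrimer-class] objects or plain IUPAC
#'   strings (wrapped with names "fwd"/"rev").
#' @param minAmplicon,maxAmplicon Product-length bounds in nt.
#' @return A [PrimerPair-class] object.
#' @export
primerPair <- function(forward, reverse, minAmplicon = 50L, maxAmplicon = 2000L) {
  if (is.character(forward)) forward <- degeneratePrimer("fwd", forward)
  if (is.character(reverse)) reverse <- degeneratePrimer("rev", reverse)
  new("PrimerPair", forward = forward, reverse = reverse,
      minAmplicon = as.integer(minAmplicon), maxAmplicon = as.integer(maxAmplicon))
}

#' @describeIn primerPair forward primer accessor
#' @param x A `PrimerPair`.
#' @export
setMethod("forwardPrimer", "PrimerPair", function(x) x@forward)

#' @describeIn primerPair reverse primer accessor
#' @export
setMethod("reversePrimer", "PrimerPair", function(x) x@reverse)

#' @describeIn primerPair amplicon length bounds, `c(min, max)`
#' @export
setMethod("ampliconBounds", "PrimerPair",
          function(x) c(min = x@minAmplicon, max = x@maxAmplicon))

setMethod("show", "PrimerPair", function(object) {
  cat("PrimerPair\n")
  show(object@forward)
  show(object@reverse)
  cat(sprintf("  amplicon bounds: %d-%d nt\n", object@minAmplicon, object@maxAmplicon))
})

#' The published Deinococcus-Thermus primer pair
#'
#' Deino-f-326-350 (5'-CGGGAGGCAGCAGTTAGGAATCTTC-3') and Deino-r-758-785
#' (5'-GTTTAGGGYGTGGACTACCCGGGTATCT-3'), named after their 1-based
#' binding coordinates on the 16S rRNA gene; the implied product spans
#' positions 326-785, i.e. 460 bp.
#'
#' @param minAmplicon,maxAmplicon Product-length bounds passed through to
#'   [primerPair()].
#' @return A [PrimerPair-class] object.
#' @examples
#' deinoPrimers()
#' @export
deinoPrimers <- function(minAmplicon = 50L, maxAmplicon = 2000L) {
  primerPair(
    degeneratePrimer("Deino-f-326-350", "CGGGAGGCAGCAGTTAGGAATCTTC",
                     refStart = 326L, refEnd = 350L),
    degeneratePrimer("Deino-r-758-785", "GTTTAGGGYGTGGACTACCCGGGTATCT",
                     refStart = 758L, refEnd = 785L),
    minAmplicon = minAmplicon, maxAmplicon = maxAmplicon
  )
}

## ---------------------------------------------------------------------------
## ConsensusProfile
## ---------------------------------------------------------------------------

#' ConsensusProfile: threshold-encoded IUPAC consensus of an alignment
#'
#' Produced by [buildConsensus()]. Stores, for every retained alignment
#' column, the non-gap base frequencies and the IUPAC code of the smallest
#' base set whose cumulative frequency reaches the threshold.
#'
#' @slot consensus IUPAC consensus string (one symbol per retained column).
#' @slot frequencies 4 x n matrix of non-gap base frequencies (rows
#'   A, C, G, T; columns sum to 1).
#' @slot threshold Consensus threshold in (0.5, 1].
#' @slot columnMap Integer vector mapping retained consensus positions to
#'   original alignment columns (1-based).
#' @slot nSequences Number of alignment rows the profile was built from.
#' @export
setClass("ConsensusProfile",
  slots = c(
    consensus = "character",
    frequencies = "matrix",
    threshold = "numeric",
    columnMap = "integer",
    nSequences = "integer"
  )
)

setValidity("ConsensusProfile", function(object) {
  msg <- character()
  n <- nchar(object@consensus)
  if (ncol(object@frequencies) != n)
    msg <- c(msg, "frequency matrix must have one column per consensus position")
  if (length(object@columnMap) != n)
    msg <- c(msg, "columnMap must have one entry per consensus position")
  if (n > 0L && any(abs(colSums(object@frequencies) - 1) > 1e-9))
    msg <- c(msg, "column frequencies must sum to 1")
  if (object@threshold <= 0.5 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in (0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildConsensus the IUPAC consensus string
#' @export
setMethod("consensusSeq", "ConsensusProfile", function(x) x@consensus)

#' @describeIn buildConsensus 4 x n matrix of per-column base frequencies
#' @export
setMethod("baseFrequencies", "ConsensusProfile", function(x) x@frequencies)

#' @describeIn buildConsensus retained-column to alignment-column map
#' @export
setMethod("columnMap", "ConsensusProfile", function(x) x@columnMap)

#' @describeIn buildConsensus the consensus threshold used
#' @export
setMethod("consensusThreshold", "ConsensusProfile", function(x) x@threshold)

setMethod("show", "ConsensusProfile", function(object) {
  n <- nchar(object@consensus)
  cat(sprintf(
    "ConsensusProfile: %d columns from %d sequences (threshold %.0f%%)\n",
    n, object@nSequences, 100 * object@threshold))
  cat(sprintf("  degenerate positions: %d\n", degeneracyCount(object@consensus)))
  if (n > 60L)
    cat(sprintf("  consensus: %s...\n", substr(object@consensus, 1L, 60L)))
  else if (n > 0L)
    cat(sprintf("  consensus: %s\n", object@consensus))
})

## ---------------------------------------------------------------------------
## ReferenceDatabase
## ---------------------------------------------------------------------------

#' ReferenceDatabase: unaligned sequences with taxonomic lineages
#'
#' SILVA-style reference container: a `DNAStringSet` of unaligned 16S
#' sequences plus a lineage table with the fixed rank order
#' Domain > Phylum > Class > Order > Family > Genus. Shorter lineages are
#' allowed; missing deep ranks are `NA`.
#'
#' @slot sequences Named `DNAStringSet`.
#' @slot lineage `data.frame` with columns `domain`..`genus`, one row per
#'   sequence, row names equal to sequence names.
#' @export
setClass("ReferenceDatabase",
  slots = c(sequences = "DNAStringSet", lineage = "data.frame")
)

setValidity("ReferenceDatabase", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be present and unique")
  if (!identical(rownames(object@lineage), ids))
    msg <- c(msg, "lineage rows must match sequence ids in order")
  if (!identical(colnames(object@lineage), .RANKS))
    msg <- c(msg, sprintf("lineage columns must be %s", paste(.RANKS, collapse = ", ")))
  if (nrow(object@lineage) && any(is.na(object@lineage$domain)))
    msg <- c(msg, "every record needs a nonempty lineage (domain at minimum)")
  if (length(msg)) msg else TRUE
})

#' @describeIn referenceDatabase the sequences as a `DNAStringSet`
#' @export
setMethod("refSequences", "ReferenceDatabase", function(x) x@sequences)

#' @describeIn referenceDatabase the lineage `data.frame`
#' @export
setMethod("lineageTable", "ReferenceDatabase", function(x) x@lineage)

#' @describeIn referenceDatabase per-sequence taxon labels at a rank
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @export
setMethod("taxaAt", "ReferenceDatabase", function(x, rank, ...) {
  rank <- match.arg(rank, .RANKS)
  stats::setNames(x@lineage[[rank]], rownames(x@lineage))
})

#' @describeIn referenceDatabase restrict the database to one taxon
#' @param taxon Taxon name to keep (or drop).
#' @param invert If `TRUE`, keep everything *except* `taxon`.
#' @export
setMethod("subsetByTaxon", "ReferenceDatabase",
          function(x, taxon, rank, invert = FALSE, ...) {
  rank <- match.arg(rank, .RANKS)
  keep <- !is.na(x@lineage[[rank]]) & x@lineage[[rank]] == taxon
  if (invert) keep <- !keep
  new("ReferenceDatabase", sequences = x@sequences[keep],
      lineage = x@lineage[keep, , drop = FALSE])
})

setMethod("length", "ReferenceDatabase", function(x) length(x@sequences))

setMethod("show", "ReferenceDatabase", function(object) {
  cat(sprintf("ReferenceDatabase: %d sequences\n", length(object)))
  if (length(object)) {
    phyla <- table(object@lineage$phylum, useNA = "no")
    cat(sprintf("  %d phyla, %d genera\n", length(phyla),
                length(unique(stats::na.omit(object@lineage$genus)))))
  }
})

## ---------------------------------------------------------------------------
## OTUPartition
## ---------------------------------------------------------------------------

#' OTUPartition: sequences clustered at a similarity cutoff
#'
#' Result of [clusterOTUs()]: a partition of sequence ids into OTUs by
#' average-linkage agglomeration at the stated percent-identity cutoff.
#'
#' @slot cutoff Similarity cutoff in percent (e.g. 97).
#' @slot clusters List of character vectors of member ids; together they
#'   partition the input ids.
#' @slot linkage Linkage method used (always `"average"` here).
#' @export
setClass("OTUPartition",
  slots = c(cutoff = "numeric", clusters = "list", linkage = "character")
)

setValidity("OTUPartition", function(object) {
  ids <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(ids)) "clusters must be disjoint" else TRUE
})

#' @describeIn clusterOTUs list of member-id vectors, one per OTU
#' @export
setMethod("otuClusters", "OTUPartition", function(x) x@clusters)

#' @describeIn clusterOTUs the similarity cutoff (percent)
#' @export
setMethod("otuCutoff", "OTUPartition", function(x) x@cutoff)

#' @describeIn clusterOTUs number of OTUs
#' @export
setMethod("nOtus", "OTUPartition", function(x) length(x@clusters))

#' @describeIn clusterOTUs integer vector of OTU sizes
#' @export
setMethod("otuSizes", "OTUPartition",
          function(x) vapply(x@clusters, length, integer(1L)))

setMethod("show", "OTUPartition", function(object) {
  cat(sprintf("OTUPartition: %d OTUs from %d sequences at %.4g%% similarity (%s linkage)\n",
              length(object@clusters),
              length(unlist(object@clusters, use.names = FALSE)),
              object@cutoff, object@linkage))
})
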