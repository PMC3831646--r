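#' @import methods
NULL

#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))

#' @export
setGeneric("primerSequence", function(x) standardGeneric("primerSequence"))

#' @export
setGeneric("forwardPrimer", function(x) standardGeneric("forwardPrimer"))

#' @export
setGeneric("reversePrimer", function(x) standardGeneric("reversePrimer"))

#' @export
setGeneric("ampliconBounds", function(x) standardGeneric("ampliconBounds"))

#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @export
setGeneric("baseFrequencies", function(x) standardGeneric("baseFrequencies"))

#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))

#' @export
setGeneric("consensusThreshold", function(x) standardGeneric("consensusThreshold"))

#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @export
setGeneric("lineageTable", function(x) standardGeneric("lineageTable"))

#' @export
setGeneric("taxaAt", function(x, rank, ...) standardGeneric("taxaAt"))

#' @export
setGeneric("subsetByTaxon", function(x, taxon, rank, ...) standardGeneric("subsetByTaxon"))

#' @export
setGeneric("otuClusters", function(x) standardGeneric("otuClusters"))

#' @export
setGeneric("otuCutoff", function(x) standardGeneric("otuCutoff"))

#' @export
setGeneric("nOtus", function(x) standardGeneric("nOtus"))

#' @export
setGeneric("otuSizes", function(x) standardGeneric("otuSizes"))
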