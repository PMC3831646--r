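#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
#' @importFrom utils read.delim write.table head
NULL

.formatError <- function(msg) {
  stop(errorCondition(msg, class = c("pcFormatError", "error", "condition")))
}

#' Read unaligned sequences from FASTA
#'
#' Wrapping and mixed case are tolerated; sequences are uppercased and
#' `U` is read as `T`. Gap characters are a format error: unaligned
#' nucleotide sequences must be gap-free.
#'
#' @param path FASTA file path.
#' @return Named `DNAStringSet`.
#' @export
readFastaSequences <- function(path) {
  x <- tryCatch(readBStringSet(path), error = function(e)
    .formatError(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e))))
  if (length(x) == 0L) .formatError(sprintf("FASTA '%s' contains no records", path))
  s <- toupper(as.character(x))
  s <- gsub("U", "T", s, fixed = TRUE)
  gapped <- grepl("[-.]", s)
  if (any(gapped))
    .formatError(sprintf("record '%s' contains gap characters; use readAlignedFasta()",
                         names(s)[gapped][1L]))
  ids <- sub("\\s.*$", "", names(s))
  if (anyDuplicated(ids))
    .formatError(sprintf("duplicate sequence id '%s'", ids[duplicated(ids)][1L]))
  names(s) <- ids
  for (i in seq_along(s)) .iupacInts(s[[i]])  # validate alphabet
  Biostrings::DNAStringSet(s)
}

#' Read an aligned FASTA file
#'
#' All records must have equal length; `.` gaps are normalized to `-`.
#'
#' @param path Aligned FASTA file path.
#' @return Named character vector of equal-length aligned sequences.
#' @export
readAlignedFasta <- function(path) {
  x <- tryCatch(readBStringSet(path), error = function(e)
    .formatError(sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e))))
  if (length(x) == 0L) .formatError(sprintf("FASTA '%s' contains no records", path))
  s <- toupper(as.character(x))
  s <- gsub("U", "T", s, fixed = TRUE)
  s <- gsub(".", "-", s, fixed = TRUE)
  names(s) <- sub("\\s.*$", "", names(s))
  lens <- nchar(s)
  if (length(unique(lens)) != 1L)
    .formatError(sprintf(
      "aligned FASTA '%s' has unequal record lengths (offending record: '%s', %d vs %d)",
      path, names(s)[which(lens != lens[1L])[1L]],
      lens[which(lens != lens[1L])[1L]], lens[1L]))
  s
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width, default 70.
#' @export
writeFastaSequences <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- BStringSet(seqs)
  writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a SILVA-style lineage table
#'
#' Two tab-separated columns without header: sequence id and a
#' semicolon-delimited lineage (`Domain;Phylum;Class;Order;Family;Genus`).
#' Shorter lineages are allowed; deeper ranks stay `NA`.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `id` plus the six ranks.
#' @export
readLineageTable <- function(path) {
  tab <- tryCatch(read.delim(path, header = FALSE, sep = "\t",
                             colClasses = "character",
                             col.names = c("id", "lineage")),
                  error = function(e)
                    .formatError(sprintf("cannot read lineage table '%s': %s",
                                         path, conditionMessage(e))))
  if (anyDuplicated(tab$id))
    .formatError(sprintf("duplicate id '%s' in lineage table",
                         tab$id[duplicated(tab$id)][1L]))
  ranks <- .splitLineage(tab$lineage)
  colnames(ranks) <- .RANKS
  cbind(data.frame(id = tab$id), as.data.frame(ranks, stringsAsFactors = FALSE))
}

#' Assemble a reference database from sequences and lineages
#'
#' Records missing from either side are dropped with a warning that
#' reports the count, so total-in always equals total-kept plus
#' total-dropped.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param lineages `data.frame` from [readLineageTable()], or a named
#'   character vector of semicolon-delimited lineage strings.
#' @return A [ReferenceDatabase-class].
#' @export
referenceDatabase <- function(sequences, lineages) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.character(lineages)) {
    ranks <- .splitLineage(unname(lineages))
    colnames(ranks) <- .RANKS
    lineages <- cbind(data.frame(id = names(lineages)),
                      as.data.frame(ranks, stringsAsFactors = FALSE))
  }
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    .formatError("sequence ids must be present and unique")
  common <- intersect(ids, lineages$id)
  droppedSeq <- setdiff(ids, common)
  droppedLin <- setdiff(lineages$id, common)
  if (length(droppedSeq))
    warning(sprintf("%d sequence(s) without lineage dropped", length(droppedSeq)))
  if (length(droppedLin))
    warning(sprintf("%d lineage record(s) without sequence dropped", length(droppedLin)))
  if (!length(common)) .formatError("no record has both a sequence and a lineage")
  lin <- lineages[match(common, lineages$id), .RANKS, drop = FALSE]
  rownames(lin) <- common
  new("ReferenceDatabase", sequences = sequences[common], lineage = lin)
}

#' Read a reference database from FASTA plus lineage TSV
#'
#' @param fastaPath Unaligned FASTA path.
#' @param lineagePath Two-column lineage TSV path.
#' @return A [ReferenceDatabase-class].
#' @export
readReferenceDatabase <- function(fastaPath, lineagePath) {
  referenceDatabase(readFastaSequences(fastaPath), readLineageTable(lineagePath))
}

## ---------------------------------------------------------------------------
## Report writers (all TSV, UTF-8, 1-based inclusive coordinates)
## ---------------------------------------------------------------------------

.writeTsv <- function(df, path, digits = 1) {
  num <- vapply(df, is.numeric, logical(1L)) &
    !vapply(df, is.integer, logical(1L))
  df[num] <- lapply(df[num], function(x) round(x, digits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a coverage/specificity report
#'
#' Coverage percentages are rounded to one decimal for display only; the
#' in-memory table keeps full precision.
#'
#' @param coverage `data.frame` from [coverageTable()].
#' @param path Output TSV path.
#' @export
writeCoverageTable <- function(coverage, path) .writeTsv(coverage, path)

#' Write ranked primer pairs
#' @param pairs `data.frame` from [selectPrimerPairs()].
#' @param path Output TSV path.
#' @export
writeRankedPairs <- function(pairs, path) .writeTsv(pairs, path, digits = 3)

#' Write amplicon predictions as TSV plus FASTA
#' @param amplicons `data.frame` from [predictAmplicons()] (optionally
#'   with a `sequence_id` column).
#' @param tsvPath,fastaPath Output paths (`fastaPath` optional).
#' @export
writeAmplicons <- function(amplicons, tsvPath, fastaPath = NULL) {
  .writeTsv(amplicons[, setdiff(names(amplicons), "product"), drop = FALSE], tsvPath)
  if (!is.null(fastaPath)) {
    ids <- if ("sequence_id" %in% names(amplicons))
      sprintf("%s_%d_%d", amplicons$sequence_id, amplicons$start, amplicons$end)
    else sprintf("amplicon_%d_%d", amplicons$start, amplicons$end)
    if (nrow(amplicons))
      writeFastaSequences(stats::setNames(amplicons$product, ids), fastaPath)
    else writeLines(character(0L), fastaPath)
  }
  invisible(tsvPath)
}

#' Write taxonomy assignments
#' @param assignments `data.frame` from [classifySequences()].
#' @param path Output TSV path.
#' @export
writeAssignments <- function(assignments, path) .writeTsv(assignments, path)

#' Write an OTU table
#'
#' One row per OTU: id, size, semicolon-joined member ids and the
#' representative (the longest member when sequences are supplied,
#' otherwise the lexicographically first id).
#'
#' @param partition An [OTUPartition-class].
#' @param path Output TSV path.
#' @param seqs Optional named sequences for representative picking.
#' @export
writeOtuTable <- function(partition, path, seqs = NULL) {
  cl <- otuClusters(partition)
  rep_ <- vapply(cl, function(members) {
    if (!is.null(seqs)) members[which.max(nchar(seqs[members]))]
    else sort(members)[1L]
  }, character(1L))
  df <- data.frame(
    otu_id = sprintf("OTU_%03d", seq_along(cl)),
    size = vapply(cl, length, integer(1L)),
    members = vapply(cl, function(m) paste(sort(m), collapse = ";"), character(1L)),
    representative = rep_
  )
  .writeTsv(df, path)
}

#' Write a rarefaction curve
#' @param curve `data.frame` from [rarefaction()].
#' @param path Output TSV path.
#' @export
writeRarefactionTable <- function(curve, path) .writeTsv(curve, path, digits = 4)

#' Write a run manifest
#'
#' Flat key-value record of the configuration, the package version and a
#' configuration hash, so identical configurations are recognizably
#' identical across runs.
#'
#' @param config Named list of run parameters.
#' @param path Output path.
#' @export
writeRunManifest <- function(config, path) {
  flat <- vapply(config, function(v) paste(format(v), collapse = ","), character(1L))
  tmp <- tempfile()
  writeLines(paste(names(flat), flat, sep = "="), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  lines <- c(
    sprintf("package=PrimerClade %s", as.character(utils::packageVersion("PrimerClade"))),
    sprintf("config_md5=%s", hash),
    paste(names(flat), flat, sep = "=")
  )
  writeLines(lines, path)
  invisible(path)
}
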