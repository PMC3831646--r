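#' Default run configuration
#'
#' The full parameter set binding the pipeline together, with defaults
#' reproducing the published design settings: 90% consensus, 15 nt
#' windows with at most 2 degeneracies, 20-30 nt candidates, scanning at
#' up to 3 mismatches, 20-hit classifier with the 99->80% step-wise
#' descent, and a 97% OTU cutoff.
#'
#' @return Named list of parameters.
#' @export
defaultRunConfig <- function() {
  list(
    consensus_threshold = 0.90,
    window_length = 15L,
    max_degeneracies = 2L,
    min_primer_length = 20L,
    max_primer_length = 30L,
    max_mismatches = 3L,
    mm_levels = "0,1,2",
    mm_sel = 1L,
    mm_spec = 2L,
    lambda = 1,
    min_amplicon = 50L,
    max_amplicon = 2000L,
    top_k = 20L,
    similarity_cutoff = 80,
    taxonomy_start = 99,
    taxonomy_floor = 80,
    taxonomy_step = 1,
    otu_cutoff = 97,
    seed = 1L
  )
}

#' Read a flat key=value configuration file
#'
#' One `key=value` pair per line; `#` starts a comment. Unknown keys are
#' an error, missing keys fall back to [defaultRunConfig()]. Values are
#' coerced to the type of the default.
#'
#' @param path Configuration file path (`NULL` for pure defaults).
#' @return Named list of parameters.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      .formatError(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (!key %in% names(cfg))
      .formatError(sprintf("unknown config key: '%s'", key))
    cfg[[key]] <- if (is.integer(cfg[[key]])) as.integer(val)
      else if (is.numeric(cfg[[key]])) as.numeric(val)
      else val
  }
  cfg
}
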