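## Independent brute-force oracles and small data helpers. These
## deliberately avoid the package's internal machinery: the IUPAC table is
## restated from its definition, matching and clustering are done the slow
## obvious way.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_match <- function(a, b) {
  length(intersect(ORACLE_IUPAC[[a]], ORACLE_IUPAC[[b]])) > 0L
}

## Minimum mismatches over all ungapped offsets: plain double loop over
## offsets and primer positions, using a match table derived by set
## expansion.
oracle_min_mm <- function(primer, template) {
  p <- strsplit(primer, "")[[1L]]
  t <- strsplit(template, "")[[1L]]
  L <- length(p); T_ <- length(t)
  if (L > T_) return(Inf)
  tab <- outer(names(ORACLE_IUPAC), names(ORACLE_IUPAC),
               Vectorize(oracle_match))
  dimnames(tab) <- list(names(ORACLE_IUPAC), names(ORACLE_IUPAC))
  best <- Inf
  for (o in seq_len(T_ - L + 1L)) {
    mm <- sum(!tab[cbind(p, t[o:(o + L - 1L)])])
    if (mm < best) best <- mm
  }
  best
}

## Threshold consensus of one column by exhaustive enumeration of all 15
## nonempty base subsets.
oracle_consensus_code <- function(freqs, threshold) {
  bases <- c("A", "C", "G", "T")
  f <- setNames(numeric(4L), bases)
  f[names(freqs)] <- freqs
  best <- NULL
  for (k in 1:4) {
    sets <- utils::combn(bases, k, simplify = FALSE)
    cand <- Filter(function(s) sum(f[s]) >= threshold - 1e-9, sets)
    if (!length(cand)) next
    cum <- vapply(cand, function(s) sum(f[s]), numeric(1L))
    cand <- cand[cum >= max(cum) - 1e-9]
    syms <- sort(vapply(cand, function(s) {
      names(Filter(function(e) setequal(e, s), ORACLE_IUPAC))[1L]
    }, character(1L)))
    best <- syms[1L]
    break
  }
  best
}

## Interval union of fixed-width windows via a coverage vector.
oracle_merge_windows <- function(starts, w, n) {
  cov <- logical(n)
  for (s in starts) cov[s:(s + w - 1L)] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  data.frame(start = begins[r$values], end = ends[r$values])
}

## Brute-force average linkage on a distance matrix: cluster-pair
## distances recomputed each round from the original matrix, same
## lexicographic tie rule as specified for the implementation.
oracle_average_linkage <- function(D, maxDist, labels = rownames(D)) {
  clusters <- lapply(seq_len(nrow(D)), function(i) labels[i])
  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      ai <- match(clusters[[i]], labels); aj <- match(clusters[[j]], labels)
      d <- mean(D[ai, aj])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           paste(key, collapse = "\r") < paste(best$key, collapse = "\r")))
        best <- list(i = i, j = j, d = d, key = key)
    }
    if (best$d > maxDist + 1e-12) break
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  canon <- lapply(clusters, sort)
  canon[order(vapply(canon, `[`, character(1L), 1L))]
}

canonical_partition <- function(clusters) {
  canon <- lapply(clusters, sort)
  canon[order(vapply(canon, `[`, character(1L), 1L))]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_iupac <- function(n, pDegen = 0.1) {
  degen <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  paste(ifelse(runif(n) < pDegen, sample(degen, n, TRUE),
               sample(c("A", "C", "G", "T"), n, TRUE)), collapse = "")
}

## Plant a subsequence at a 1-based position.
plant <- function(template, site, at) {
  paste0(substring(template, 1L, at - 1L), site,
         substring(template, at + nchar(site), nchar(template)))
}
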