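## ---------------------------------------------------------------------------
## Seeded synthetic databases and clone libraries
##
## Substitution-only hierarchical evolution (root -> phylum -> genus ->
## strain) with a planted clade-specific primer signature, so the whole
## design/scan/classify pipeline is testable without downloads. The
## scanner is ungapped, hence the default model plants no indels.
## ---------------------------------------------------------------------------

.randomSequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence by i.i.d. substitutions
#'
#' Every position is substituted independently with probability `rate`,
#' to a base drawn uniformly from the three alternatives. Uses the
#' current RNG state unless `seed` is given.
#'
#' @param sequence Nucleotide string.
#' @param rate Per-position substitution probability in `[0, 1)`.
#' @param seed Optional seed applied before drawing.
#' @return The mutated sequence string.
#' @export
mutateSequence <- function(sequence, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("'rate' must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

## Exactly k substitutions at distinct positions (decayed out-group
## signature homologs).
.injectSubstitutions <- function(sequence, k) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (k > length(chars)) stop("cannot inject more substitutions than positions")
  for (i in sample.int(length(chars), k)) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.replaceRegion <- function(sequence, start, replacement) {
  paste0(substring(sequence, 1L, start - 1L), replacement,
         substring(sequence, start + nchar(replacement), nchar(sequence)))
}

#' Generate a taxonomically structured synthetic reference database
#'
#' Simulates a hierarchy root -> phylum -> genus -> strain with
#' substitutions at the stated per-level rates, then plants a
#' clade-specific signature: every member of the target phylum carries
#' the forward site and the (plus-strand) reverse site exactly, while
#' every out-group sequence carries homologs of both sites degraded by
#' exactly `outgroupDecay` substitutions per site. Scanning the implied
#' primer pair at an allowance below `outgroupDecay` therefore recovers
#' the target clade and nothing else.
#'
#' Default sites are the published Deinococcus-Thermus signature: forward
#' site `CGGGAGGCAGCAGTTAGGAATCTTC` at positions 326-350 and the reverse
#' binding site ending at position 785, giving a 460 bp product. Lineages
#' are `Bacteria;Phylum_p;Class_p;Order_p;Family_p.f;Genus_p.g`, with two
#' genera per family so that family-level consensus fallback is
#' exercisable.
#'
#' @param nPhyla,generaPerPhylum,seqsPerGenus Database shape (defaults
#'   3, 4, 10).
#' @param seqLength Sequence length in nt, default 900.
#' @param phylumRate,genusRate,strainRate Per-level substitution rates
#'   (defaults 0.16, 0.06, 0.04 — roughly 16S-like divergence between
#'   phyla, between genera within a phylum, and between species/strains
#'   within a genus; the strain-level rate keeps the non-signature
#'   background variable relative to the planted signature).
#' @param targetPhylum Index of the phylum carrying the intact signature,
#'   default 1.
#' @param signatureFwd Forward site (IUPAC-free), planted on the plus
#'   strand at `fwdStart`.
#' @param signatureRev Plus-strand reverse binding site; the reverse
#'   primer is its reverse complement. Planted so that it ends at
#'   `revSiteEnd`.
#' @param fwdStart,revSiteEnd 1-based signature coordinates (326, 785).
#' @param outgroupDecay Substitutions injected into each out-group site
#'   homolog, default 4 (one more than the scanner's usual allowance).
#' @param seed RNG seed; fixes every random draw, so equal seeds give
#'   byte-identical databases.
#' @return List with `db` (a [ReferenceDatabase-class]), `truth`
#'   (`data.frame` of planted site coordinates and injected substitutions
#'   per sequence) and `pair` (the planted [PrimerPair-class]).
#' @export
generateReferenceDatabase <- function(nPhyla = 3L, generaPerPhylum = 4L,
                                      seqsPerGenus = 10L, seqLength = 900L,
                                      phylumRate = 0.16, genusRate = 0.06,
                                      strainRate = 0.04, targetPhylum = 1L,
                                      signatureFwd = "CGGGAGGCAGCAGTTAGGAATCTTC",
                                      signatureRev = "AGATACCCGGGTAGTCCACGCCCTAAAC",
                                      fwdStart = 326L, revSiteEnd = 785L,
                                      outgroupDecay = 4L, seed = 1L) {
  for (r in c(phylumRate, genusRate, strainRate))
    if (r < 0 || r >= 1) stop("substitution rates must lie in [0, 1)")
  if (degeneracyCount(signatureFwd) || degeneracyCount(signatureRev))
    stop("signature sites must be IUPAC-free")
  lf <- nchar(signatureFwd); lr <- nchar(signatureRev)
  revStart <- revSiteEnd - lr + 1L
  if (fwdStart < 1L || fwdStart + lf - 1L >= revStart || revSiteEnd > seqLength)
    stop("signature coordinates do not fit the sequence length")
  if (targetPhylum < 1L || targetPhylum > nPhyla)
    stop("'targetPhylum' must index one of the phyla")
  set.seed(seed)
  root <- .randomSequence(seqLength)
  ids <- character(0L); seqs <- character(0L)
  lin <- list(); truth <- list()
  for (p in seq_len(nPhyla)) {
    ancP <- mutateSequence(root, phylumRate)
    for (g in seq_len(generaPerPhylum)) {
      ancG <- mutateSequence(ancP, genusRate)
      fam <- (g + 1L) %/% 2L
      for (s in seq_len(seqsPerGenus)) {
        sq <- mutateSequence(ancG, strainRate)
        if (p == targetPhylum) {
          sq <- .replaceRegion(sq, fwdStart, signatureFwd)
          sq <- .replaceRegion(sq, revStart, signatureRev)
          decayed <- 0L
        } else {
          sq <- .replaceRegion(sq, fwdStart, .injectSubstitutions(signatureFwd, outgroupDecay))
          sq <- .replaceRegion(sq, revStart, .injectSubstitutions(signatureRev, outgroupDecay))
          decayed <- as.integer(outgroupDecay)
        }
        id <- sprintf("P%02dG%02dS%02d", p, g, s)
        ids <- c(ids, id); seqs <- c(seqs, sq)
        lin[[id]] <- c(domain = "Bacteria",
                       phylum = sprintf("Phylum_%02d", p),
                       class = sprintf("Class_%02d", p),
                       order = sprintf("Order_%02d", p),
                       family = sprintf("Family_%02d.%d", p, fam),
                       genus = sprintf("Genus_%02d.%d", p, g))
        truth[[id]] <- data.frame(
          seq_id = id, phylum = sprintf("Phylum_%02d", p),
          genus = sprintf("Genus_%02d.%d", p, g),
          fwd_start = fwdStart, fwd_end = fwdStart + lf - 1L,
          rev_start = revStart, rev_end = revSiteEnd,
          site_substitutions = decayed)
      }
    }
  }
  lineage <- as.data.frame(do.call(rbind, lin), stringsAsFactors = FALSE)
  rownames(lineage) <- ids
  db <- new("ReferenceDatabase",
            sequences = Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
            lineage = lineage[, .RANKS])
  pair <- primerPair(
    degeneratePrimer("synth-f", signatureFwd, refStart = fwdStart,
                     refEnd = fwdStart + lf - 1L),
    degeneratePrimer("synth-r", reverseComplementIupac(signatureRev),
                     refStart = revStart, refEnd = revSiteEnd)
  )
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(db = db, truth = truth, pair = pair)
}

#' Generate a synthetic clone library from a reference database
#'
#' Samples clone templates from the database with per-genus weights,
#' optionally trims each clone to the region amplified by a primer pair
#' (as a cloned PCR product would be), and applies i.i.d. substitution
#' noise. True taxonomy labels are returned alongside, so classifier
#' round-trips never have to re-derive ground truth.
#'
#' @param db A [ReferenceDatabase-class].
#' @param nClones Number of clones, at least 1.
#' @param weights Named numeric vector of sampling weights over genera
#'   (normalized internally); default uniform over all genera with at
#'   least one usable template (when a pair is supplied, the amplifiable
#'   ones). Names absent from the database are an error.
#' @param rate Per-clone substitution rate, default 0 (noise-free).
#' @param pair Optional [PrimerPair-class]; clones become predicted
#'   amplicons of their template, and templates the pair fails to
#'   amplify at `maxMm` are excluded from sampling.
#' @param maxMm Mismatch allowance for amplicon trimming, default 3.
#' @param seed RNG seed.
#' @return List with `clones` (named character vector) and `truth`
#'   (`data.frame` with `clone_id`, `source_id`, `phylum`, `genus`).
#' @export
generateCloneLibrary <- function(db, nClones, weights = NULL, rate = 0,
                                 pair = NULL, maxMm = 3L, seed = 1L) {
  if (length(db) == 0L) stop("'db' is empty")
  if (nClones < 1L) stop("'nClones' must be at least 1")
  genera <- taxaAt(db, "genus")
  present <- sort(unique(stats::na.omit(genera)))
  missing_ <- setdiff(names(weights), present)
  if (length(missing_))
    stop(sprintf("weights given for absent taxa: %s", paste(missing_, collapse = ", ")))
  seqs <- as.character(refSequences(db))
  lin <- lineageTable(db)
  eligible <- names(genera)[!is.na(genera)]
  if (!is.null(pair)) {
    amplified <- vapply(eligible, function(id)
      is.finite(.pairMinLevel(pair, seqs[[id]], maxMm)), logical(1L))
    eligible <- eligible[amplified]
    if (!length(eligible)) stop("the primer pair amplifies no eligible template")
  }
  if (is.null(weights)) {
    ## default: uniform over the genera that actually have templates
    ## (with a pair supplied, only amplifiable ones)
    amplifiable <- sort(unique(genera[eligible]))
    weights <- stats::setNames(rep(1, length(amplifiable)), amplifiable)
  }
  eligible <- eligible[genera[eligible] %in% names(weights)]
  weights <- weights / sum(weights)
  set.seed(seed)
  clones <- character(nClones); truthRows <- list()
  for (i in seq_len(nClones)) {
    gpick <- sample(names(weights), 1L, prob = weights)
    members <- eligible[genera[eligible] == gpick]
    if (!length(members)) stop(sprintf("no amplifiable template in genus %s", gpick))
    src <- if (length(members) == 1L) members else sample(members, 1L)
    tpl <- seqs[[src]]
    cl <- if (!is.null(pair)) {
      amp <- predictAmplicons(pair, tpl, maxMm)
      amp$product[1L]
    } else tpl
    if (rate > 0) cl <- mutateSequence(cl, rate)
    clones[i] <- cl
    truthRows[[i]] <- data.frame(clone_id = sprintf("clone_%03d", i),
                                 source_id = src,
                                 phylum = lin[src, "phylum"],
                                 genus = lin[src, "genus"])
  }
  truth <- do.call(rbind, truthRows)
  names(clones) <- truth$clone_id
  list(clones = clones, truth = truth)
}

#' Generate well-separated divergence groups
#'
#' Seeds `nGroups` independent random ancestors (mutually ~75%
#' divergent) and derives each group's members by light substitution
#' noise, so clustering at the usual 97% cutoff recovers exactly the
#' planted groups. Useful for OTU and rarefaction checks.
#'
#' @param nGroups Number of groups.
#' @param groupSizes Integer vector of members per group (recycled to
#'   `nGroups`).
#' @param seqLength Sequence length, default 460 (an amplicon-sized
#'   fragment).
#' @param withinRate Within-group substitution rate, default 0.005.
#' @param seed RNG seed.
#' @return List with `seqs` (named character vector) and `truth`
#'   (`data.frame` with `seq_id`, `group`).
#' @export
generateOtuGroups <- function(nGroups, groupSizes = 3L, seqLength = 460L,
                              withinRate = 0.005, seed = 1L) {
  set.seed(seed)
  groupSizes <- rep_len(as.integer(groupSizes), nGroups)
  seqs <- character(0L); truth <- list()
  for (g in seq_len(nGroups)) {
    anc <- .randomSequence(seqLength)
    for (m in seq_len(groupSizes[g])) {
      id <- sprintf("G%02dM%02d", g, m)
      seqs[id] <- mutateSequence(anc, withinRate)
      truth[[id]] <- data.frame(seq_id = id, group = g)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(seqs = seqs, truth = truth)
}
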