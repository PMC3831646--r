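test_that("mutation is rate-faithful and identity at rate zero", {
  set.seed(61)
  s <- rand_dna(500L)
  expect_identical(mutateSequence(s, 0), s)
  expect_error(mutateSequence(s, 1), "rate")

  long <- rand_dna(10000L)
  mut <- mutateSequence(long, 0.1, seed = 62L)
  nDiff <- sum(strsplit(long, "")[[1L]] != strsplit(mut, "")[[1L]])
  ## binomial 99% interval around 1000 for n = 10^4, p = 0.1
  expect_gt(nDiff, qbinom(0.005, 10000L, 0.1))
  expect_lt(nDiff, qbinom(0.995, 10000L, 0.1))
})

test_that("mutating a primer site raises its mismatch count by at most the edit count", {
  set.seed(63)
  tpl <- rand_dna(400L)
  primer <- substring(tpl, 151L, 175L)
  tpl2 <- tpl
  for (p in c(155L, 160L))
    substr(tpl2, p, p) <- setdiff(c("A", "C", "G", "T"), substring(tpl, p, p))[1L]
  before <- minMismatches(primer, tpl)$min_mismatches
  after <- minMismatches(primer, tpl2)$min_mismatches
  expect_lte(after - before, 2L)
})

test_that("database generation is seed-reproducible and plants the signature", {
  a <- generateReferenceDatabase(nPhyla = 2L, generaPerPhylum = 2L,
                                 seqsPerGenus = 2L, seqLength = 850L, seed = 64L)
  b <- generateReferenceDatabase(nPhyla = 2L, generaPerPhylum = 2L,
                                 seqsPerGenus = 2L, seqLength = 850L, seed = 64L)
  expect_identical(as.character(refSequences(a$db)), as.character(refSequences(b$db)))
  expect_identical(a$truth, b$truth)

  ## in-group sequences carry the sites exactly where truth says
  fwdSite <- primerSequence(forwardPrimer(a$pair))
  inIds <- a$truth$seq_id[a$truth$phylum == "Phylum_01"]
  for (id in inIds) {
    row <- a$truth[a$truth$seq_id == id, ]
    sq <- as.character(refSequences(a$db))[[id]]
    expect_identical(substring(sq, row$fwd_start, row$fwd_end), fwdSite)
  }

  ## out-group homologs carry exactly the stated number of substitutions
  outIds <- a$truth$seq_id[a$truth$phylum != "Phylum_01"]
  for (id in outIds[1:2]) {
    row <- a$truth[a$truth$seq_id == id, ]
    sq <- as.character(refSequences(a$db))[[id]]
    site <- substring(sq, row$fwd_start, row$fwd_end)
    nDiff <- sum(strsplit(site, "")[[1L]] != strsplit(fwdSite, "")[[1L]])
    expect_identical(nDiff, 4L)
  }
})

test_that("degenerate limit: zero rates and zero decay make every taxon identical", {
  g <- generateReferenceDatabase(nPhyla = 2L, generaPerPhylum = 2L,
                                 seqsPerGenus = 2L, seqLength = 850L,
                                 phylumRate = 0, genusRate = 0, strainRate = 0,
                                 outgroupDecay = 0L, seed = 65L)
  seqs <- as.character(refSequences(g$db))
  expect_true(all(seqs == seqs[[1L]]))
  ct <- coverageTable(g$pair, g$db, mmLevels = 0L)
  expect_true(all(ct$cov_0 == 100))
})

test_that("decayed out-group sites stay invisible to a 3-mismatch scan", {
  g <- generateReferenceDatabase(nPhyla = 3L, generaPerPhylum = 2L,
                                 seqsPerGenus = 3L, seqLength = 850L,
                                 outgroupDecay = 4L, seed = 66L)
  ct <- coverageTable(g$pair, g$db, mmLevels = 0:3)
  inRow <- ct[ct$taxon == "Phylum_01", ]
  outRows <- ct[ct$taxon != "Phylum_01", ]
  expect_equal(inRow$cov_0, 100)
  expect_true(all(outRows[, paste0("cov_", 0:3)] == 0))
})

test_that("clone libraries respect weights, truth labels and amplicon trimming", {
  g <- generateReferenceDatabase(nPhyla = 2L, generaPerPhylum = 2L,
                                 seqsPerGenus = 3L, seqLength = 850L, seed = 67L)
  lib <- generateCloneLibrary(g$db, nClones = 12L,
                              weights = c(`Genus_01.1` = 1),
                              pair = g$pair, seed = 68L)
  expect_identical(length(lib$clones), 12L)
  expect_true(all(lib$truth$genus == "Genus_01.1"))
  ## amplicon-trimmed clones have the planted product length
  expect_true(all(nchar(lib$clones) == 460L))
  ## noise-free clones start with the forward primer sequence
  expect_true(all(startsWith(lib$clones, primerSequence(forwardPrimer(g$pair)))))

  expect_error(generateCloneLibrary(g$db, 0L), "nClones")
  expect_error(generateCloneLibrary(g$db, 5L, weights = c(NoSuchGenus = 1)),
               "absent")
})

test_that("planted divergence groups are recovered as OTUs", {
  groups <- generateOtuGroups(6L, groupSizes = c(3L, 2L, 2L, 1L, 1L, 1L),
                              seqLength = 150L, withinRate = 0.005, seed = 69L)
  part <- clusterOTUs(groups$seqs, 97)
  expect_identical(nOtus(part), 6L)
  ## members of one OTU share a planted group
  for (cl in otuClusters(part)) {
    gids <- groups$truth$group[match(cl, groups$truth$seq_id)]
    expect_identical(length(unique(gids)), 1L)
  }
})
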