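test_that("global similarity behaves as a percent identity", {
  set.seed(51)
  a <- rand_dna(100L)
  expect_equal(globalSimilarity(a, a)$identity_pct, 100)

  b <- "ACGTACGTAC"
  b1 <- "ACGAACGTAC"  # one substitution in ten
  expect_equal(globalSimilarity(b, b1)$identity_pct, 90)

  ## symmetric
  x <- rand_dna(60L); y <- rand_dna(60L)
  expect_equal(globalSimilarity(x, y)$identity_pct,
               globalSimilarity(y, x)$identity_pct)

  ## orientation matters for the raw aligner
  z <- rand_dna(80L)
  expect_lt(globalSimilarity(z, reverseComplementIupac(z))$identity_pct, 100)
  expect_error(globalSimilarity("", "ACGT"), "nonempty")
})

test_that("top-hit retrieval filters, sorts and truncates deterministically", {
  set.seed(52)
  base <- rand_dna(200L)
  refs <- c(
    exact = base,
    setNames(vapply(1:24, function(i) mutateSequence(base, 0.05), character(1L)),
             paste0("near", sprintf("%02d", 1:24))),
    setNames(vapply(1:5, function(i) rand_dna(200L), character(1L)),
             paste0("far", 1:5))
  )
  lineages <- setNames(rep("Bacteria;P;C;O;F;G", length(refs)), names(refs))
  db <- referenceDatabase(refs, lineages)

  hits <- topHits(base, db, k = 20L, cutoffPct = 80)
  expect_identical(nrow(hits), 20L)
  expect_identical(hits$ref_id[1L], "exact")
  expect_equal(hits$identity_pct[1L], 100)
  expect_true(all(diff(hits$identity_pct) <= 0))
  expect_true(all(hits$identity_pct >= 80))

  ## brute-force check of the returned set
  all_ident <- vapply(names(refs), function(id)
    globalSimilarity(base, refs[[id]])$identity_pct, numeric(1L))
  ord <- order(-all_ident, names(refs))
  keep <- ord[all_ident[ord] >= 80][1:20]
  expect_setequal(hits$ref_id, names(refs)[keep])

  ## orientation normalization recovers reverse-complemented queries
  hitsRc <- topHits(reverseComplementIupac(base), db, k = 5L)
  expect_identical(hitsRc$ref_id[1L], "exact")
  expect_equal(hitsRc$identity_pct[1L], 100)

  expect_error(topHits(base, referenceDatabase(refs[0], lineages[0])))
})

test_that("consensus taxonomy walks thresholds and ranks as specified", {
  mkhits <- function(idents, lineages)
    data.frame(ref_id = sprintf("r%d", seq_along(idents)),
               identity_pct = idents, lineage = lineages)

  ## all hits >= 99 share the genus
  h1 <- mkhits(c(99.5, 99.2, 98.0),
               c("Bacteria;P;C;O;F;G1", "Bacteria;P;C;O;F;G1", "Bacteria;P;C;O;F;G2"))
  t1 <- consensusTaxonomy(h1)
  expect_identical(t1[c("rank", "name")], list(rank = "genus", name = "G1"))
  expect_equal(t1$threshold, 99)

  ## hits >= 99 split two genera of one family -> family
  h2 <- mkhits(c(99.5, 99.2),
               c("Bacteria;P;C;O;F;G1", "Bacteria;P;C;O;F;G2"))
  t2 <- consensusTaxonomy(h2)
  expect_identical(t2[c("rank", "name")], list(rank = "family", name = "F"))

  ## best hit 85%: stepwise descent stops there, phylum-level agreement only
  h3 <- mkhits(c(85.4, 85.2, 84.0),
               c("Bacteria;P;C1;O1;F1;G1", "Bacteria;P;C2;O2;F2;G2",
                 "Bacteria;Q;C3;O3;F3;G3"))
  t3 <- consensusTaxonomy(h3)
  expect_identical(t3$rank, "phylum")
  expect_identical(t3$name, "P")
  expect_equal(t3$threshold, 85)

  ## nothing at or above the floor -> unassigned
  expect_identical(consensusTaxonomy(mkhits(numeric(0L), character(0L)))$status,
                   "unassigned")

  ## short lineages cap the achievable depth
  h4 <- mkhits(c(99.5, 99.4),
               c("Bacteria;P;C;O", "Bacteria;P;C;O;F;G1"))
  expect_identical(consensusTaxonomy(h4)$rank, "order")

  ## invariant under hit-order permutation
  set.seed(53)
  for (i in 1:5) {
    idx <- sample(nrow(h3))
    expect_identical(consensusTaxonomy(h3[idx, ]), consensusTaxonomy(h3))
  }
})

test_that("OTU clustering reproduces hand-checked cases", {
  ## identical sequences collapse to one OTU
  seqs <- setNames(rep(rand_dna(80L), 4L), paste0("s", 1:4))
  expect_identical(nOtus(clusterOTUs(seqs, 97)), 1L)

  ## (A,B)=100, (A,C)=(B,C)=90 at cutoff 97 -> {A,B},{C}
  m <- matrix(c(100, 100, 90, 100, 100, 90, 90, 90, 100), 3L, 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  part <- clusterOTUs(m, 97)
  expect_identical(canonical_partition(otuClusters(part)),
                   list(c("A", "B"), "C"))

  ## cutoff 100: any difference separates
  set.seed(54)
  s1 <- rand_dna(100L); s2 <- mutateSequence(s1, 0.05)
  part100 <- clusterOTUs(c(a = s1, b = s2, c = s1), 100)
  expect_identical(canonical_partition(otuClusters(part100)),
                   list(c("a", "c"), "b"))
})

test_that("average linkage agrees with the brute-force oracle on random matrices", {
  set.seed(55)
  for (i in 1:30) {
    n <- sample(3:12, 1L)
    d <- matrix(runif(n * n, 0, 30), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    ids <- sprintf("s%02d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    maxDist <- runif(1, 0, 25)
    got <- canonical_partition(otuClusters(clusterOTUs(100 - d, 100 - maxDist)))
    exp <- oracle_average_linkage(d, maxDist)
    expect_identical(got, exp, info = paste("trial", i))
  }
})

test_that("average linkage agrees with hclust/cutree on tie-free instances", {
  set.seed(56)
  n <- 10L
  d <- matrix(runif(n * n, 1, 40), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
  ids <- sprintf("s%02d", seq_len(n)); dimnames(d) <- list(ids, ids)
  h <- stats::hclust(stats::as.dist(d), method = "average")
  for (cut in c(5, 12, 20, 30)) {
    ours <- canonical_partition(otuClusters(clusterOTUs(100 - d, 100 - cut)))
    ## cutree cuts strictly above h; merges at exactly the cut height are
    ## included by our rule, so compare at a height just above the cut
    ct <- stats::cutree(h, h = cut + 1e-9)
    theirs <- canonical_partition(split(names(ct), ct))
    expect_identical(ours, unname(theirs))
  }
})

test_that("OTU count is monotone non-increasing as the cutoff is lowered", {
  set.seed(57)
  groups <- generateOtuGroups(5L, groupSizes = 3L, seqLength = 120L,
                              withinRate = 0.02, seed = 58L)
  m <- pairwiseIdentityMatrix(groups$seqs)
  counts <- vapply(seq(100, 85, by = -1), function(cut)
    nOtus(clusterOTUs(m, cut)), integer(1L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("rarefaction closed form and Monte Carlo agree", {
  ## full sample recovers observed richness; all singletons give E = n
  expect_equal(rarefaction(c(3, 2, 1), sampleSizes = 6)$expected_otus, 3)
  singletons <- rarefaction(rep(1L, 12L))
  expect_equal(singletons$expected_otus, as.numeric(singletons$sample_size))

  sizes <- c(8L, 5L, 3L, 2L, 1L, 1L)
  an <- rarefaction(sizes, sampleSizes = c(5L, 10L, 15L, 20L))
  mc <- rarefaction(sizes, sampleSizes = c(5L, 10L, 15L, 20L),
                    method = "monte_carlo", replicates = 3000L, seed = 59L)
  ## SE of a mean of bounded counts (<= 6 OTUs) over 3000 reps is < 0.05
  expect_true(all(abs(an$expected_otus - mc$expected_otus) < 3 * 0.05))
  expect_true(all(diff(an$expected_otus) >= 0))
  expect_error(rarefaction(sizes, sampleSizes = 100L), "sample sizes")
})

test_that("rarefaction matches vegan's analytic curve", {
  skip_if_not_installed("vegan")
  sizes <- c(10L, 7L, 4L, 2L, 1L)
  ns <- c(3L, 8L, 14L, 24L)
  ours <- rarefaction(sizes, sampleSizes = ns)$expected_otus
  theirs <- as.numeric(vegan::rarefy(matrix(sizes, nrow = 1L), sample = ns))
  expect_equal(ours, theirs, tolerance = 1e-10)
})
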