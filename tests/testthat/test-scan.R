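test_that("exact hits, planted substitutions and degenerate matches are scored correctly", {
  set.seed(41)
  tpl <- rand_dna(300L)
  primer <- substring(tpl, 101L, 125L)
  r <- minMismatches(primer, tpl)
  expect_identical(r$min_mismatches, 0L)
  expect_identical(r$best_position, 101L)

  ## two planted substitutions, no better placement elsewhere
  mut <- primer
  substr(mut, 3L, 3L) <- setdiff(c("A", "C", "G", "T"), substring(primer, 3L, 3L))[1L]
  substr(mut, 20L, 20L) <- setdiff(c("A", "C", "G", "T"), substring(primer, 20L, 20L))[1L]
  expect_identical(minMismatches(mut, tpl)$min_mismatches,
                   as.integer(oracle_min_mm(mut, tpl)))

  ## primer Y over template C contributes no mismatch
  expect_identical(minMismatches("AYA", "GGACAGG")$min_mismatches, 0L)

  ## primer longer than template
  expect_identical(minMismatches(strrep("A", 10L), "ACGT")$min_mismatches, Inf)
})

test_that("the scanner equals the brute-force double loop on random instances", {
  set.seed(42)
  for (i in 1:60) {
    tpl <- rand_iupac(sample(40:200, 1L), pDegen = 0.03)
    primer <- rand_iupac(sample(8:25, 1L), pDegen = 0.15)
    expect_equal(minMismatches(primer, tpl)$min_mismatches,
                 oracle_min_mm(primer, tpl), info = paste("instance", i))
  }
})

test_that("plus and minus strand scans mirror each other", {
  set.seed(43)
  for (i in 1:10) {
    tpl <- rand_dna(150L)
    primer <- rand_iupac(18L, 0.1)
    plus <- scanPrimer(primer, tpl, "plus")
    minusOnRc <- scanPrimer(primer, reverseComplementIupac(tpl), "minus")
    expect_identical(plus, rev(minusOnRc))
  }
})

test_that("pair recognition enforces orientation, bounds and per-primer allowance", {
  set.seed(44)
  fwd <- rand_dna(20L); revBind <- rand_dna(20L)
  pair <- primerPair(fwd, reverseComplementIupac(revBind),
                     minAmplicon = 100L, maxAmplicon = 1000L)
  tpl <- paste0(rand_dna(50L), fwd, rand_dna(260L), revBind, rand_dna(50L))
  hit <- pairRecognizes(pair, tpl, maxMm = 3L)
  expect_true(hit$recognized)
  expect_identical(hit$reason, "ok")
  expect_identical(hit$product_length, hit$rev_end - hit$fwd_start + 1L)

  ## reverse site upstream of forward site -> orientation failure
  tplSwap <- paste0(rand_dna(50L), revBind, rand_dna(260L), fwd, rand_dna(50L))
  swap <- pairRecognizes(pair, tplSwap, maxMm = 0L)
  expect_false(swap$recognized)
  expect_identical(swap$reason, "orientation")

  ## reverse site degraded by 4 substitutions -> no_rev at maxMm 3
  revBad <- revBind
  for (p in c(2L, 7L, 12L, 18L))
    substr(revBad, p, p) <- setdiff(c("A", "C", "G", "T"), substring(revBind, p, p))[1L]
  tplBad <- paste0(rand_dna(50L), fwd, rand_dna(260L), revBad, rand_dna(50L))
  bad <- pairRecognizes(pair, tplBad, maxMm = 3L)
  expect_false(bad$recognized)
  expect_identical(bad$reason, "no_rev")

  ## product too short for the bounds -> length failure
  tplShort <- paste0(rand_dna(10L), fwd, rand_dna(20L), revBind, rand_dna(10L))
  short <- pairRecognizes(pair, tplShort, maxMm = 0L)
  expect_false(short$recognized)
  expect_identical(short$reason, "length")

  ## recognition is monotone in the allowance
  for (k in 0:2)
    if (pairRecognizes(pair, tplBad, k)$recognized)
      expect_true(pairRecognizes(pair, tplBad, k + 1L)$recognized)
})

test_that("summed allowance is stricter than per-primer at the same cap", {
  set.seed(45)
  fwd <- rand_dna(20L); revBind <- rand_dna(20L)
  fwdMut <- fwd; substr(fwdMut, 5L, 5L) <- setdiff(c("A","C","G","T"), substring(fwd, 5L, 5L))[1L]
  revMut <- revBind; substr(revMut, 5L, 5L) <- setdiff(c("A","C","G","T"), substring(revBind, 5L, 5L))[1L]
  tpl <- paste0(rand_dna(30L), fwdMut, rand_dna(200L), revMut, rand_dna(30L))
  pair <- primerPair(fwd, reverseComplementIupac(revBind))
  expect_true(pairRecognizes(pair, tpl, 1L, allowance = "per-primer")$recognized)
  expect_false(pairRecognizes(pair, tpl, 1L, allowance = "summed")$recognized)
  expect_true(pairRecognizes(pair, tpl, 2L, allowance = "summed")$recognized)
})

test_that("coverage tables report per-taxon recognition and are monotone in allowance", {
  set.seed(46)
  fwd <- rand_dna(22L); revBind <- rand_dna(22L)
  pair <- primerPair(fwd, reverseComplementIupac(revBind))
  mkSeq <- function(withSites, mutateFwd = 0L) {
    f <- fwd
    if (mutateFwd > 0L)
      for (p in seq_len(mutateFwd))
        substr(f, p, p) <- setdiff(c("A", "C", "G", "T"), substring(fwd, p, p))[1L]
    if (withSites) paste0(rand_dna(40L), f, rand_dna(200L), revBind, rand_dna(40L))
    else rand_dna(326L)
  }
  seqs <- c(
    setNames(vapply(1:3, function(i) mkSeq(TRUE), character(1L)), paste0("in", 1:3)),
    in4 = mkSeq(TRUE, mutateFwd = 1L),
    setNames(vapply(1:4, function(i) mkSeq(FALSE), character(1L)), paste0("out", 1:4))
  )
  lineages <- setNames(c(rep("Bacteria;PhyA;c;o;f;gA", 4L),
                         rep("Bacteria;PhyB;c;o;f;gB", 4L)), names(seqs))
  db <- referenceDatabase(seqs, lineages)
  ct <- coverageTable(pair, db, rank = "phylum", mmLevels = 0:2)
  a <- ct[ct$taxon == "PhyA", ]
  b <- ct[ct$taxon == "PhyB", ]
  expect_identical(a$n, 4L)
  expect_equal(a$cov_0, 75)   # 3 of 4 perfect
  expect_equal(a$cov_1, 100)  # the 1-mismatch sequence joins at 1
  expect_equal(b$cov_0 + b$cov_1, 0)
  expect_true(all(diff(unlist(a[paste0("cov_", 0:2)])) >= 0))
  expect_true(all(diff(unlist(b[paste0("cov_", 0:2)])) >= 0))
})

test_that("genus detail rows are inserted after the target phylum row", {
  g <- generateReferenceDatabase(nPhyla = 2L, generaPerPhylum = 2L,
                                 seqsPerGenus = 3L, seqLength = 850L, seed = 5L)
  ct <- coverageTable(g$pair, g$db, rank = "phylum", mmLevels = 0:2,
                      detailTaxon = "Phylum_01")
  expect_identical(ct$taxon[1L], "Phylum_01")
  expect_identical(ct$rank[2:3], rep("genus", 2L))
  expect_true(all(startsWith(ct$taxon[2:3], "Genus_01")))
  expect_identical(ct$rank[4L], "phylum")
})
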