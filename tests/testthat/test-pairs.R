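test_that("the published coordinates imply a 460 bp product", {
  ## template carrying perfect binding sites exactly at 326-350 / 758-785
  set.seed(71)
  pair <- deinoPrimers()
  tpl <- rand_dna(900L)
  tpl <- plant(tpl, primerSequence(forwardPrimer(pair)), 326L)
  tpl <- plant(tpl, reverseComplementIupac(primerSequence(reversePrimer(pair))), 758L)
  amp <- predictAmplicons(pair, tpl, maxMm = 0L)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$start, 326L)
  expect_identical(amp$end, 785L)
  expect_identical(amp$length, 460L)
  expect_identical(amp$length, amp$end - amp$start + 1L)
})

test_that("amplicon products carry primer-derived termini", {
  set.seed(72)
  fwd <- rand_dna(22L)
  revBind <- rand_dna(24L)
  pair <- primerPair(paste0(substring(fwd, 1L, 10L), "Y", substring(fwd, 12L)),
                     reverseComplementIupac(revBind))
  tpl <- paste0(rand_dna(40L), fwd, rand_dna(150L), revBind, rand_dna(40L))
  amp <- predictAmplicons(pair, tpl, maxMm = 1L)
  expect_identical(nrow(amp), 1L)
  expect_true(startsWith(amp$product, primerSequence(forwardPrimer(pair))))
  expect_true(endsWith(amp$product,
                       reverseComplementIupac(primerSequence(reversePrimer(pair)))))
  expect_identical(nchar(amp$product), amp$length)

  ## resolved termini replace degenerate codes by the matching template base
  ampR <- predictAmplicons(pair, tpl, maxMm = 1L, resolveTermini = TRUE)
  expect_identical(substring(ampR$product, 1L, 22L), fwd)
})

test_that("multiple reverse sites yield multiple products within bounds", {
  set.seed(73)
  fwd <- rand_dna(20L); revBind <- rand_dna(20L)
  pair <- primerPair(fwd, reverseComplementIupac(revBind),
                     minAmplicon = 50L, maxAmplicon = 2000L)
  tpl <- paste0(rand_dna(20L), fwd, rand_dna(80L), revBind, rand_dna(80L),
                revBind, rand_dna(20L))
  amp <- predictAmplicons(pair, tpl, maxMm = 0L)
  expect_identical(nrow(amp), 2L)
  expect_true(all(amp$length >= 50L & amp$length <= 2000L))
})

test_that("nested PCR amplifies inside the outer product and only there", {
  set.seed(74)
  oF <- rand_dna(20L); oR <- rand_dna(20L)
  iF <- rand_dna(20L); iR <- rand_dna(20L)
  outer_ <- primerPair(oF, reverseComplementIupac(oR))
  inner <- primerPair(iF, reverseComplementIupac(iR))
  tpl <- paste0(rand_dna(30L), oF, rand_dna(25L), iF, rand_dna(120L), iR,
                rand_dna(25L), oR, rand_dna(30L))
  nested <- nestedPcr(outer_, inner, tpl, 0L, 0L)
  expect_identical(nrow(nested), 1L)
  ## consistency: direct inner amplification gives the same product
  direct <- predictAmplicons(inner, tpl, 0L)
  expect_identical(nested$product, direct$product)

  ## inner forward site outside the outer product -> nothing
  tpl2 <- paste0(rand_dna(10L), iF, rand_dna(20L), oF, rand_dna(120L), iR,
                 rand_dna(25L), oR, rand_dna(30L))
  expect_identical(nrow(nestedPcr(outer_, inner, tpl2, 0L, 0L)), 0L)

  ## a 1-mismatch outer site gates the nested result on the outer allowance
  oFmut <- oF
  substr(oFmut, 5L, 5L) <- setdiff(c("A", "C", "G", "T"), substring(oF, 5L, 5L))[1L]
  tpl3 <- paste0(rand_dna(30L), oFmut, rand_dna(25L), iF, rand_dna(120L), iR,
                 rand_dna(25L), oR, rand_dna(30L))
  expect_identical(nrow(nestedPcr(outer_, inner, tpl3, 0L, 0L)), 0L)
  expect_identical(nrow(nestedPcr(outer_, inner, tpl3, 1L, 0L)), 1L)
})

test_that("pair selection recovers a planted signature on a toy database", {
  set.seed(75)
  fwdSite <- rand_dna(24L)
  revSite <- rand_dna(24L)
  mkIn <- function() {
    s <- rand_dna(400L)
    s <- plant(s, fwdSite, 61L)
    plant(s, revSite, 301L)
  }
  seqs <- c(
    setNames(vapply(1:6, function(i) mkIn(), character(1L)), paste0("in", 1:6)),
    setNames(vapply(1:6, function(i) rand_dna(400L), character(1L)), paste0("out", 1:6))
  )
  lineages <- setNames(c(rep("Bacteria;Target;c;o;f;gT", 6L),
                         rep("Bacteria;Other;c;o;f;gO", 6L)), names(seqs))
  db <- referenceDatabase(seqs, lineages)
  fwdCands <- data.frame(id = "f", sequence = substring(fwdSite, 1L, 22L),
                         start = 61L, end = 82L, length = 22L, degeneracy = 0L,
                         orientation = "forward")
  decoy <- data.frame(id = "fd", sequence = rand_dna(22L), start = 10L,
                      end = 31L, length = 22L, degeneracy = 0L,
                      orientation = "forward")
  revCands <- data.frame(id = "r",
                         sequence = reverseComplementIupac(substring(revSite, 1L, 22L)),
                         start = 301L, end = 322L, length = 22L, degeneracy = 0L,
                         orientation = "reverse")
  ranked <- selectPrimerPairs(rbind(fwdCands, decoy), revCands, db, "Target",
                              mmSel = 1L, mmSpec = 2L)
  expect_identical(ranked$fwd_id[1L], "f")
  expect_equal(ranked$coverage_in[1L], 100)
  expect_equal(ranked$coverage_out[1L], 0)

  ## lambda = 0: ranking depends only on in-group coverage
  r0 <- selectPrimerPairs(rbind(fwdCands, decoy), revCands, db, "Target",
                          mmSel = 1L, mmSpec = 2L, lambda = 0)
  expect_identical(r0$score, r0$coverage_in)

  ## swapping the group labels inverts which pair scores positively
  swapped <- selectPrimerPairs(rbind(fwdCands, decoy), revCands, db, "Other",
                               mmSel = 1L, mmSpec = 2L)
  best <- swapped[1L, ]
  expect_lte(best$coverage_in, 100)
  expect_identical(swapped$coverage_in[swapped$fwd_id == "f"], 0)
  expect_identical(swapped$coverage_out[swapped$fwd_id == "f"], 100)

  expect_error(selectPrimerPairs(fwdCands[0, ], revCands, db, "Target"),
               "nonempty")
  expect_error(selectPrimerPairs(fwdCands, revCands, db, "NoSuchTaxon"),
               "not present")
})
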