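mkPileup <- function(counts, locus = "locus1") {
  rownames(counts) <- c("A", "C", "G", "T")
  list(locus = locus, counts = counts, nReads = max(colSums(counts)))
}

test_that("consensus follows majority / single-read / template rules", {
  # 4 positions: A:3 G:1 -> A; zero coverage -> template; coverage 1 ->
  # observed; tie at coverage 2 -> template
  counts <- matrix(0L, 4, 4)
  counts[1, 1] <- 3L; counts[3, 1] <- 1L     # majority A
  counts[4, 3] <- 1L                         # single read T
  counts[1, 4] <- 1L; counts[3, 4] <- 1L     # tie A/G
  cons <- consensusAllele(mkPileup(counts), template = "GGGG")
  expect_equal(cons, "AGTG")
})

test_that("error-free reads reproduce the true allele and its ST", {
  sch <- simulateMlstScheme(seed = 121)
  st1 <- vapply(sch$loci, function(l) sch$alleles[[l]][["1"]], "")
  rd <- simulateMlstReads(st1, readLen = 100, coverage = 10,
                          errorRate = 0, seed = 1)
  prof <- assignST(buildPileups(rd$reads, sch), sch, "s0")
  expect_identical(unname(prof@alleleSeqs), unname(st1))
  expect_equal(sequenceType(prof), "1")

  # an uncatalogued allele (one SNP) makes the locus "new", the ST novel
  mut <- st1
  mut[3] <- mutateAt(mut[3], 200)
  rdM <- simulateMlstReads(mut, readLen = 100, coverage = 10,
                           errorRate = 0, seed = 2)
  profM <- assignST(buildPileups(rdM$reads, sch), sch, "s1")
  expect_equal(profM@alleleIds[3], "new")
  expect_equal(sequenceType(profM), "novel")

  # a locus with no reads at all -> incomplete
  rdI <- rd$reads[rd$reads$locus != "locus2", ]
  profI <- assignST(buildPileups(rdI, sch), sch, "s2")
  expect_equal(sequenceType(profI), "incomplete")
})

test_that("consensus recovery holds at 20x coverage with 1% error", {
  exact <- vapply(1:5, function(s) {
    sch <- simulateMlstScheme(seed = 130 + s)
    true <- vapply(sch$loci, function(l) sch$alleles[[l]][["2"]], "")
    rd <- simulateMlstReads(true, readLen = 100, coverage = 20,
                            errorRate = 0.01, seed = 700 + s)
    prof <- assignST(buildPileups(rd$reads, sch), sch, "s")
    all(prof@alleleSeqs == unname(true))
  }, TRUE)
  expect_gte(sum(exact), 4L)
})

test_that("the strain-identity rule matches brute force on the exhaustive
           truth table", {
  sch <- simulateMlstScheme(seed = 141)
  base <- vapply(sch$loci, function(l) sch$alleles[[l]][["1"]], "")
  mkProfile <- function(seqs, id) methods::new(
    "MLSTProfile", sampleId = id, loci = sch$loci,
    alleleIds = rep("1", 8), alleleSeqs = unname(seqs), st = "novel")
  pa <- mkProfile(base, "a")

  # all combinations of 0-2 differing loci x 1-2 SNPs per differing locus
  for (nDiff in 0:2) {
    lociSets <- if (nDiff == 0) list(integer(0)) else
      combn(8, nDiff, simplify = FALSE)[c(1, 5, 10)[seq_len(min(3,
        choose(8, nDiff)))]]
    lociSets <- lociSets[!vapply(lociSets, is.null, TRUE)]
    for (lociIdx in lociSets) {
      snpGrid <- if (nDiff == 0) list(integer(0)) else
        do.call(expand.grid, rep(list(1:2), nDiff))
      if (nDiff > 0) snpGrid <- split(as.matrix(snpGrid), row(as.matrix(
        snpGrid)))
      for (snps in snpGrid) {
        seqs <- base
        snpCounts <- setNames(rep(0L, 8), sch$loci)
        for (k in seq_along(lociIdx)) {
          seqs[lociIdx[k]] <- mutateAt(seqs[lociIdx[k]],
                                       seq_len(snps[k]) * 37)
          snpCounts[lociIdx[k]] <- snps[k]
        }
        res <- strainsIdentical(pa, mkProfile(seqs, "b"))
        expect_equal(res$identical, strainRuleOracle(snpCounts),
                     label = paste("diff loci", nDiff, "snps",
                                   paste(snps, collapse = ",")))
        expect_equal(unname(res$snps), unname(snpCounts))
      }
    }
  }

  # headline cases of the rule
  same <- strainsIdentical(pa, pa)
  expect_true(same$identical)                       # 8/8 identical
  one1 <- mkProfile(replace(base, 1, mutateAt(base[1], 50)), "b")
  expect_true(strainsIdentical(pa, one1)$identical) # 7/8, 1 SNP
  one2 <- mkProfile(replace(base, 1, mutateAt(base[1], c(50, 90))), "b")
  expect_false(strainsIdentical(pa, one2)$identical) # 7/8 but 2 SNPs
  two <- mkProfile(replace(base, 1:2,
                           c(mutateAt(base[1], 50),
                             mutateAt(base[2], 60))), "b")
  expect_false(strainsIdentical(pa, two)$identical)  # 6/8 identical

  # symmetry
  expect_equal(strainsIdentical(pa, one1)$identical,
               strainsIdentical(one1, pa)$identical)
})

test_that("schemes round-trip through the PubMLST-style directory format", {
  sch <- simulateMlstScheme(nLoci = 3, nAlleles = 4, seed = 151)
  dir <- file.path(tempdir(), "scheme-test")
  writeMlstScheme(sch, dir)
  back <- readMlstScheme(dir)
  expect_equal(back$loci, sch$loci)
  for (l in sch$loci)
    expect_equal(back$alleles[[l]], sch$alleles[[l]])
  expect_equal(back$profiles$ST, sch$profiles$ST)
})
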