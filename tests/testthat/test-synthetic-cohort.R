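test_that("evolveGenomeSet honours rates, truth table and determinism", {
  anc <- genomeSpec("anc", 100000)
  # zero-rate child is byte-identical to the parent
  res0 <- evolveGenomeSet(anc, list(genomeSpec("c0", 100000,
                                               divergence = 0)), seed = 3)
  expect_identical(res0$genomes[["c0"]], res0$genomes[["anc"]])
  expect_equal(res0$divergence["anc", "c0"], 0)

  # realized mismatch fraction is binomial around the stated rate
  res <- evolveGenomeSet(anc, list(genomeSpec("c1", 100000,
                                              divergence = 0.05)),
                         seed = 11)
  obs <- 1 - hammingIdentity(res$genomes[["anc"]], res$genomes[["c1"]])
  sdev <- sqrt(0.05 * 0.95 / 100000)
  expect_lt(abs(obs - 0.05), 3 * sdev)

  # same seed -> byte-identical genomes
  res2 <- evolveGenomeSet(anc, list(genomeSpec("c1", 100000,
                                               divergence = 0.05)),
                          seed = 11)
  expect_identical(res$genomes, res2$genomes)

  # truth table by path addition along a chain
  chain <- evolveGenomeSet(
    genomeSpec("r", 10000),
    list(genomeSpec("a", 10000, divergence = 0.05),
         genomeSpec("b", 10000, divergence = 0.03, parent = "a")),
    seed = 5)
  expect_equal(chain$divergence["r", "b"], 0.08)
  expect_equal(chain$divergence["a", "b"], 0.03)
  expect_equal(chain$divergence["r", "a"], 0.05)

  # out-of-range divergence is a parameter error
  expect_error(genomeSpec("x", 10000, divergence = 0.6), "divergence")
})

test_that("fragmentToContigs partitions the genome with seeded coverage", {
  g <- randomGenome(20000, 0.5, seed = 7)

  # single contig at cv = 0 is the whole genome at exactly the mean depth
  one <- fragmentToContigs(g, 1, coverageMean = 25, coverageCv = 0,
                           seed = 1)
  expect_identical(unname(contigSeqs(one)), g)
  expect_equal(unname(contigCoverage(one)), 25)

  cs <- fragmentToContigs(g, 8, coverageMean = 30, coverageCv = 0.2,
                          minLen = 1000, sourceId = "g1", seed = 2)
  expect_equal(sum(contigLengths(cs)), nchar(g))
  expect_identical(paste(contigSeqs(cs), collapse = ""), g)
  expect_true(all(contigLengths(cs) >= 1000))
  expect_true(all(contigSource(cs) == "g1"))

  # per-contig GC equals the per-base counting oracle
  for (s in contigSeqs(cs)[1:3]) {
    v <- strsplit(s, "")[[1]]
    expect_equal(gcContent(s), sum(v %in% c("G", "C")) / length(v))
  }

  # determinism and infeasibility
  cs2 <- fragmentToContigs(g, 8, 30, 0.2, 1000, "g1", seed = 2)
  expect_identical(contigSeqs(cs), contigSeqs(cs2))
  expect_identical(contigCoverage(cs), contigCoverage(cs2))
  expect_error(fragmentToContigs(g, 30, 30, 0.2, 1000, seed = 1),
               "infeasible")
})

test_that("simulateCohort plants the design it reports as truth", {
  spec <- cohortSpec(6, effectMultiplier = 3, depthPerSample = 5000,
                     seed = 9)
  se <- simulateCohort(spec)
  counts <- SummarizedExperiment::assay(se, "counts")
  cd <- SummarizedExperiment::colData(se)

  # multinomial conservation: every column sums to the sampling depth
  expect_true(all(colSums(counts) == 5000))
  # 6 patients x 2 sites x 2 sides
  expect_equal(ncol(counts), 24)
  # per patient and site: exactly one diseased and one unaffected side
  for (p in unique(cd$patient)) for (s in unique(cd$site)) {
    sub <- cd[cd$patient == p & cd$site == s, ]
    expect_setequal(sub$disease_state, c("diseased", "unaffected"))
  }
  # truth metadata records the planted multiplier per diseased sample
  truth <- S4Vectors::metadata(se)$truth
  expect_equal(truth$effectTaxon, "Staphylococcus")
  expect_true(all(truth$diseasedMultiplier[
    cd$sample_id[cd$disease_state == "diseased"]] == 3))
  expect_true(all(truth$diseasedMultiplier[
    cd$sample_id[cd$disease_state == "unaffected"]] == 1))
})

test_that("subject individuality makes intra-patient profiles closer than
           inter-patient ones", {
  closer <- vapply(1:10, function(s) {
    se <- simulateCohort(cohortSpec(8, effectMultiplier = 1,
                                    subjectSd = 1.2, sampleSd = 0.3,
                                    depthPerSample = 10000, seed = s))
    b <- intraInterBeta(se)
    mean(b$intra) < mean(b$inter)
  }, TRUE)
  expect_true(all(closer))
})

test_that("simulateMlstReads matches its stated error and depth", {
  sch <- simulateMlstScheme(seed = 21)
  true <- vapply(sch$loci, function(l) sch$alleles[[l]][["1"]], "")

  # error-free reads are exact substrings of their allele
  r0 <- simulateMlstReads(true, readLen = 100, coverage = 10,
                          errorRate = 0, seed = 1)
  for (i in seq_len(nrow(r0$reads)))
    expect_true(grepl(r0$reads$seq[i], true[[r0$reads$locus[i]]],
                      fixed = TRUE))

  # realized error fraction within 3 binomial s.d. of the rate
  r1 <- simulateMlstReads(true, readLen = 100, coverage = 20,
                          errorRate = 0.01, seed = 2)
  trueInts <- lapply(true, utf8ToInt)
  pick <- seq(1, nrow(r1$reads), by = 7)  # systematic read subsample
  nerr <- 0; nb <- 0
  for (i in pick) {
    rv <- utf8ToInt(r1$reads$seq[i])
    tv <- trueInts[[r1$reads$locus[i]]]
    L <- length(rv)
    # best placement = offset with fewest mismatches (reads have no indels)
    mism <- vapply(0:(length(tv) - L), function(off)
      sum(tv[(off + 1):(off + L)] != rv), 0L)
    nerr <- nerr + min(mism)
    nb <- nb + L
  }
  rate <- nerr / nb
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / nb))

  # per-locus mean depth within 20% of the target
  for (loc in names(true)) {
    sel <- r1$reads$locus == loc
    depth <- sum(nchar(r1$reads$seq[sel])) / nchar(true[[loc]])
    expect_lt(abs(depth - 20) / 20, 0.2)
  }

  # determinism
  r2 <- simulateMlstReads(true, readLen = 100, coverage = 20,
                          errorRate = 0.01, seed = 2)
  expect_identical(r1$reads, r2$reads)
})
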