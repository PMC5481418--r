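test_that("ortholog search matches planted presence and applies strict
           filters", {
  presence <- matrix(TRUE, 5, 4,
                     dimnames = list(paste0("gene", 1:5),
                                     paste0("G", 1:4)))
  presence["gene2", "G3"] <- FALSE
  presence["gene5", c("G1", "G4")] <- FALSE
  pg <- mkPangenome(presence, seed = 3)
  tab <- findOrthologs(pg$genes, pg$genomes)

  # accepted set equals the planted presence matrix exactly
  for (g in rownames(presence)) for (G in colnames(presence)) {
    found <- any(tab$hits$gene == g & tab$hits$genome == G)
    expect_equal(found, presence[g, G],
                 label = paste(g, G, "presence"))
  }
  expect_equal(unname(tab$prevalence),
               unname(rowMeans(presence)))

  # a 400 bp gene is excluded even as a perfect match (> 500 strict)
  short <- setNames(substring(pg$genes[1], 1, 400), "shortGene")
  tabS <- findOrthologs(short, pg$genomes["G1"])
  expect_equal(nrow(tabS$hits), 0L)

  # a copy diverged far beyond 30% is excluded by the identity filter
  diverged <- setNames(darkbin:::.mutateSeq(pg$genes[[1]], 0.45,
                                            seed = 7), "farGene")
  tabD <- findOrthologs(diverged, pg$genomes["G1"])
  expect_equal(nrow(tabD$hits), 0L)
})

test_that("core selection is strict at the prevalence boundary and
           monotone", {
  tab <- list(prevalence = c(gA = 0.90, gB = 1.0, gC = 0.95, gD = 0.96))
  core <- selectCore(tab)
  expect_equal(core, c("gB", "gD"))          # 0.95 exactly is excluded
  expect_error(selectCore(list(prevalence = c(g = 0.5))), "empty core")

  # monotone non-increasing in the threshold
  sizes <- vapply(c(0.5, 0.9, 0.95, 0.99),
                  function(th) length(selectCore(tab, th)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("concatenation, gap blocks and trimming behave as specified", {
  presence <- matrix(TRUE, 3, 4,
                     dimnames = list(paste0("gene", 1:3),
                                     paste0("G", 1:4)))
  presence["gene3", "G2"] <- FALSE   # near-core gene missing in one genome
  pg <- mkPangenome(presence, seed = 5)
  tab <- findOrthologs(pg$genes, pg$genomes)
  aln <- buildConcatAlignment(tab, names(pg$genes))

  rows <- alignmentRows(aln)
  expect_equal(unique(nchar(rows)), sum(nchar(pg$genes)))
  # the genome missing gene3 carries an all-gap block of that gene
  b3 <- alignmentBlocks(aln)
  g3 <- b3[b3$gene == "gene3", ]
  expect_equal(unname(substring(rows["G2"], g3$start, g3$end)),
               strrep("-", g3$end - g3$start + 1))
  expect_false(grepl("-", substring(rows["G1"], g3$start, g3$end),
                     fixed = TRUE))

  # trimming: gapless alignment unchanged; gappy columns removed
  gapless <- methods::new("ConcatAlignment",
    rows = c(a = "ACGTAC", b = "ACGTAC", c = "ACTTAC"),
    blocks = data.frame(gene = "g", start = 1L, end = 6L))
  expect_identical(alignmentRows(trimAlignment(gapless)),
                   alignmentRows(gapless))

  tenRows <- c(paste0(c(rep("A", 7), rep("-", 3)), "CG"),
               rep("ACG", 0))
  aln10 <- methods::new("ConcatAlignment",
    rows = setNames(tenRows, paste0("r", 1:10)),
    blocks = data.frame(gene = "g", start = 1L, end = 3L))
  tr <- trimAlignment(aln10, 0.2)   # column 1 has gap fraction 0.3
  expect_equal(unique(nchar(alignmentRows(tr))), 2L)
  allGap <- methods::new("ConcatAlignment",
    rows = c(a = "A-G", b = "C-G", c = "T-G"),
    blocks = data.frame(gene = "g", start = 1L, end = 3L))
  expect_equal(unique(nchar(alignmentRows(trimAlignment(allGap)))), 2L)
  expect_error(trimAlignment(methods::new("ConcatAlignment",
    rows = c(a = "--", b = "--", c = "--", d = "--", e = "--"),
    blocks = data.frame(gene = "g", start = 1L, end = 2L))),
    "every column")
})

test_that("concatenated divergence matches the planted truth table", {
  gs <- evolveGenomeSet(
    genomeSpec("anc", 30000),
    list(genomeSpec("x", 30000, divergence = 0.03),
         genomeSpec("y", 30000, divergence = 0.06)),
    seed = 17)
  starts <- seq(1, by = 1200, length.out = 20)
  genes <- setNames(substring(gs$genomes[["anc"]], starts, starts + 999),
                    sprintf("g%02d", 1:20))
  tab <- findOrthologs(genes, gs$genomes[c("x", "y")])
  aln <- buildConcatAlignment(tab, selectCore(tab))
  D <- alignmentDistances(aln, model = "p")
  # expected mismatch fraction between x and y ~ 0.03 + 0.06
  expect_lt(abs(D["x", "y"] - 0.09), 0.012)
})

test_that("neighbor joining solves the 3-taxon system and recovers
           quartets", {
  D <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  el <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                      tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(el["a"]), (0.2 + 0.3 - 0.4) / 2)
  expect_equal(unname(el["b"]), (0.2 + 0.4 - 0.3) / 2)
  expect_equal(unname(el["c"]), (0.3 + 0.4 - 0.2) / 2)

  # additive 4-taxon distances: NJ picks the quartet satisfying the
  # four-point condition, here ((a,b),(c,d))
  lab <- c("a", "b", "c", "d")
  D4 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  # tree: a,b joined by internal edge 0.1 to c,d; tips 0.05 each
  dist4 <- function(i, j) 0.05 * 2 + 0.1 * (xor(i <= 2, j <= 2))
  for (i in 1:4) for (j in 1:4) if (i != j) D4[i, j] <- dist4(i, j)
  tr4 <- njTree(D4)
  expect_equal(rfDistance(tr4, "((a,b),(c,d));"), 0L)
  expect_equal(rfDistance(tr4, "((a,c),(b,d));"), 2L)
})

test_that("Robinson-Foulds distance matches bipartition enumeration", {
  expect_equal(rfDistance("((a,b),(c,d));", "((a,b),(c,d));"), 0L)
  # the two other resolved 4-taxon topologies differ by 2
  expect_equal(rfDistance("((a,b),(c,d));", "((a,d),(b,c));"), 2L)
  # star vs fully resolved 5-taxon tree: the resolved tree's 2 internal
  # edges
  expect_equal(rfDistance("(a,b,c,d,e);", "((a,b),(c,d),e);"), 2L)
  expect_error(rfDistance("((a,b),(c,d));", "((a,b),(c,e));"),
               "leaf sets")
})

test_that("planted topologies are recovered from concatenated cores", {
  for (s in 1:2) {
    gs <- evolveGenomeSet(
      genomeSpec("root", 32000),
      list(genomeSpec("n1", 32000, divergence = 0.03),
           genomeSpec("n2", 32000, divergence = 0.03),
           genomeSpec("t1", 32000, divergence = 0.02, parent = "n1"),
           genomeSpec("t2", 32000, divergence = 0.03, parent = "n1"),
           genomeSpec("n3", 32000, divergence = 0.03, parent = "n2"),
           genomeSpec("t3", 32000, divergence = 0.02, parent = "n3"),
           genomeSpec("t4", 32000, divergence = 0.03, parent = "n3"),
           genomeSpec("t5", 32000, divergence = 0.04, parent = "n2"),
           genomeSpec("t6", 32000, divergence = 0.05)),
      seed = 500 + s)
    leaves <- c("t1", "t2", "t3", "t4", "t5", "t6")
    starts <- seq(1, by = 1250, length.out = 24)
    genes <- setNames(substring(gs$genomes[["root"]], starts,
                                starts + 999), sprintf("g%02d", 1:24))
    tab <- findOrthologs(genes, gs$genomes[leaves])
    aln <- buildConcatAlignment(tab, selectCore(tab))
    tr <- njTree(aln)
    planted <- ape::keep.tip(plantedTree(gs$edges), leaves)
    expect_equal(rfDistance(tr, planted), 0L)
    # leaf set equals alignment row set; Newick round-trips losslessly
    expect_setequal(tr$tip.label, names(alignmentRows(aln)))
    rt <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(rfDistance(tr, rt), 0L)
  }
})
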