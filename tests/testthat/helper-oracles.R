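# Independent oracles used across the suite. These deliberately use naive
# per-base loops or closed forms, never the package's own fast paths.

# per-base boolean-array breadth + length-weighted identity
breadthOracle <- function(contigLength, hits) {
  covered <- logical(contigLength)
  wsum <- 0
  lsum <- 0
  if (!is.null(hits) && nrow(hits)) for (i in seq_len(nrow(hits))) {
    if (hits$alignedLength[i] > 0)
      covered[(hits$queryStart[i] + 1L):hits$queryEnd[i]] <- TRUE
    wsum <- wsum + hits$alignedLength[i] * hits$identity[i]
    lsum <- lsum + hits$alignedLength[i]
  }
  c(breadth = mean(covered),
    identity = if (lsum > 0) wsum / lsum else 0)
}

# Hamming identity between two equal-length sequences
hammingIdentity <- function(a, b) {
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# deterministic sequence with an exact GC fraction (gc * len integral)
makeSeqGC <- function(len, gc, seed = 1L) {
  ngc <- round(len * gc)
  base <- c(rep(c("G", "C"), length.out = ngc),
            rep(c("A", "T"), length.out = len - ngc))
  set.seed(seed)
  paste(sample(base), collapse = "")
}

# expected richness of a hypergeometric subsample at depth d
expectedRarefiedRichness <- function(counts, d) {
  N <- sum(counts)
  sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
}

# Welch t computed from the textbook formula
welchOracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

# brute-force strain-identity rule: at most one differing locus, none by
# more than one SNP
strainRuleOracle <- function(snps) {
  differing <- snps > 0
  sum(differing) <= 1 && all(snps[differing] <= 1)
}

# a tiny pangenome: genomes are concatenations of selected genes with
# random spacers, so the accepted ortholog set is enumerable by hand
mkPangenome <- function(presence, geneLen = 600, seed = 1) {
  genes <- setNames(vapply(seq_len(nrow(presence)), function(i)
    randomGenome(geneLen, 0.5, seed = seed * 100 + i), ""),
    rownames(presence))
  genomes <- vapply(seq_len(ncol(presence)), function(j) {
    present <- rownames(presence)[presence[, j]]
    spacers <- vapply(seq_len(length(present) + 1), function(s)
      randomGenome(1000, 0.5, seed = seed * 1000 + j * 50 + s), "")
    paste(c(rbind(spacers[seq_along(present)], genes[present]),
            spacers[length(present) + 1]), collapse = "")
  }, "")
  names(genomes) <- colnames(presence)
  list(genes = genes, genomes = genomes)
}

bundledConfig <- function() {
  validateConfig(system.file("extdata", "pipeline-config.json",
                             package = "darkbin"))
}

# plant substitutions at given positions of a sequence
mutateAt <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  v[pos] <- rot[v[pos]]
  paste(v, collapse = "")
}
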