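# Core-genome concatenated alignment across genomes/bins and a
# neighbor-joining placement tree. Ortholog search uses the native
# ungapped aligner with the strict length/identity/prevalence filters;
# substitution-only inputs make per-gene "alignment" a coordinate fill-in.

#' ConcatAlignment: concatenated core-gene alignment
#'
#' Equal-length aligned rows (one per genome, `-` = gap) with recorded
#' per-gene block boundaries.
#'
#' @slot rows named character vector of equal-length aligned sequences.
#' @slot blocks data.frame `gene`, `start`, `end` (1-based column ranges).
#' @export
setClass("ConcatAlignment",
  representation(rows = "character", blocks = "data.frame"))

setValidity("ConcatAlignment", function(object) {
  if (length(unique(nchar(object@rows))) > 1L)
    return("all rows must have equal length")
  TRUE
})

setMethod("show", "ConcatAlignment", function(object) {
  cat(sprintf("ConcatAlignment: %d genomes x %d columns (%d gene blocks)\n",
              length(object@rows),
              if (length(object@rows)) nchar(object@rows[[1L]]) else 0L,
              nrow(object@blocks)))
})

#' Rows of a ConcatAlignment
#' @param x a [ConcatAlignment-class].
#' @return Named character vector of aligned rows.
#' @export
alignmentRows <- function(x) x@rows

#' Gene block boundaries of a ConcatAlignment
#' @param x a [ConcatAlignment-class].
#' @return data.frame `gene`, `start`, `end`.
#' @export
alignmentBlocks <- function(x) x@blocks

#' Find orthologs of a reference gene set across genomes
#'
#' Aligns every reference gene to every genome with the native aligner and
#' keeps, per (gene, genome), the best-scoring hit that is strictly longer
#' than `minLen` and has identity strictly above `minIdentity` — the
#' plausible-ortholog filter. Multi-copy hits are resolved by best score.
#'
#' @param referenceGenes named character vector of gene sequences.
#' @param genomes named character vector of genome (or bin) sequences.
#' @param minLen minimum accepted hit length, exclusive (default 500).
#' @param minIdentity minimum accepted identity, exclusive (default 0.70).
#' @param k aligner seed length (default 11; orthologs may be diverged).
#' @param xDrop aligner X-drop (default 30).
#' @return An ortholog table: list with `genes` (the input), `genomes`
#'   (ids), `hits` (data.frame `gene`, `genome`, `identity`, `length`,
#'   `gene_start`, `gene_end` (0-based half-open on the gene), `seq` — the
#'   genome's sequence over the hit), and `prevalence` (named fraction of
#'   genomes with an accepted hit, per gene).
#' @export
findOrthologs <- function(referenceGenes, genomes, minLen = 500L,
                          minIdentity = 0.70, k = 11L, xDrop = 30L) {
  stopifnot(length(referenceGenes) > 0L, !is.null(names(referenceGenes)),
            !is.null(names(genomes)))
  rows <- list()
  for (g in names(genomes)) {
    idx <- .subjectIndex(genomes[[g]], k)
    for (gene in names(referenceGenes)) {
      h <- seedExtendAlign(referenceGenes[[gene]], "", k = k,
                           minIdentity = 0, minLen = 1L, xDrop = xDrop,
                           queryId = gene, subjectId = g, index = idx)
      if (!nrow(h)) next
      h <- h[h$alignedLength > minLen & h$identity > minIdentity, ,
             drop = FALSE]
      if (!nrow(h)) next
      best <- which.max(h$alignedLength * h$identity)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, genome = g, identity = h$identity[best],
        length = h$alignedLength[best],
        gene_start = h$queryStart[best], gene_end = h$queryEnd[best],
        seq = substring(genomes[[g]], h$subjectStart[best] + 1L,
                        h$subjectEnd[best]),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), genome = character(),
               identity = numeric(), length = integer(),
               gene_start = integer(), gene_end = integer(),
               seq = character(), stringsAsFactors = FALSE)
  prev <- vapply(names(referenceGenes), function(gene)
    length(unique(hits$genome[hits$gene == gene])) / length(genomes), 0)
  list(genes = referenceGenes, genomes = names(genomes), hits = hits,
       prevalence = prev)
}

#' Select the core genes of an ortholog table
#'
#' Genes with an accepted ortholog in strictly more than `minPrevalence`
#' of the genomes, in the stable order of the reference gene set.
#'
#' @param table ortholog table from [findOrthologs()].
#' @param minPrevalence prevalence threshold, exclusive (default 0.95).
#' @return Character vector of core gene ids.
#' @export
selectCore <- function(table, minPrevalence = 0.95) {
  core <- names(table$prevalence)[table$prevalence > minPrevalence]
  if (!length(core))
    stop("empty core: no gene exceeds prevalence ", minPrevalence,
         "; a tree cannot be built")
  core
}

#' Build the concatenated core-gene alignment
#'
#' For each core gene, a block of columns equal to the gene's length; each
#' genome's accepted hit sequence is placed at its gene coordinates
#' (substitution-only hits are already column-aligned to the gene) and the
#' rest of the block is gap-filled. A genome lacking a hit for a core gene
#' receives an all-gap block. Blocks are concatenated in stable gene order.
#'
#' @param table ortholog table from [findOrthologs()].
#' @param coreGenes gene ids from [selectCore()].
#' @return A [ConcatAlignment-class].
#' @export
buildConcatAlignment <- function(table, coreGenes) {
  stopifnot(length(coreGenes) > 0L)
  genomes <- table$genomes
  pieces <- matrix("", nrow = length(genomes), ncol = length(coreGenes),
                   dimnames = list(genomes, coreGenes))
  blocks <- data.frame(gene = coreGenes, start = NA_integer_,
                       end = NA_integer_, stringsAsFactors = FALSE)
  pos <- 0L
  for (j in seq_along(coreGenes)) {
    gene <- coreGenes[j]
    w <- nchar(table$genes[[gene]])
    gap <- strrep("-", w)
    for (g in genomes) {
      i <- which(table$hits$gene == gene & table$hits$genome == g)
      if (!length(i)) {
        pieces[g, j] <- gap
      } else {
        h <- table$hits[i[1L], ]
        block <- gap
        substr(block, h$gene_start + 1L, h$gene_end) <- h$seq
        pieces[g, j] <- block
      }
    }
    blocks$start[j] <- pos + 1L
    blocks$end[j] <- pos + w
    pos <- pos + w
  }
  rows <- apply(pieces, 1L, paste, collapse = "")
  new("ConcatAlignment", rows = rows, blocks = blocks)
}

#' Trim gappy columns from a concatenated alignment
#'
#' Removes every column whose gap fraction strictly exceeds
#' `maxGapFraction` and updates the gene block boundaries (a fixed-cutoff
#' stand-in for automatic gap trimming).
#'
#' @param aln a [ConcatAlignment-class].
#' @param maxGapFraction maximum tolerated gap fraction per column
#'   (default 0.2).
#' @return A trimmed [ConcatAlignment-class].
#' @export
trimAlignment <- function(aln, maxGapFraction = 0.2) {
  m <- .alnMatrix(aln)
  gapFrac <- colMeans(m == "-")
  keep <- gapFrac <= maxGapFraction
  if (!any(keep)) stop("trimming removed every column; empty alignment")
  blocks <- aln@blocks
  keptBefore <- cumsum(keep)
  newBlocks <- lapply(seq_len(nrow(blocks)), function(j) {
    idx <- blocks$start[j]:blocks$end[j]
    nk <- sum(keep[idx])
    if (nk == 0L) return(NULL)
    start <- if (blocks$start[j] > 1L) keptBefore[blocks$start[j] - 1L] + 1L
             else 1L
    data.frame(gene = blocks$gene[j], start = start,
               end = start + nk - 1L, stringsAsFactors = FALSE)
  })
  rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(rows) <- names(aln@rows)
  new("ConcatAlignment", rows = rows,
      blocks = do.call(rbind, newBlocks[!vapply(newBlocks, is.null,
                                                TRUE)]))
}

.alnMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@rows, "", fixed = TRUE))
  rownames(m) <- names(aln@rows)
  m
}

#' Pairwise distances from a concatenated alignment
#'
#' p-distance or Jukes-Cantor distance with pairwise deletion of gap
#' sites.
#'
#' @param aln a [ConcatAlignment-class].
#' @param model `"JC"` (default) or `"p"`.
#' @return A symmetric distance matrix.
#' @export
alignmentDistances <- function(aln, model = c("JC", "p")) {
  model <- match.arg(model)
  m <- .alnMatrix(aln)
  n <- nrow(m)
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop("no shared ungapped sites between '", ids[i],
                       "' and '", ids[j], "'")
    p <- mean(m[i, ok] != m[j, ok])
    d <- if (model == "p") p else {
      if (p >= 0.75)
        stop("Jukes-Cantor distance undefined for pair '", ids[i],
             "', '", ids[j], "' (mismatch fraction ", round(p, 3), ")")
      -0.75 * log(1 - 4 * p / 3)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a concatenated alignment
#'
#' Distances via [alignmentDistances()] (pairwise deletion), tree via
#' neighbor joining; negative branch lengths are clamped to zero. The
#' result is deterministic under a fixed row order.
#'
#' @param aln a [ConcatAlignment-class], or a distance matrix.
#' @param model distance model passed to [alignmentDistances()].
#' @return An `ape` `phylo` object (unrooted).
#' @export
njTree <- function(aln, model = c("JC", "p")) {
  D <- if (is(aln, "ConcatAlignment"))
    alignmentDistances(aln, model) else as.matrix(aln)
  stopifnot(nrow(D) >= 3L)
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions. Accepts `phylo`
#' objects or Newick strings; the two trees must share a leaf set.
#'
#' @param treeA,treeB `phylo` objects or Newick strings.
#' @return Non-negative integer count.
#' @export
rfDistance <- function(treeA, treeB) {
  as_tree <- function(x) if (is.character(x)) ape::read.tree(text = x)
                         else x
  a <- as_tree(treeA)
  b <- as_tree(treeB)
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets")
  as.integer(phangorn::RF.dist(a, b, check.labels = TRUE))
}
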