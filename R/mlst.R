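# Metagenomic MLST: read placement by exact k-mer anchoring against the
# scheme's catalogued alleles, per-locus pileups, majority-rule consensus
# with the closest catalogued allele as template, ST assignment, and the
# strain-identity rule for comparing paired samples.

#' Build per-locus pileups from reads by exact k-mer anchoring
#'
#' Each read is placed by scanning its k-mers in order and taking the
#' first exact match against any catalogued allele of the scheme (alleles
#' of one locus share coordinates in this substitution-only setting); the
#' matching k-mer fixes the locus and the read's offset. Unplaceable reads
#' are dropped. Base counts are accumulated per locus position.
#'
#' @param reads data.frame with a `seq` column (a `locus` column, if
#'   present, is ignored — placement is by anchoring only).
#' @param scheme scheme list as from [simulateMlstScheme()] or
#'   [readMlstScheme()].
#' @param k anchor k-mer length (default 21).
#' @return Named list (one per locus) of pileups: list with `locus`,
#'   `counts` (4 x length matrix, rows A/C/G/T), `nReads`.
#' @export
buildPileups <- function(reads, scheme, k = 21L) {
  # combined anchor index over all catalogued alleles
  anchorCodes <- list()
  anchorLocus <- list()
  anchorPos <- list()
  for (loc in scheme$loci) {
    for (a in scheme$alleles[[loc]]) {
      codes <- .kmerCodes(.seqToInt(a), k)
      anchorCodes[[length(anchorCodes) + 1L]] <- codes
      anchorLocus[[length(anchorLocus) + 1L]] <-
        rep(loc, length(codes))
      anchorPos[[length(anchorPos) + 1L]] <- seq_along(codes)
    }
  }
  codes <- unlist(anchorCodes)
  locus <- unlist(anchorLocus)
  pos <- unlist(anchorPos)
  ok <- !is.na(codes)
  dup <- duplicated(codes[ok])
  codes <- codes[ok][!dup]
  locus <- locus[ok][!dup]
  pos <- pos[ok][!dup]
  ord <- order(codes)
  codes <- codes[ord]; locus <- locus[ord]; pos <- pos[ord]

  lociLen <- vapply(scheme$loci, function(l)
    nchar(scheme$alleles[[l]][[1L]]), 0L)
  piles <- lapply(scheme$loci, function(l)
    list(locus = l,
         counts = matrix(0L, 4L, lociLen[[l]],
                         dimnames = list(c("A", "C", "G", "T"), NULL)),
         nReads = 0L))
  names(piles) <- scheme$loci

  for (s in reads$seq) {
    v <- .seqToInt(s)
    rc <- .kmerCodes(v, k)
    hit <- findInterval(rc, codes)
    m <- which(hit > 0L & !is.na(rc))
    m <- m[codes[hit[m]] == rc[m]]
    if (!length(m)) next
    i <- m[1L]                      # first anchoring k-mer in the read
    loc <- locus[hit[i]]
    offset <- pos[hit[i]] - i       # 0-based shift read -> locus
    rp <- seq_along(v) + offset     # locus positions (1-based)
    keep <- rp >= 1L & rp <= lociLen[[loc]] & !is.na(v)
    idx <- cbind(v[keep] + 1L, rp[keep])
    piles[[loc]]$counts[idx] <- piles[[loc]]$counts[idx] + 1L
    piles[[loc]]$nReads <- piles[[loc]]$nReads + 1L
  }
  piles
}

#' Majority-rule consensus of a locus pileup
#'
#' Positions covered by more than one read take the majority base (a tie
#' takes the template base); positions covered by exactly one read take
#' the observed base; uncovered positions take the template base.
#'
#' @param pileup pileup list (`counts` 4 x L matrix, rows A/C/G/T).
#' @param template template sequence of length L (the closest catalogued
#'   allele).
#' @return Consensus sequence (character scalar).
#' @export
consensusAllele <- function(pileup, template) {
  counts <- pileup$counts
  L <- ncol(counts)
  stopifnot(nchar(template) == L)
  tmplInt <- .seqToInt(template)
  cov <- colSums(counts)
  best <- max.col(t(counts), ties.method = "first")
  topCount <- counts[cbind(best, seq_len(L))]
  nTop <- colSums(counts == matrix(topCount, 4L, L, byrow = TRUE) &
                    counts > 0L)
  out <- tmplInt                         # coverage 0 -> template
  one <- cov == 1L
  out[one] <- best[one] - 1L             # single read -> observed base
  multi <- cov >= 2L
  tie <- multi & nTop > 1L
  out[multi & !tie] <- best[multi & !tie] - 1L
  # tie at >=2 coverage -> template base (already in out)
  .intToSeq(out)
}

# closest catalogued allele to a preliminary majority sequence
# (min Hamming, ties to the lowest allele id)
.closestAllele <- function(prelim, alleles) {
  pv <- .seqToInt(prelim)
  dists <- vapply(alleles, function(a) sum(pv != .seqToInt(a)), 0L)
  ids <- names(alleles)[order(dists, as.integer(names(alleles)))]
  ids[1L]
}

#' Call the MLST profile and sequence type of one sample
#'
#' For each locus, a preliminary majority sequence (template = allele 1)
#' selects the closest catalogued allele as template; the final consensus
#' is rebuilt against that template with [consensusAllele()] and matched
#' to the catalogued alleles by exact sequence equality (no match ->
#' allele `"new"`). The ST is the catalogued profile row matching all
#' allele ids; `"novel"` when all loci are present but no row matches
#' (>= 1 new allele or an uncatalogued combination); `"incomplete"` when
#' a locus received no reads.
#'
#' @param pileups result of [buildPileups()].
#' @param scheme the scheme.
#' @param sampleId id recorded on the profile.
#' @return An [MLSTProfile-class].
#' @export
assignST <- function(pileups, scheme, sampleId = "sample") {
  if (!setequal(names(pileups), scheme$loci))
    stop("pileup loci do not match the scheme")
  loci <- scheme$loci
  ids <- setNames(rep(NA_character_, length(loci)), loci)
  seqs <- setNames(rep(NA_character_, length(loci)), loci)
  for (loc in loci) {
    p <- pileups[[loc]]
    if (p$nReads == 0L || all(colSums(p$counts) == 0L)) next
    prelim <- consensusAllele(p, scheme$alleles[[loc]][[1L]])
    tmplId <- .closestAllele(prelim, scheme$alleles[[loc]])
    cons <- consensusAllele(p, scheme$alleles[[loc]][[tmplId]])
    seqs[loc] <- cons
    hit <- which(scheme$alleles[[loc]] == cons)
    ids[loc] <- if (length(hit)) names(scheme$alleles[[loc]])[hit[1L]]
                else "new"
  }
  st <- if (anyNA(ids)) {
    "incomplete"
  } else if (any(ids == "new")) {
    "novel"
  } else {
    prof <- scheme$profiles
    row <- which(apply(prof[loci], 1L, function(r)
      all(as.character(r) == ids)))
    if (length(row)) as.character(prof$ST[row[1L]]) else "novel"
  }
  new("MLSTProfile", sampleId = sampleId, loci = loci,
      alleleIds = unname(ids), alleleSeqs = unname(seqs), st = st)
}

#' Strain-identity rule for two MLST profiles
#'
#' Two samples carry the same strain iff at most one locus differs between
#' their consensus sequences and no differing locus differs by more than
#' one SNP — the "more than six of eight loci identical, no locus differing
#' by more than one SNP" rule, generalised to schemes of any size as: at
#' most one differing locus, each by at most one SNP. A locus missing in
#' either profile is treated as differing by more than one SNP.
#'
#' @param profileA,profileB [MLSTProfile-class] objects on the same scheme.
#' @return list: `identical` (logical) and `snps` (named per-locus SNP
#'   counts; `NA` when a locus is missing).
#' @export
strainsIdentical <- function(profileA, profileB) {
  if (!identical(profileA@loci, profileB@loci))
    stop("profiles come from different schemes")
  snps <- setNames(rep(NA_integer_, length(profileA@loci)),
                   profileA@loci)
  for (i in seq_along(profileA@loci)) {
    a <- profileA@alleleSeqs[i]
    b <- profileB@alleleSeqs[i]
    if (is.na(a) || is.na(b)) next
    if (nchar(a) != nchar(b))
      stop("allele length mismatch at locus ", profileA@loci[i])
    snps[i] <- sum(.seqToInt(a) != .seqToInt(b))
  }
  differing <- is.na(snps) | snps > 0L
  ok <- sum(differing) <= 1L &&
    all(snps[differing] <= 1L, na.rm = TRUE) &&
    !anyNA(snps[differing])
  list(identical = ok, snps = snps)
}

#' Read a PubMLST-style scheme directory
#'
#' Expects one FASTA per locus (`<locus>.fas`, headers `<locus>_<id>`)
#' plus `profiles.tsv` with a column `ST` and one column per locus.
#'
#' @param dir scheme directory.
#' @return Scheme list (`loci`, `alleles`, `profiles`).
#' @export
readMlstScheme <- function(dir) {
  prof <- read.table(file.path(dir, "profiles.tsv"), header = TRUE,
                     sep = "\t", check.names = FALSE)
  loci <- setdiff(names(prof), "ST")
  alleles <- lapply(loci, function(loc) {
    s <- readFasta(file.path(dir, paste0(loc, ".fas")))
    names(s) <- sub(paste0("^", loc, "_"), "", vapply(
      strsplit(names(s), "[ \t]"), `[`, "", 1L))
    s
  })
  names(alleles) <- loci
  list(loci = loci, alleles = alleles, profiles = prof)
}

#' Write a scheme to a PubMLST-style directory
#'
#' @param scheme scheme list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMlstScheme <- function(scheme, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in scheme$loci) {
    s <- scheme$alleles[[loc]]
    writeFasta(setNames(unname(s), paste0(loc, "_", names(s))),
               file.path(dir, paste0(loc, ".fas")))
  }
  write.table(scheme$profiles, file.path(dir, "profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
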