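# Synthetic-cohort generators. Everything here is a pure function of its
# seed and emits machine-readable ground truth consumed by downstream
# validation: true pairwise divergences, true contig sources, planted
# abundance multipliers, true MLST alleles.

#' Evolve a set of genomes by substitution-only divergence
#'
#' Generates the ancestor genome de novo, then each child genome as its
#' parent's sequence with i.i.d. substitutions at the child's stated
#' per-site rate (no indels). Child specs may name any previously defined
#' genome as `parent`, so arbitrary planted clade structures can be
#' expressed as chained specs; a child with `parent = NA` descends from the
#' ancestor.
#'
#' @param ancestor a [GenomeSpec-class] for the root genome (its
#'   `divergence` is ignored).
#' @param children list of [GenomeSpec-class] child specs, in an order in
#'   which every parent precedes its children.
#' @param seed integer seed.
#' @return A list with components:
#'   \describe{
#'     \item{genomes}{named character vector of sequences (ancestor first).}
#'     \item{divergence}{matrix of expected pairwise divergences computed
#'       by summing per-branch rates along the connecting path.}
#'     \item{edges}{data.frame `(parent, child, rate)` — the planted tree.}
#'   }
#' @export
evolveGenomeSet <- function(ancestor, children = list(), seed = 1L) {
  stopifnot(is(ancestor, "GenomeSpec"))
  for (ch in children) {
    stopifnot(is(ch, "GenomeSpec"))
    validObject(ch)
  }
  validObject(ancestor)
  ids <- c(ancestor@id, vapply(children, slot, "", "id"))
  if (anyDuplicated(ids)) stop("duplicate genome ids")

  genomes <- character(0)
  genomes[ancestor@id] <- randomGenome(ancestor@length, ancestor@gcTarget,
                                       seed = seed)
  parent <- setNames(rep(NA_character_, length(ids)), ids)
  rate <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(children)) {
    ch <- children[[i]]
    p <- if (is.na(ch@parent)) ancestor@id else ch@parent
    if (!p %in% names(genomes))
      stop("parent '", p, "' of '", ch@id, "' not yet defined")
    genomes[ch@id] <- .mutateSeq(genomes[[p]], ch@divergence,
                                 seed = seed + i)
    parent[ch@id] <- p
    rate[ch@id] <- ch@divergence
  }

  # expected divergence for every pair by path addition on the tree
  depth <- setNames(numeric(length(ids)), ids)  # distance to root
  anc <- lapply(ids, function(id) {
    path <- id
    while (!is.na(parent[path[length(path)]]))
      path <- c(path, parent[path[length(path)]])
    path
  })
  names(anc) <- ids
  for (id in ids) depth[id] <- sum(rate[anc[[id]]])
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in ids) for (b in ids) {
    if (a == b) next
    common <- intersect(anc[[a]], anc[[b]])
    mrcaDepth <- max(depth[common])
    D[a, b] <- depth[a] + depth[b] - 2 * mrcaDepth
  }
  edges <- data.frame(parent = unname(parent[-1L]), child = ids[-1L],
                      rate = unname(rate[-1L]), stringsAsFactors = FALSE)
  list(genomes = genomes, divergence = D, edges = edges)
}

#' Planted tree topology from an evolveGenomeSet edge list
#'
#' Converts the `edges` data.frame returned by [evolveGenomeSet()] into an
#' `ape` phylo object whose leaves are the genomes that are not parents of
#' any other genome, with branch lengths equal to the per-branch
#' substitution rates. Used as the truth topology in tree-recovery checks.
#'
#' @param edges data.frame `(parent, child, rate)`.
#' @return An object of class `phylo`.
#' @export
plantedTree <- function(edges) {
  kids <- split(seq_len(nrow(edges)), edges$parent)
  root <- setdiff(edges$parent, edges$child)
  stopifnot(length(root) == 1L)
  rec <- function(id) {
    if (is.null(kids[[id]])) return(id)
    subs <- vapply(kids[[id]], function(i)
      sprintf("%s:%g", rec(edges$child[i]), edges$rate[i]), "")
    sprintf("(%s)", paste(subs, collapse = ","))
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

#' Fragment a genome into non-overlapping contigs with simulated coverage
#'
#' Cuts the genome into `nContigs` contiguous, non-overlapping substrings
#' that jointly cover the whole genome, each at least `minLen` bases, with
#' random breakpoints. Each contig receives a mean depth of coverage drawn
#' log-normally around `coverageMean` with coefficient of variation
#' `coverageCv` (exactly `coverageMean` when `coverageCv = 0`), and carries
#' the source genome id as truth.
#'
#' @param genome a single sequence (character scalar).
#' @param nContigs number of contigs.
#' @param coverageMean mean depth of coverage.
#' @param coverageCv coefficient of variation of coverage across contigs.
#' @param minLen minimum contig length (default 500).
#' @param sourceId source genome id recorded per contig.
#' @param seed integer seed.
#' @return A [ContigSet-class]; contig names are `<sourceId>_c<i>`.
#' @export
fragmentToContigs <- function(genome, nContigs, coverageMean,
                              coverageCv = 0.3, minLen = 500L,
                              sourceId = "g", seed = 1L) {
  n <- nchar(genome)
  nContigs <- as.integer(nContigs)
  stopifnot(nContigs >= 1L, coverageMean > 0, coverageCv >= 0)
  if (nContigs * minLen > n)
    stop("infeasible fragmentation: nContigs * minLen exceeds genome length")
  .withSeed(seed, {
    extra <- n - nContigs * minLen
    add <- if (extra > 0)
      as.vector(stats::rmultinom(1L, extra, rep(1, nContigs))) else
      rep(0L, nContigs)
    lens <- minLen + add
    ends <- cumsum(lens)
    starts <- c(1L, head(ends, -1L) + 1L)
    seqs <- substring(genome, starts, ends)
    names(seqs) <- sprintf("%s_c%d", sourceId, seq_len(nContigs))
    if (coverageCv == 0) {
      cov <- rep(coverageMean, nContigs)
    } else {
      sdlog <- sqrt(log(1 + coverageCv^2))
      meanlog <- log(coverageMean) - sdlog^2 / 2
      cov <- stats::rlnorm(nContigs, meanlog, sdlog)
    }
    contigSet(seqs, cov, sourceId)
  })
}

#' Simulate a paired-site skin cohort with a planted disease effect
#'
#' For each patient, samples are generated at every site on both the left
#' and the right side; per site, one randomly chosen side is diseased and
#' the contralateral side unaffected, so every patient retains at least one
#' unaffected site. Per-sample counts are a multinomial draw at
#' `depthPerSample` from a profile combining (i) the base profile, (ii) a
#' per-patient, per-taxon log-normal offset with s.d. `subjectSd` shared by
#' all samples of the patient (subject individuality), (iii) independent
#' per-sample log-normal noise with s.d. `sampleSd`, and (iv)
#' `effectMultiplier` applied to `effectTaxon` at diseased sites.
#'
#' @param spec a [CohortSpec-class].
#' @param baseProfile named non-negative vector summing to 1 (relative
#'   abundances of the taxa); defaults to [skinBaseProfile()].
#' @return A `SummarizedExperiment` from [abundanceTable()]; planted truth
#'   (effect taxon, per-sample multipliers, patient offsets) is stored in
#'   `S4Vectors::metadata(x)$truth`.
#' @export
simulateCohort <- function(spec, baseProfile = skinBaseProfile()) {
  validObject(spec)
  stopifnot(abs(sum(baseProfile) - 1) < 1e-8, all(baseProfile >= 0),
            !is.null(names(baseProfile)))
  if (spec@effectMultiplier > 1 &&
      !spec@effectTaxon %in% names(baseProfile))
    stop("effectTaxon '", spec@effectTaxon, "' not in base profile")
  taxa <- names(baseProfile)
  .withSeed(spec@seed, {
    rows <- list()
    counts <- list()
    offsets <- matrix(stats::rnorm(spec@nPatients * length(taxa),
                                   0, spec@subjectSd),
                      nrow = spec@nPatients,
                      dimnames = list(NULL, taxa))
    k <- 0L
    for (p in seq_len(spec@nPatients)) {
      pid <- sprintf("P%02d", p)
      for (site in spec@sites) {
        diseasedSide <- sample(c("left", "right"), 1L)
        for (side in c("left", "right")) {
          k <- k + 1L
          diseased <- side == diseasedSide
          mult <- setNames(rep(1, length(taxa)), taxa)
          if (diseased) mult[spec@effectTaxon] <- spec@effectMultiplier
          noise <- stats::rnorm(length(taxa), 0, spec@sampleSd)
          w <- baseProfile * exp(offsets[p, ] + noise) * mult
          prob <- w / sum(w)
          counts[[k]] <- as.vector(
            stats::rmultinom(1L, spec@depthPerSample, prob))
          rows[[k]] <- data.frame(
            sample_id = sprintf("%s_%s_%s", pid, site, side),
            patient = pid, site = site, side = side,
            disease_state = if (diseased) "diseased" else "unaffected",
            antibiotic_flag = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    meta <- do.call(rbind, rows)
    mat <- do.call(cbind, counts)
    rownames(mat) <- taxa
    se <- abundanceTable(mat, meta)
    S4Vectors::metadata(se)$truth <- list(
      effectTaxon = spec@effectTaxon,
      effectMultiplier = spec@effectMultiplier,
      diseasedMultiplier = setNames(
        ifelse(meta$disease_state == "diseased", spec@effectMultiplier, 1),
        meta$sample_id),
      patientOffsets = offsets, baseProfile = baseProfile)
    se
  })
}

#' Default skin-like base abundance profile
#'
#' A genus-level relative-abundance profile shaped like sebaceous/dry skin
#' communities: dominated by Cutibacterium/Propionibacterium,
#' Staphylococcus, Corynebacterium, Micrococcus and Malassezia with a tail
#' of minor genera.
#'
#' @return Named numeric vector summing to 1.
#' @export
skinBaseProfile <- function() {
  p <- c(Propionibacterium = 0.34, Staphylococcus = 0.10,
         Corynebacterium = 0.16, Micrococcus = 0.09, Malassezia = 0.09,
         Streptococcus = 0.07, Moraxella = 0.05, Paracoccus = 0.03,
         Acinetobacter = 0.03, Dermacoccus = 0.02, Kocuria = 0.01,
         Veillonella = 0.01)
  p / sum(p)
}

#' Simulate a PubMLST-style typing scheme
#'
#' Generates `nLoci` random locus reference sequences and, per locus,
#' `nAlleles` catalogued alleles: allele 1 is the base sequence, the others
#' differ from it by 1–3 substitutions. ST profile rows are built from
#' random allele combinations (ST 1 is all-1).
#'
#' @param nLoci number of loci (default 8, as in the Cutibacterium scheme).
#' @param nAlleles catalogued alleles per locus.
#' @param lociLen allele length in bases (equal within and across loci).
#' @param nSTs number of catalogued sequence types.
#' @param seed integer seed.
#' @return A scheme list: `loci` (ordered names), `alleles` (per-locus
#'   named character vector of allele sequences, names = allele ids), and
#'   `profiles` (data.frame with column `ST` plus one column per locus).
#' @export
simulateMlstScheme <- function(nLoci = 8L, nAlleles = 10L, lociLen = 450L,
                               nSTs = 12L, seed = 1L) {
  .withSeed(seed, {
    loci <- sprintf("locus%d", seq_len(nLoci))
    alleles <- lapply(seq_len(nLoci), function(i) {
      base <- randomGenome(lociLen, 0.5,
                           seed = sample.int(.Machine$integer.max, 1L))
      al <- character(nAlleles)
      al[1L] <- base
      for (j in seq_len(nAlleles - 1L) + 1L) {
        repeat {
          v <- .seqToInt(base)
          nmut <- sample(1:3, 1L)
          pos <- sample.int(lociLen, nmut)
          v[pos] <- (v[pos] + sample.int(3L, nmut, replace = TRUE)) %% 4L
          cand <- .intToSeq(v)
          if (!cand %in% al[seq_len(j - 1L)]) break
        }
        al[j] <- cand
      }
      setNames(al, as.character(seq_len(nAlleles)))
    })
    names(alleles) <- loci
    prof <- matrix(NA_integer_, nSTs, nLoci, dimnames = list(NULL, loci))
    prof[1L, ] <- 1L
    for (s in seq_len(nSTs - 1L) + 1L)
      prof[s, ] <- sample.int(nAlleles, nLoci, replace = TRUE)
    profiles <- data.frame(ST = seq_len(nSTs), prof, check.names = FALSE)
    # drop accidental duplicate profiles (keep first)
    profiles <- profiles[!duplicated(profiles[loci]), , drop = FALSE]
    list(loci = loci, alleles = alleles, profiles = profiles)
  })
}

#' Simulate shotgun reads over a set of MLST alleles
#'
#' Reads are uniformly-placed substrings of the true allele of each locus,
#' with i.i.d. substitution errors at `errorRate`. The number of reads per
#' locus is chosen so the realised mean depth is within 20% of `coverage`.
#'
#' @param alleles named character vector: the true allele sequence per
#'   locus.
#' @param readLen read length (must not exceed the shortest allele).
#' @param coverage target mean depth per locus.
#' @param errorRate per-base substitution error rate in [0, 0.1].
#' @param seed integer seed.
#' @return A list: `reads` (data.frame `read_id`, `locus`, `seq` — the
#'   locus column is synthetic truth, not used by the caller for
#'   placement), and `trueAlleles` (the input, as truth).
#' @export
simulateMlstReads <- function(alleles, readLen = 100L, coverage = 20,
                              errorRate = 0.01, seed = 1L) {
  stopifnot(errorRate >= 0, errorRate <= 0.1,
            readLen <= min(nchar(alleles)), !is.null(names(alleles)))
  .withSeed(seed, {
    out <- lapply(names(alleles), function(loc) {
      a <- alleles[[loc]]
      n <- nchar(a)
      # reads may overhang either end and are clipped to the allele, so
      # terminal positions reach the same expected depth as the interior
      nReads <- max(1L, round(coverage * (n + readLen - 1L) / readLen))
      starts0 <- sample.int(n + readLen - 1L, nReads, replace = TRUE) -
        readLen + 1L
      starts <- pmax(1L, starts0)
      ends <- pmin(n, starts0 + readLen - 1L)
      keep <- ends - starts + 1L >= min(35L, readLen)
      starts <- starts[keep]
      ends <- ends[keep]
      seqs <- substring(a, starts, ends)
      if (errorRate > 0) {
        seqs <- vapply(seqs, function(s) {
          v <- .seqToInt(s)
          hit <- which(stats::runif(length(v)) < errorRate)
          if (length(hit)) {
            v[hit] <- (v[hit] +
                         sample.int(3L, length(hit), replace = TRUE)) %% 4L
            s <- .intToSeq(v)
          }
          s
        }, "", USE.NAMES = FALSE)
      }
      data.frame(read_id = sprintf("%s_r%d", loc, seq_along(seqs)),
                 locus = loc, seq = seqs, stringsAsFactors = FALSE)
    })
    list(reads = do.call(rbind, out), trueAlleles = alleles)
  })
}
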