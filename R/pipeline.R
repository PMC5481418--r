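# End-to-end orchestration: a single JSON (or list) configuration drives
# simulate -> align -> assign -> bin -> ani -> coregenome -> mlst ->
# diversity, writes per-stage outputs plus a machine-readable report, and
# is byte-identical under a fixed seed + config.

.DEFAULT_THRESHOLDS <- list(
  breadth = 0.90, identity = 0.90, minContigLen = 1000L,
  alignK = 15L, alignMinIdentity = 0.70, alignMinLen = 100L,
  kMax = 8L, gcTol = 0.05, covTol = 0.25, sepThreshold = 2.0,
  minBinContigs = 5L, minBinTotalLen = 50000L,
  fragLen = 1000L, aniThreshold = 97.5,
  orthMinLen = 500L, orthMinIdentity = 0.70, minPrevalence = 0.95,
  maxGapFraction = 0.2, rarefactionDepth = 50000L, correction = "BH",
  mlstK = 21L)

.THRESHOLD_DOMAINS <- list(
  breadth = c(0, 1), identity = c(0, 1), alignMinIdentity = c(0, 1),
  orthMinIdentity = c(0, 1), gcTol = c(0, 1), covTol = c(0, 1),
  minPrevalence = c(0, 1), maxGapFraction = c(0, 1),
  aniThreshold = c(0, 100))

#' Validate and normalise a pipeline configuration
#'
#' Fills documented threshold defaults, checks every threshold against its
#' domain, rejects unknown keys, and enforces that exactly one of a
#' `simulation` block or file-based inputs is present.
#'
#' @param config a named list, or a path to a JSON config file.
#' @return The normalised config list (defaults filled).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(
    config, simplifyVector = TRUE)
  known <- c("seed", "outdir", "simulation", "thresholds", "contigs",
             "references", "referenceMetadata", "scheme", "counts",
             "metadata", "genes")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$seed))
    stop("field 'seed' is mandatory (stochastic stages are seeded)")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outdir)) stop("field 'outdir' is required")
  hasSim <- !is.null(config$simulation)
  hasFiles <- !is.null(config$contigs)
  if (hasSim && hasFiles)
    stop("'contigs' and 'simulation' are mutually exclusive: supply ",
         "either assembled inputs or a simulation spec")
  if (!hasSim && !hasFiles)
    stop("one of 'simulation' or 'contigs' (+'references') is required")
  if (hasFiles) {
    for (f in c("contigs", "references", "referenceMetadata"))
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        stop("field '", f, "': file not found: ", config[[f]])
  }
  th <- config$thresholds
  if (is.null(th)) th <- list()
  badTh <- setdiff(names(th), names(.DEFAULT_THRESHOLDS))
  if (length(badTh))
    stop("unknown threshold(s): ", paste(badTh, collapse = ", "))
  for (nm in names(.THRESHOLD_DOMAINS)) {
    v <- th[[nm]]
    if (!is.null(v)) {
      dom <- .THRESHOLD_DOMAINS[[nm]]
      if (!is.numeric(v) || v <= dom[1L] || v >= dom[2L])
        stop("threshold '", nm, "' out of domain (", dom[1L], ", ",
             dom[2L], "): ", v)
    }
  }
  config$thresholds <- utils::modifyList(.DEFAULT_THRESHOLDS, th)
  config
}

# fixed-shape synthetic world for the simulation-driven pipeline:
# three references (one of them in a two-species clade), contigs from a
# near-reference genome plus two unknown genomes (one moderately diverged
# from reference 2, one unrelated), an MLST scheme with three samples, and
# a paired-site cohort.
.simulateWorld <- function(sim, seed) {
  L <- sim$genomeLength %||% 40000L
  gSet <- evolveGenomeSet(
    genomeSpec("anc2", L, gcTarget = 0.50),
    list(genomeSpec("ref2", L, divergence = 0.02, parent = "anc2"),
         genomeSpec("ref3", L, divergence = 0.05, parent = "anc2"),
         genomeSpec("novel1", L, divergence = sim$novelDivergence %||%
                      0.12, parent = "ref2")),
    seed = seed)
  ref1 <- randomGenome(L, gc = 0.45, seed = seed + 101L)
  known <- .mutateSeq(ref1, sim$knownDivergence %||% 0.005,
                      seed = seed + 102L)
  novel2 <- randomGenome(L, gc = 0.65, seed = seed + 103L)
  refs <- c(ref1 = ref1, ref2 = unname(gSet$genomes["ref2"]),
            ref3 = unname(gSet$genomes["ref3"]))
  refMeta <- data.frame(genome_id = names(refs),
                        species = paste0("Species_", 1:3),
                        stringsAsFactors = FALSE)
  nC <- sim$contigsPerGenome %||% 15L
  minL <- sim$minContigLen %||% 1500L
  cv <- sim$coverageCv %||% 0.1
  contigs <- list(
    fragmentToContigs(known, nC, sim$coverageKnown %||% 30, cv, minL,
                      sourceId = "known", seed = seed + 201L),
    fragmentToContigs(gSet$genomes[["novel1"]], nC,
                      sim$coverageNovel1 %||% 10, cv, minL,
                      sourceId = "novel1", seed = seed + 202L),
    fragmentToContigs(novel2, nC, sim$coverageNovel2 %||% 100, cv, minL,
                      sourceId = "novel2", seed = seed + 203L))
  allSeqs <- unlist(lapply(contigs, contigSeqs))
  allCov <- unlist(lapply(contigs, function(x) unname(contigCoverage(x))))
  allSrc <- unlist(lapply(contigs, function(x) unname(contigSource(x))))
  contigSetAll <- contigSet(allSeqs, allCov, allSrc)

  nGenes <- sim$nGenes %||% 15L
  gl <- sim$geneLength %||% 800L
  starts <- seq(1L, by = gl + 200L, length.out = nGenes)
  genes <- setNames(substring(gSet$genomes[["anc2"]], starts,
                              starts + gl - 1L),
                    sprintf("gene%02d", seq_len(nGenes)))

  mlstCfg <- sim$mlst %||% list()
  scheme <- simulateMlstScheme(
    nLoci = mlstCfg$nLoci %||% 8L, seed = seed + 301L)
  st1 <- vapply(scheme$loci, function(l)
    scheme$alleles[[l]][["1"]], "")
  bAll <- st1
  v <- .seqToInt(bAll[[1L]])
  v[5L] <- (v[5L] + 1L) %% 4L   # one SNP at the first locus
  bAll[1L] <- .intToSeq(v)
  row2 <- scheme$profiles[2L, scheme$loci]
  st2 <- vapply(seq_along(scheme$loci), function(i)
    scheme$alleles[[scheme$loci[i]]][[as.character(row2[[i]])]], "")
  names(st2) <- scheme$loci
  mkReads <- function(alle, s) simulateMlstReads(
    alle, readLen = mlstCfg$readLen %||% 100L,
    coverage = mlstCfg$coverage %||% 20,
    errorRate = mlstCfg$errorRate %||% 0.01, seed = s)
  mlstSamples <- list(sampleA = mkReads(st1, seed + 311L),
                      sampleB = mkReads(bAll, seed + 312L),
                      sampleC = mkReads(st2, seed + 313L))

  cohortCfg <- sim$cohort %||% list()
  cSpec <- cohortSpec(
    nPatients = cohortCfg$nPatients %||% 10L,
    effectMultiplier = cohortCfg$effectMultiplier %||% 2,
    depthPerSample = cohortCfg$depthPerSample %||% 20000L,
    seed = seed + 401L)
  cohort <- simulateCohort(cSpec)

  list(refs = refs, refMeta = refMeta, contigs = contigSetAll,
       genomes = gSet$genomes, genes = genes, scheme = scheme,
       mlstSamples = mlstSamples, cohort = cohort)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Chains the analysis stages in order (simulate or load inputs -> align
#' -> assign -> bin -> ani -> coregenome -> mlst -> diversity), writes
#' per-stage output files under `outdir`, and returns (and writes) a
#' machine-readable report. The same seed and config produce a
#' byte-identical `report.json`.
#'
#' @param config list or JSON path accepted by [validateConfig()].
#' @return The report, invisibly (a nested list; written to
#'   `<outdir>/report.json`).
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  th <- cfg$thresholds
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed, thresholds = th, stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    world <- stage("simulate", .simulateWorld(cfg$simulation, cfg$seed))
    writeContigs(world$contigs, file.path(cfg$outdir, "contigs.fasta"))
    writeFasta(world$refs, file.path(cfg$outdir, "references.fasta"))
    report$stages$simulate <- list(
      n_references = length(world$refs),
      n_contigs = length(world$contigs),
      n_genes = length(world$genes),
      n_cohort_samples = ncol(SummarizedExperiment::assay(world$cohort)))
  } else {
    world <- list(
      contigs = readContigs(cfg$contigs),
      refs = readFasta(cfg$references),
      refMeta = read.table(cfg$referenceMetadata, header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE))
    report$stages$simulate <- NULL
  }

  # --- align + assign -------------------------------------------------
  hits <- stage("align", alignContigs(
    world$contigs, world$refs, k = th$alignK,
    minIdentity = th$alignMinIdentity, minLen = th$alignMinLen))
  writeHitTable(hits, file.path(cfg$outdir, "hits.tsv"))
  report$stages$align <- list(n_hits = nrow(hits))

  assignments <- stage("assign",
    assignContigs(world$contigs, hits, world$refMeta))
  write.table(assignments, file.path(cfg$outdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  labels <- stage("assign", binByLabel(assignments, world$contigs,
                                       th$minContigLen))
  report$stages$assign <- list(
    n_contigs = nrow(assignments),
    n_assigned = sum(assignments$label != "unassigned"),
    species_bins = lapply(labels$bins, length),
    n_residual = length(labels$residual))

  # --- dark binning ---------------------------------------------------
  residual <- world$contigs[labels$residual]
  clustering <- stage("bin", clusterUnassigned(residual, th$kMax,
                                               seed = cfg$seed + 501L))
  curation <- stage("bin", curateBins(
    residual, clustering, th$gcTol, th$covTol, th$sepThreshold,
    th$minBinContigs, th$minBinTotalLen))
  write.table(curation[setdiff(names(curation), "members")],
              file.path(cfg$outdir, "bin_curation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$bin <- list(
    k = clustering$k,
    curated = curation$bin_id[curation$status == "curated"],
    rejected = curation$bin_id[curation$status == "rejected"])

  # --- ANI novelty ----------------------------------------------------
  aniRows <- list()
  novelBins <- character()
  binSeqs <- list()
  for (i in which(curation$status == "curated")) {
    bid <- curation$bin_id[i]
    members <- curation$members[[i]]
    binContigs <- residual[members]
    binSeqs[[bid]] <- paste(contigSeqs(binContigs), collapse = "")
    reports <- do.call(rbind, lapply(names(world$refs), function(r)
      stage("ani", fragmentAni(binContigs, world$refs[[r]],
                               fragLen = th$fragLen, k = th$alignK,
                               queryId = bid, referenceId = r))))
    cls <- classifyBin(reports, th$aniThreshold)
    aniRows[[bid]] <- cls$reports
    if (cls$call == "novel") novelBins <- c(novelBins, bid)
    report$stages$ani[[bid]] <- list(
      call = cls$call, best_reference = cls$best_reference,
      ani_mean = if (!is.na(cls$best_reference))
        cls$reports$ani_mean[cls$reports$reference_id ==
                               cls$best_reference] else NA)
  }
  if (length(aniRows))
    write.table(do.call(rbind, aniRows),
                file.path(cfg$outdir, "ani_reports.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$ani$novel_bins <- novelBins

  # --- core-genome tree ----------------------------------------------
  # placed on the tree: the clade references plus bins called novel by
  # ANI (no-signal bins have no orthologs of the reference gene set)
  if (!is.null(world$genes)) {
    treeGenomes <- c(world$refs["ref2"], world$refs["ref3"],
                     binSeqs[novelBins])
    tab <- stage("coregenome", findOrthologs(
      world$genes, treeGenomes, minLen = th$orthMinLen,
      minIdentity = th$orthMinIdentity))
    core <- stage("coregenome", selectCore(tab, th$minPrevalence))
    aln <- stage("coregenome", trimAlignment(
      buildConcatAlignment(tab, core), th$maxGapFraction))
    newick <- if (length(alignmentRows(aln)) >= 3L) {
      tr <- stage("coregenome", njTree(aln))
      ape::write.tree(tr)
    } else NA_character_
    if (!is.na(newick))
      writeLines(newick, file.path(cfg$outdir, "core_tree.nwk"))
    report$stages$coregenome <- list(
      n_core_genes = length(core),
      alignment_columns = nchar(alignmentRows(aln)[[1L]]),
      newick = newick)
  }

  # --- MLST -----------------------------------------------------------
  if (!is.null(world$scheme)) {
    profiles <- lapply(names(world$mlstSamples), function(s)
      stage("mlst", assignST(
        buildPileups(world$mlstSamples[[s]]$reads, world$scheme,
                     k = th$mlstK),
        world$scheme, sampleId = s)))
    names(profiles) <- names(world$mlstSamples)
    sts <- vapply(profiles, sequenceType, "")
    idPairs <- list()
    nm <- names(profiles)
    for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
      r <- stage("mlst", strainsIdentical(profiles[[i]], profiles[[j]]))
      idPairs[[paste(nm[i], nm[j], sep = "|")]] <- r$identical
    }
    report$stages$mlst <- list(sequence_types = as.list(sts),
                               identical_pairs = idPairs)
  }

  # --- diversity ------------------------------------------------------
  if (!is.null(world$cohort)) {
    counts <- SummarizedExperiment::assay(world$cohort, "counts")
    depth <- min(colSums(counts), th$rarefactionDepth)
    div <- stage("diversity", diversityAnalysis(
      world$cohort, depth = depth, seed = cfg$seed + 601L))
    beta <- stage("diversity", intraInterBeta(div$rarefied))
    paired <- stage("diversity", pairedSiteTest(
      world$cohort, correction = th$correction, seed = cfg$seed + 602L))
    write.table(div$alpha, file.path(cfg$outdir, "alpha_diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(paired, file.path(cfg$outdir, "paired_test.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$diversity <- list(
      n_samples_used = nrow(div$alpha),
      n_excluded = length(div$excluded),
      mean_richness = mean(div$alpha$richness),
      mean_gini_simpson = mean(div$alpha$gini_simpson),
      mean_intra_bc = mean(beta$intra),
      mean_inter_bc = mean(beta$inter),
      significant_taxa = paired$taxon[paired$p_adjusted < 0.05])
  }

  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(cfg$outdir, "report.json"))
  invisible(report)
}
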