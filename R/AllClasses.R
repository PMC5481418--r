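#' @import methods
#' @importFrom stats sd median setNames
NULL

#' GenomeSpec: specification of one synthetic genome
#'
#' Describes a genome to be generated, either de novo (the ancestor) or by
#' substitution-only evolution from a parent genome at a stated per-site
#' divergence.
#'
#' @slot id genome identifier.
#' @slot length genome length in bases (>= 1000).
#' @slot gcTarget target GC fraction in (0, 1).
#' @slot divergence expected substitutions per site from the parent, in
#'   [0, 0.5).
#' @slot parent id of the parent genome; `NA` for the ancestor.
#' @export
setClass("GenomeSpec",
  representation(id = "character", length = "integer",
                 gcTarget = "numeric", divergence = "numeric",
                 parent = "character"),
  prototype(gcTarget = 0.5, divergence = 0, parent = NA_character_))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty string")
  if (object@length < 1000L)
    msg <- c(msg, "length must be >= 1000")
  if (object@gcTarget <= 0 || object@gcTarget >= 1)
    msg <- c(msg, "gcTarget must be in (0, 1)")
  if (object@divergence < 0 || object@divergence >= 0.5)
    msg <- c(msg, "divergence must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param id genome identifier.
#' @param length genome length in bases.
#' @param gcTarget target GC fraction.
#' @param divergence expected substitutions per site from the parent.
#' @param parent parent genome id (`NA` for the ancestor).
#' @return A [GenomeSpec-class] object.
#' @export
genomeSpec <- function(id, length, gcTarget = 0.5, divergence = 0,
                       parent = NA_character_) {
  new("GenomeSpec", id = as.character(id), length = as.integer(length),
      gcTarget = gcTarget, divergence = divergence,
      parent = as.character(parent))
}

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec '%s': %d bp, GC %.2f, divergence %.3f%s\n",
              object@id, object@length, object@gcTarget, object@divergence,
              if (is.na(object@parent)) "" else
                sprintf(" from '%s'", object@parent)))
})

#' CohortSpec: design of a synthetic paired-site cohort
#'
#' Encodes the sampling design the generator emulates: each patient is
#' sampled at every site on both the left and the right side; for each site
#' one side carries visible disease and the contralateral side is
#' unaffected, so every patient always retains at least one unaffected
#' site. A disease effect is planted as a multiplicative increase of one
#' taxon at diseased sites.
#'
#' @slot nPatients number of patients (>= 1).
#' @slot sites site names (e.g. ear, elbow).
#' @slot effectTaxon taxon receiving the planted disease effect.
#' @slot effectMultiplier ratio >= 1 applied to `effectTaxon` at diseased
#'   sites.
#' @slot subjectSd standard deviation of the per-patient, per-taxon
#'   log-abundance offset shared by all samples of a patient.
#' @slot sampleSd standard deviation of the independent per-sample,
#'   per-taxon log-abundance noise (technical / temporal within-subject
#'   variability).
#' @slot depthPerSample sequencing depth (reads) per sample.
#' @slot seed integer seed.
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", sites = "character",
                 effectTaxon = "character", effectMultiplier = "numeric",
                 subjectSd = "numeric", sampleSd = "numeric",
                 depthPerSample = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (!length(object@sites)) msg <- c(msg, "at least one site required")
  if (object@effectMultiplier < 1)
    msg <- c(msg, "effectMultiplier must be >= 1")
  if (object@subjectSd < 0 || object@sampleSd < 0)
    msg <- c(msg, "dispersions must be >= 0")
  if (object@depthPerSample < 1L) msg <- c(msg, "depthPerSample must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nPatients number of patients.
#' @param sites character vector of site names.
#' @param effectTaxon taxon id carrying the planted disease effect.
#' @param effectMultiplier fold-increase (>= 1) of `effectTaxon` at
#'   diseased sites.
#' @param subjectSd per-patient log-normal offset s.d. (default 0.8).
#' @param sampleSd per-sample log-normal noise s.d. (default 0.5).
#' @param depthPerSample reads per sample (default 50000).
#' @param seed integer seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nPatients, sites = c("ear", "elbow"),
                       effectTaxon = "Staphylococcus",
                       effectMultiplier = 1, subjectSd = 0.8,
                       sampleSd = 0.5, depthPerSample = 50000L, seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients), sites = sites,
      effectTaxon = effectTaxon, effectMultiplier = effectMultiplier,
      subjectSd = subjectSd, sampleSd = sampleSd,
      depthPerSample = as.integer(depthPerSample), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d patients x {%s} x {left,right}, ",
                     "depth %d\n  effect: %gx on '%s'; subjectSd %g, ",
                     "sampleSd %g, seed %d\n"),
              object@nPatients, paste(object@sites, collapse = ","),
              object@depthPerSample, object@effectMultiplier,
              object@effectTaxon, object@subjectSd, object@sampleSd,
              object@seed))
})

#' ContigSet: assembled contigs with depth-of-coverage annotations
#'
#' Container for assembled contigs carrying, per contig, its mean depth of
#' coverage and (for synthetic data) the id of the genome it was fragmented
#' from.
#'
#' @slot seqs named character vector of contig sequences.
#' @slot coverage numeric mean depth per contig.
#' @slot source character source-genome id per contig (`NA` when unknown).
#' @export
setClass("ContigSet",
  representation(seqs = "character", coverage = "numeric",
                 source = "character"))

setValidity("ContigSet", function(object) {
  n <- length(object@seqs)
  msg <- character()
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "contigs must have unique names")
  if (length(object@coverage) != n || length(object@source) != n)
    msg <- c(msg, "coverage and source must parallel seqs")
  if (n && any(object@coverage <= 0, na.rm = TRUE))
    msg <- c(msg, "coverage must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ContigSet
#'
#' @param seqs named character vector of contig sequences.
#' @param coverage per-contig mean depth of coverage.
#' @param source per-contig true source genome id (synthetic truth),
#'   `NA` when unknown.
#' @return A [ContigSet-class] object.
#' @export
contigSet <- function(seqs, coverage, source = NA_character_) {
  n <- length(seqs)
  new("ContigSet", seqs = seqs, coverage = rep_len(coverage, n),
      source = rep_len(as.character(source), n))
}

setMethod("show", "ContigSet", function(object) {
  n <- length(object@seqs)
  cat(sprintf("ContigSet: %d contigs, %d bp total\n",
              n, sum(nchar(object@seqs))))
  if (n) cat(sprintf("  coverage: median %.1f [%.1f, %.1f]\n",
                     median(object@coverage), min(object@coverage),
                     max(object@coverage)))
})

#' @describeIn ContigSet-class number of contigs
#' @param x a `ContigSet`.
#' @export
setMethod("length", "ContigSet", function(x) length(x@seqs))

#' Accessors for ContigSet
#'
#' @param x a [ContigSet-class].
#' @return `contigSeqs`: named character vector; `contigCoverage`: numeric
#'   vector; `contigSource`: character vector; `contigLengths`: integer
#'   vector of contig lengths.
#' @export
contigSeqs <- function(x) x@seqs

#' @rdname contigSeqs
#' @export
contigCoverage <- function(x) setNames(x@coverage, names(x@seqs))

#' @rdname contigSeqs
#' @export
contigSource <- function(x) setNames(x@source, names(x@seqs))

#' @rdname contigSeqs
#' @export
contigLengths <- function(x) setNames(nchar(x@seqs), names(x@seqs))

#' Subset a ContigSet by name or index
#'
#' @param x a `ContigSet`.
#' @param i character names or indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ContigSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  new("ContigSet", seqs = x@seqs[i], coverage = x@coverage[i],
      source = x@source[i])
})

#' Write a ContigSet to FASTA
#'
#' Headers carry `cov=<float>` and `src=<id>` key=value tokens after the
#' contig name, the interchange format understood by [readContigs()].
#'
#' @param x a [ContigSet-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeContigs <- function(x, path) {
  hdr <- sprintf("%s cov=%.6g src=%s", names(x@seqs), x@coverage,
                 ifelse(is.na(x@source), ".", x@source))
  writeFasta(setNames(x@seqs, hdr), path)
}

#' Read a ContigSet from FASTA
#'
#' Inverse of [writeContigs()]; contigs without a `cov=` token get coverage
#' 1, `src=.` becomes `NA`.
#'
#' @param path FASTA path.
#' @return A [ContigSet-class].
#' @export
readContigs <- function(path) {
  s <- readFasta(path)
  toks <- strsplit(names(s), "[ \t]+")
  ids <- vapply(toks, `[`, "", 1L)
  getTok <- function(tt, key) {
    hit <- grep(paste0("^", key, "="), tt, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else NA_character_
  }
  cov <- vapply(toks, getTok, "", key = "cov")
  src <- vapply(toks, getTok, "", key = "src")
  cov <- ifelse(is.na(cov), 1, as.numeric(cov))
  src[!is.na(src) & src == "."] <- NA_character_
  contigSet(setNames(unname(s), ids), cov, src)
}

#' MLSTProfile: per-sample multi-locus sequence typing result
#'
#' Ordered locus-to-allele assignments (with consensus sequences) and the
#' derived sequence type for one sample. Allele id `"new"` marks a
#' consensus not matching any catalogued allele; a missing locus has an
#' `NA` sequence.
#'
#' @slot sampleId sample identifier.
#' @slot loci ordered locus names (scheme order).
#' @slot alleleIds per-locus allele id ("new" for uncatalogued, `NA` for
#'   missing).
#' @slot alleleSeqs per-locus consensus sequence (`NA` for missing).
#' @slot st sequence type: a known ST number (as character), "novel", or
#'   "incomplete".
#' @export
setClass("MLSTProfile",
  representation(sampleId = "character", loci = "character",
                 alleleIds = "character", alleleSeqs = "character",
                 st = "character"))

setValidity("MLSTProfile", function(object) {
  n <- length(object@loci)
  if (length(object@alleleIds) != n || length(object@alleleSeqs) != n)
    return("alleleIds and alleleSeqs must parallel loci")
  known <- !is.na(object@alleleIds) & object@alleleIds != "new"
  if (object@st %in% c("novel", "incomplete")) return(TRUE)
  if (!all(known))
    return("st may be a known ST only when every allele is catalogued")
  TRUE
})

setMethod("show", "MLSTProfile", function(object) {
  cat(sprintf("MLSTProfile '%s' (ST %s): %s\n", object@sampleId, object@st,
              paste(object@loci, object@alleleIds, sep = ":",
                    collapse = " ")))
})

#' Sequence type of an MLSTProfile
#'
#' @param x an [MLSTProfile-class].
#' @return Character scalar: a known ST number, "novel" or "incomplete".
#' @export
sequenceType <- function(x) x@st

#' Build a taxon abundance table with sample metadata
#'
#' Packs a taxa-by-samples count matrix and its sample metadata into a
#' [SummarizedExperiment::SummarizedExperiment] (assay `"counts"`,
#' metadata in `colData`), the container the diversity and paired-test
#' functions consume.
#'
#' @param counts integer matrix, taxa in rows, samples in columns.
#' @param metadata data.frame with one row per sample; must contain columns
#'   `sample_id`, `patient`, `site`, `side`, `disease_state`, and
#'   optionally `antibiotic_flag`.
#' @return A `SummarizedExperiment`.
#' @export
abundanceTable <- function(counts, metadata) {
  stopifnot(is.matrix(counts), nrow(metadata) == ncol(counts))
  need <- c("sample_id", "patient", "site", "side", "disease_state")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!"antibiotic_flag" %in% names(metadata))
    metadata$antibiotic_flag <- FALSE
  colnames(counts) <- metadata$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id))
}
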