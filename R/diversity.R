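# Diversity and paired-site comparison protocol: rarefaction to a common
# depth, richness and Gini-Simpson alpha diversity, Bray-Curtis beta
# diversity split into intra- vs inter-subject distances, and the paired
# contralateral-site Wilcoxon signed-rank test with multiple-testing
# correction.

#' Rarefy a count vector to a fixed depth
#'
#' Multivariate hypergeometric subsampling (without replacement) to
#' exactly `depth` reads. A sample shallower than `depth` cannot be
#' rarefied and raises an explicit exclusion condition (class
#' `"darkbinRarefactionExclusion"`) rather than being silently truncated,
#' mirroring the protocol of dropping samples below the rarefaction depth.
#'
#' @param counts named non-negative integer vector.
#' @param depth target depth.
#' @param seed integer seed.
#' @return Integer vector summing to `depth` exactly.
#' @export
rarefyCounts <- function(counts, depth, seed = 1L) {
  total <- sum(counts)
  if (depth > total) {
    cond <- structure(
      class = c("darkbinRarefactionExclusion", "error", "condition"),
      list(message = sprintf(
        "sample depth %d is below the rarefaction depth %d; exclude it",
        total, as.integer(depth)), call = sys.call()))
    stop(cond)
  }
  if (depth == total) return(counts)
  .withSeed(seed, {
    # rrarefy emits a heuristic "observed counts" warning whenever the
    # smallest non-zero count exceeds 1; spurious for valid count data
    out <- as.integer(suppressWarnings(
      vegan::rrarefy(matrix(counts, nrow = 1L), depth)))
    names(out) <- names(counts)
    out
  })
}

#' Richness and Gini-Simpson evenness of one sample
#'
#' Richness is the number of taxa with non-zero counts; the Gini-Simpson
#' index is `1 - sum(p_i^2)` over relative abundances — the probability
#' that two randomly drawn reads come from different taxa.
#'
#' @param counts non-negative count vector with a positive total.
#' @param sampleId optional id recorded in the output.
#' @return One-row data.frame: `sample_id`, `richness`, `gini_simpson`,
#'   `depth_used`.
#' @export
alphaDiversity <- function(counts, sampleId = NA_character_) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total <= 0) stop("alpha diversity undefined for an empty sample")
  p <- counts / total
  data.frame(sample_id = sampleId, richness = sum(counts > 0),
             gini_simpson = 1 - sum(p^2), depth_used = total,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis distance between two relative-abundance profiles
#'
#' `1 - sum(min(p_i, q_i))` over the shared taxon universe; both profiles
#' must sum to 1. Symmetric and bounded in [0, 1].
#'
#' @param p,q numeric vectors over the same taxa, each summing to 1.
#' @return Distance in [0, 1].
#' @export
brayCurtis <- function(p, q) {
  stopifnot(length(p) == length(q),
            abs(sum(p) - 1) < 1e-6, abs(sum(q) - 1) < 1e-6)
  1 - sum(pmin(p, q))
}

#' Intra- vs inter-subject Bray-Curtis beta diversity
#'
#' All pairwise Bray-Curtis distances between samples (each unordered pair
#' once) partitioned into same-patient and different-patient sets, with a
#' descriptive Wilcoxon rank-sum comparison. Pairwise distances sharing
#' samples are not independent, so the p-value is descriptive only; the
#' returned `caveat` says so.
#'
#' @param se `SummarizedExperiment` from [abundanceTable()], already
#'   rarefied to a common depth if desired.
#' @return list: `intra`, `inter` (numeric distance vectors), `test`
#'   (`htest` from the rank-sum comparison, or `NULL` when degenerate),
#'   `caveat`.
#' @export
intraInterBeta <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  patient <- SummarizedExperiment::colData(se)$patient
  stopifnot(length(unique(patient)) >= 2L)
  rel <- sweep(counts, 2L, colSums(counts), "/")
  n <- ncol(rel)
  D <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  same <- outer(patient, patient, "==")
  ut <- upper.tri(D)
  intra <- D[ut & same]
  inter <- D[ut & !same]
  test <- if (length(intra) && length(inter) &&
              (length(unique(c(intra, inter))) > 1L))
    suppressWarnings(stats::wilcox.test(intra, inter)) else NULL
  list(intra = intra, inter = inter, test = test,
       caveat = paste("pairwise distances share samples and are not",
                      "independent; the rank-sum p-value is descriptive",
                      "only"))
}

#' Per-sample diversity records at a common rarefaction depth
#'
#' Rarefies every sample to `depth` (samples shallower than `depth`, and
#' antibiotic-flagged samples, are excluded) and computes
#' [alphaDiversity()] per remaining sample.
#'
#' @param se `SummarizedExperiment` from [abundanceTable()].
#' @param depth rarefaction depth (default 50000 reads).
#' @param seed integer seed.
#' @return list: `alpha` (data.frame of per-sample records), `rarefied`
#'   (the rarefied `SummarizedExperiment`), `excluded` (ids of dropped
#'   samples).
#' @export
diversityAnalysis <- function(se, depth = 50000L, seed = 1L) {
  cd <- SummarizedExperiment::colData(se)
  keep <- !as.logical(cd$antibiotic_flag)
  counts <- SummarizedExperiment::assay(se, "counts")
  deep <- colSums(counts) >= depth
  excluded <- colnames(counts)[!(keep & deep)]
  sel <- which(keep & deep)
  if (!length(sel)) stop("no samples at or above the rarefaction depth")
  rar <- vapply(seq_along(sel), function(i)
    as.numeric(rarefyCounts(counts[, sel[i]], depth, seed = seed + i)),
    numeric(nrow(counts)))
  colnames(rar) <- colnames(counts)[sel]
  rownames(rar) <- rownames(counts)
  alpha <- do.call(rbind, lapply(colnames(rar), function(s)
    alphaDiversity(rar[, s], s)))
  rse <- abundanceTable(rar, as.data.frame(cd[sel, , drop = FALSE]))
  list(alpha = alpha, rarefied = rse, excluded = excluded)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param groupA,groupB numeric vectors, each with at least two values;
#'   at least one group must have positive variance.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
welchT <- function(groupA, groupB) {
  stopifnot(length(groupA) >= 2L, length(groupB) >= 2L)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0 &&
      mean(groupA) == mean(groupB)) {
    # identical constant groups: no evidence of a difference
    if (!identical(sort(groupA), sort(groupB)))
      stop("degenerate zero-variance groups")
    return(list(statistic = 0, df = NA_real_, p_value = 1))
  }
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0)
    stop("both groups have zero variance; Welch t undefined")
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

# locate (diseased, unaffected) contralateral pairs: per patient and site,
# one diseased and one unaffected sample on opposite sides
.findPairs <- function(cd, siteClass = NULL) {
  cd <- as.data.frame(cd)
  cd <- cd[!as.logical(cd$antibiotic_flag), , drop = FALSE]
  if (!is.null(siteClass)) cd <- cd[cd$site %in% siteClass, , drop = FALSE]
  pairs <- list()
  for (p in unique(cd$patient)) for (s in unique(cd$site)) {
    sub <- cd[cd$patient == p & cd$site == s, , drop = FALSE]
    dis <- sub$sample_id[sub$disease_state == "diseased"]
    un <- sub$sample_id[sub$disease_state == "unaffected"]
    if (length(dis) == 1L && length(un) == 1L &&
        sub$side[match(dis, sub$sample_id)] !=
        sub$side[match(un, sub$sample_id)])
      pairs[[length(pairs) + 1L]] <-
        data.frame(patient = p, site = s, diseased = dis,
                   unaffected = un, stringsAsFactors = FALSE)
  }
  if (!length(pairs)) return(NULL)
  do.call(rbind, pairs)
}

#' Paired contralateral-site differential-abundance test
#'
#' For every patient contributing one diseased and one unaffected
#' contralateral sample of the same site, both samples are rarefied to the
#' pair's minimum depth (seeded); per taxon, a two-sided Wilcoxon
#' signed-rank test is applied to the relative abundances across pairs and
#' p-values are corrected over the taxa tested.
#'
#' @param se `SummarizedExperiment` from [abundanceTable()].
#' @param taxa taxa to test (default: all taxa in the table).
#' @param siteClass optional site subset (e.g. `"elbow"` for
#'   elbow-only pairings).
#' @param correction multiple-testing correction method for
#'   [stats::p.adjust()] (default `"BH"`).
#' @param seed integer seed for the pair-minimum rarefaction.
#' @return data.frame with one row per taxon: `taxon`, `n_pairs`,
#'   `statistic`, `p_raw`, `p_adjusted`, `direction` (`"diseased_up"` /
#'   `"diseased_down"` / `"none"`). Fewer than 6 pairs triggers a
#'   small-sample warning; no eligible pairs is an error.
#' @export
pairedSiteTest <- function(se, taxa = NULL, siteClass = NULL,
                           correction = "BH", seed = 1L) {
  counts <- SummarizedExperiment::assay(se, "counts")
  pairs <- .findPairs(SummarizedExperiment::colData(se), siteClass)
  if (is.null(pairs)) stop("no eligible (diseased, unaffected) ",
                           "contralateral pairs in the table")
  if (nrow(pairs) < 6L)
    warning("only ", nrow(pairs), " pairs; the signed-rank test has ",
            "little power below 6 pairs")
  if (is.null(taxa)) taxa <- rownames(counts)
  stopifnot(all(taxa %in% rownames(counts)))

  relD <- matrix(NA_real_, length(taxa), nrow(pairs),
                 dimnames = list(taxa, NULL))
  relU <- relD
  for (i in seq_len(nrow(pairs))) {
    d <- counts[, pairs$diseased[i]]
    u <- counts[, pairs$unaffected[i]]
    dm <- min(sum(d), sum(u))
    d <- rarefyCounts(d, dm, seed = seed + 2L * i)
    u <- rarefyCounts(u, dm, seed = seed + 2L * i + 1L)
    relD[, i] <- (d / sum(d))[taxa]
    relU[, i] <- (u / sum(u))[taxa]
  }

  rows <- lapply(taxa, function(tx) {
    x <- relD[tx, ]
    y <- relU[tx, ]
    diffs <- x - y
    if (all(diffs == 0)) {
      stat <- 0; p <- 1
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    med <- stats::median(diffs)
    data.frame(taxon = tx, n_pairs = length(x), statistic = stat,
               p_raw = p,
               direction = if (med > 0) "diseased_up"
                           else if (med < 0) "diseased_down" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = correction)
  out[, c("taxon", "n_pairs", "statistic", "p_raw", "p_adjusted",
          "direction")]
}
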