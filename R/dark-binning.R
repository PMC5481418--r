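# Preliminary K-means binning of unassigned contigs on (GC, log10 coverage)
# and automated curation replacing the visual inspection step: per-member
# GC/coverage consistency around the bin median plus a quantitative
# centroid-separation score.

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguous bases are excluded from
#' both numerator and denominator.
#'
#' @param sequence character scalar.
#' @return GC fraction in [0, 1].
#' @export
gcContent <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  f <- Biostrings::letterFrequency(
    Biostrings::DNAString(toupper(sequence)), c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0)
    stop("sequence has no unambiguous A/C/G/T bases; GC undefined")
  unname((f[["C"]] + f[["G"]]) / tot)
}

# standardized (gc, log10 cov) feature matrix; a zero-variance feature
# maps to all-zeros instead of NaN
.binFeatures <- function(contigs) {
  gc <- vapply(contigSeqs(contigs), gcContent, 0)
  f <- cbind(gc = gc, logcov = log10(contigCoverage(contigs)))
  apply(f, 2L, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
}

#' Cluster unassigned contigs on GC content and coverage
#'
#' K-means (10 restarts, seeded) on per-contig (GC fraction, log10
#' coverage), each standardized to zero mean and unit variance. K is
#' chosen in `2..kMax` by maximum mean silhouette width; when the best
#' silhouette is below 0.25 the contigs are left as a single bin.
#'
#' @param contigs residual [ContigSet-class] (the unassigned set).
#' @param kMax largest K considered (default 8).
#' @param seed integer seed for the K-means restarts.
#' @return list: `assignment` (named integer vector, contig -> bin),
#'   `k` (number of bins), `silhouette` (mean silhouette of the chosen K,
#'   `NA` for a single bin), `features` (the standardized feature matrix).
#' @export
clusterUnassigned <- function(contigs, kMax = 8L, seed = 1L) {
  n <- length(contigs)
  ids <- names(contigSeqs(contigs))
  if (n < 2L) {
    return(list(assignment = setNames(rep(1L, n), ids), k = 1L,
                silhouette = NA_real_,
                features = if (n) .binFeatures(contigs) else NULL))
  }
  feats <- .binFeatures(contigs)
  nDistinct <- nrow(unique(feats))
  if (nDistinct < 2L)
    return(list(assignment = setNames(rep(1L, n), ids), k = 1L,
                silhouette = NA_real_, features = feats))
  kGrid <- seq(2L, max(2L, min(kMax, n - 1L, nDistinct)))
  .withSeed(seed, {
    d <- stats::dist(feats)
    best <- NULL
    bestSil <- -Inf
    for (kk in kGrid) {
      km <- stats::kmeans(feats, centers = kk, nstart = 10L,
                          iter.max = 50L)
      sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (sil > bestSil) {
        bestSil <- sil
        best <- km$cluster
      }
    }
    if (bestSil < 0.25) {
      list(assignment = setNames(rep(1L, n), ids), k = 1L,
           silhouette = bestSil, features = feats)
    } else {
      list(assignment = setNames(as.integer(best), ids),
           k = length(unique(best)), silhouette = bestSil,
           features = feats)
    }
  })
}

#' Curate preliminary GC-coverage bins
#'
#' A preliminary bin is curated iff (i) every member's relative deviation
#' of GC from the bin's GC median is below `gcTol`; (ii) every member's
#' relative deviation of coverage from the bin's coverage median is below
#' `covTol`; (iii) its separation score — distance from its centroid to the
#' nearest other bin centroid in the standardized feature space, divided by
#' its RMS within-bin radius — exceeds `sepThreshold`; and (iv) it holds at
#' least `minContigs` contigs and `minTotalLen` bases (smaller bins cannot
#' support ANI or phylogeny downstream). All other bins are rejected with a
#' reason. Curation depends only on the bin memberships, so it is
#' idempotent and order-independent.
#'
#' @param contigs the residual [ContigSet-class] that was clustered.
#' @param clustering result of [clusterUnassigned()].
#' @param gcTol maximum relative GC deviation (default 0.05).
#' @param covTol maximum relative coverage deviation (default 0.25).
#' @param sepThreshold minimum separation score (default 2).
#' @param minContigs minimum bin size in contigs (default 5).
#' @param minTotalLen minimum bin size in bases (default 50000).
#' @return data.frame with one row per bin: `bin_id`, `n_contigs`,
#'   `total_length`, `gc_mean`, `gc_max_rel_dev`, `cov_median`,
#'   `cov_max_rel_dev`, `separation_score`, `status`
#'   (`curated`/`rejected`), `reject_reason`, and a `members` list-column
#'   of contig ids.
#' @export
curateBins <- function(contigs, clustering, gcTol = 0.05, covTol = 0.25,
                       sepThreshold = 2.0, minContigs = 5L,
                       minTotalLen = 50000L) {
  assign <- clustering$assignment
  ids <- names(assign)
  feats <- clustering$features
  if (is.null(feats)) feats <- .binFeatures(contigs[ids])
  gc <- vapply(contigSeqs(contigs)[ids], gcContent, 0)
  cov <- contigCoverage(contigs)[ids]
  lens <- contigLengths(contigs)[ids]
  binIds <- sort(unique(assign))
  cent <- t(vapply(binIds, function(b)
    colMeans(feats[assign == b, , drop = FALSE]), numeric(2L)))
  rows <- lapply(seq_along(binIds), function(i) {
    b <- binIds[i]
    sel <- assign == b
    gcMed <- median(gc[sel])
    covMed <- median(cov[sel])
    gcDev <- if (gcMed > 0) max(abs(gc[sel] - gcMed) / gcMed) else Inf
    covDev <- if (covMed > 0) max(abs(cov[sel] - covMed) / covMed) else Inf
    radius <- sqrt(mean(rowSums(
      (feats[sel, , drop = FALSE] -
         matrix(cent[i, ], sum(sel), 2L, byrow = TRUE))^2)))
    if (length(binIds) > 1L) {
      nd <- min(sqrt(rowSums(
        (cent[-i, , drop = FALSE] -
           matrix(cent[i, ], length(binIds) - 1L, 2L, byrow = TRUE))^2)))
      sepScore <- if (radius == 0) {
        if (nd > 0) Inf else 0
      } else nd / radius
    } else {
      sepScore <- Inf  # a lone bin is vacuously separated
    }
    reasons <- character()
    if (gcDev >= gcTol) reasons <- c(reasons, "gc_consistency")
    if (covDev >= covTol) reasons <- c(reasons, "cov_consistency")
    if (sepScore <= sepThreshold) reasons <- c(reasons, "separation")
    if (sum(sel) < minContigs || sum(lens[sel]) < minTotalLen)
      reasons <- c(reasons, "size")
    data.frame(bin_id = sprintf("bin%02d", b), n_contigs = sum(sel),
               total_length = sum(lens[sel]), gc_mean = mean(gc[sel]),
               gc_max_rel_dev = gcDev, cov_median = covMed,
               cov_max_rel_dev = covDev, separation_score = sepScore,
               status = if (length(reasons)) "rejected" else "curated",
               reject_reason = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(binIds, function(b) ids[assign == b])
  out
}
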