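# Conservative per-contig taxonomy: breadth of coverage and identity
# against the best-matching reference genome, then a strict 90/90
# species-assignment rule and binning of long labelled contigs.

#' Breadth of coverage and mean identity of one contig against one
#' reference
#'
#' Breadth is the fraction of the contig covered by the union of the hits'
#' query intervals; identity is the alignment-length-weighted mean of the
#' hit identities (overlapping hits each contribute their full length).
#'
#' @param contigLength contig length in bases.
#' @param hits hits data.frame; all rows must share one query (the contig)
#'   and one subject (the reference).
#' @return `c(breadth, identity)`; `(0, 0)` when there are no hits.
#' @export
breadthAndIdentity <- function(contigLength, hits) {
  if (is.null(hits) || !nrow(hits)) return(c(breadth = 0, identity = 0))
  if (length(unique(hits$queryId)) > 1L ||
      length(unique(hits$subjectId)) > 1L)
    stop("hits must involve a single contig and a single reference")
  if (any(hits$queryStart < 0L) || any(hits$queryEnd > contigLength))
    stop("hit interval outside [0, contigLength)")
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$queryStart + 1L,
                                         end = hits$queryEnd))
  breadth <- sum(IRanges::width(ir)) / contigLength
  identity <- sum(hits$alignedLength * hits$identity) /
    sum(hits$alignedLength)
  c(breadth = breadth, identity = identity)
}

#' Best-matching reference genome for a contig
#'
#' The reference maximising the summed alignment score
#' `sum(alignedLength * identity)` over its hits; ties broken by
#' lexicographically smaller genome id.
#'
#' @param hits all hits of one contig (any number of subjects).
#' @return Reference id, or `NA` when there are no hits.
#' @export
bestReference <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return(NA_character_)
  sc <- tapply(hits$alignedLength * hits$identity, hits$subjectId, sum)
  ids <- sort(names(sc))  # lexicographic tie-break
  sc <- sc[ids]
  ids[which.max(sc)]
}

#' Apply the conservative 90/90 species-assignment rule
#'
#' A contig receives the species label of its best-matching reference iff
#' both breadth of coverage and identity are strictly greater than 0.90;
#' boundary equality leaves it unassigned.
#'
#' @param breadth breadth of coverage in [0, 1].
#' @param identity identity fraction in [0, 1].
#' @param species species name of the best-matching reference.
#' @return The species label, or `"unassigned"`.
#' @export
assignContig <- function(breadth, identity, species) {
  stopifnot(breadth >= 0, breadth <= 1, identity >= 0, identity <= 1)
  if (breadth > 0.90 && identity > 0.90 && !is.na(species)) species
  else "unassigned"
}

#' Assign taxonomy to every contig in a set
#'
#' Driver: groups `hits` per contig, picks the best reference via
#' [bestReference()], computes breadth and identity against that
#' reference's hits only, and applies [assignContig()] with the species of
#' the best reference from `refMeta`.
#'
#' @param contigs a [ContigSet-class].
#' @param hits hits data.frame covering all contigs (e.g. from
#'   [alignContigs()] or [readHitTable()]).
#' @param refMeta data.frame mapping `genome_id` to `species`.
#' @return data.frame with one row per contig: `contig_id`,
#'   `best_reference`, `breadth`, `identity`, `label`.
#' @export
assignContigs <- function(contigs, hits, refMeta) {
  stopifnot(all(c("genome_id", "species") %in% names(refMeta)))
  ids <- names(contigSeqs(contigs))
  lens <- contigLengths(contigs)
  split_hits <- if (nrow(hits)) split(hits, hits$queryId) else list()
  rows <- lapply(ids, function(cid) {
    h <- split_hits[[cid]]
    best <- bestReference(h)
    if (is.na(best)) {
      bi <- c(0, 0)
    } else {
      bi <- breadthAndIdentity(lens[[cid]], h[h$subjectId == best, ,
                                              drop = FALSE])
    }
    sp <- if (is.na(best)) NA_character_ else
      refMeta$species[match(best, refMeta$genome_id)]
    data.frame(contig_id = cid, best_reference = best,
               breadth = unname(bi[1L]), identity = unname(bi[2L]),
               label = assignContig(bi[1L], bi[2L], sp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bin labelled contigs by species; route the rest to the residual set
#'
#' Long contigs (strictly longer than `minContigLen`, default 1000 nt)
#' carrying a species label form one bin per species; every other contig
#' (unassigned, or labelled but short) goes to the residual set handed to
#' the GC-coverage binning of unassigned contigs. Every input contig
#' appears in exactly one output set.
#'
#' @param assignments data.frame from [assignContigs()].
#' @param contigs the matching [ContigSet-class].
#' @param minContigLen length threshold (exclusive) for binned contigs.
#' @return list with `bins` (named list: species -> character vector of
#'   contig ids) and `residual` (character vector of contig ids).
#' @export
binByLabel <- function(assignments, contigs, minContigLen = 1000L) {
  stopifnot(setequal(assignments$contig_id, names(contigSeqs(contigs))))
  lens <- contigLengths(contigs)[assignments$contig_id]
  binned <- assignments$label != "unassigned" & lens > minContigLen
  bins <- split(assignments$contig_id[binned], assignments$label[binned])
  residual <- assignments$contig_id[!binned]
  list(bins = bins, residual = residual)
}
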