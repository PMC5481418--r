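# Fragment-based average nucleotide identity between a bin (or genome) and
# candidate references, and the species-vs-novel call at the strict 97.5%
# boundary.

#' Fragment-based ANI of a query sequence set against one reference
#'
#' Each query sequence is cut into consecutive `fragLen` windows (terminal
#' fragments shorter than `fragLen/2` are discarded); each fragment is
#' aligned to the reference with the native seed-and-extend aligner and its
#' best hit kept. A fragment is retained when that hit has identity at
#' least `minFragIdentity` and covers at least `minFragCov` of the
#' fragment. `ani_mean`/`ani_sd` are the mean and standard deviation of the
#' retained fragment identities, expressed as percentages.
#'
#' @param query named character vector of sequences (a bin's contigs or a
#'   genome), or a [ContigSet-class].
#' @param reference reference sequence (character scalar).
#' @param fragLen fragment window length (default 1000).
#' @param minFragIdentity retention threshold on hit identity (default
#'   0.70).
#' @param minFragCov retention threshold on the covered fraction of the
#'   fragment (default 0.70).
#' @param k seed length for the aligner (default 15).
#' @param queryId,referenceId ids recorded in the report.
#' @return One-row data.frame: `query_id`, `reference_id`, `ani_mean`,
#'   `ani_sd` (percent; `ani_sd` 0 for a single retained fragment),
#'   `n_fragments_retained`, `n_fragments_total`, `call` (`"no_signal"`
#'   when nothing is retained, otherwise `NA` until [classifyBin()]).
#' @export
fragmentAni <- function(query, reference, fragLen = 1000L,
                        minFragIdentity = 0.70, minFragCov = 0.70,
                        k = 15L, queryId = "query",
                        referenceId = "reference") {
  if (is(query, "ContigSet")) query <- contigSeqs(query)
  if (is.null(names(query))) names(query) <- sprintf("q%d", seq_along(query))
  frags <- character(0)
  for (qn in names(query)) {
    s <- query[[qn]]
    n <- nchar(s)
    if (n < fragLen / 2) next
    starts <- seq(1L, n, by = fragLen)
    ends <- pmin(starts + fragLen - 1L, n)
    keep <- (ends - starts + 1L) >= fragLen / 2
    frags <- c(frags, substring(s, starts[keep], ends[keep]))
  }
  total <- length(frags)
  idx <- .subjectIndex(reference, k)
  idents <- numeric(0)
  for (fr in frags) {
    h <- seedExtendAlign(fr, "", k = k, minIdentity = minFragIdentity,
                         minLen = as.integer(ceiling(
                           minFragCov * nchar(fr))),
                         index = idx)
    if (!nrow(h)) next
    best <- which.max(h$alignedLength * h$identity)
    idents <- c(idents, h$identity[best])
  }
  retained <- length(idents)
  data.frame(
    query_id = queryId, reference_id = referenceId,
    ani_mean = if (retained) mean(idents) * 100 else NA_real_,
    ani_sd = if (retained > 1L) sd(idents) * 100 else
      if (retained == 1L) 0 else NA_real_,
    n_fragments_retained = retained, n_fragments_total = total,
    call = if (retained) NA_character_ else "no_signal",
    stringsAsFactors = FALSE)
}

#' Classify a bin as assigned-to-species or novel from its ANI reports
#'
#' The best reference is the one with the highest `ani_mean` among reports
#' with signal. The bin is assigned to that reference's species iff its
#' `ani_mean` is strictly greater than `threshold` (default 97.5%); ANI at
#' or below the boundary yields `"novel"` (a conservative call: an exact
#' 97.5% is not enough for a species assignment). If every report is
#' `no_signal` the call is `"no_signal"`.
#'
#' @param reports data.frame of rows from [fragmentAni()] against all
#'   candidate references.
#' @param threshold ANI percentage boundary (default 97.5).
#' @return list: `call` (`"assigned"`, `"novel"` or `"no_signal"`),
#'   `best_reference` (id or `NA`), and `reports` with the `call` column
#'   filled on the best row.
#' @export
classifyBin <- function(reports, threshold = 97.5) {
  stopifnot(nrow(reports) >= 1L)
  withSignal <- which(!is.na(reports$ani_mean))
  if (!length(withSignal)) {
    reports$call <- "no_signal"
    return(list(call = "no_signal", best_reference = NA_character_,
                reports = reports))
  }
  best <- withSignal[which.max(reports$ani_mean[withSignal])]
  call <- if (reports$ani_mean[best] > threshold) "assigned" else "novel"
  reports$call[best] <- call
  list(call = call, best_reference = reports$reference_id[best],
       reports = reports)
}
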