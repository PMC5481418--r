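# Deterministic seed-and-extend local aligner (ungapped) plus reader/writer
# for the 12-column BLAST tabular dialect. Coordinates inside the package
# are 0-based half-open; the tabular dialect on disk is 1-based inclusive.

.HIT_COLS <- c("queryId", "subjectId", "queryStart", "queryEnd",
               "subjectStart", "subjectEnd", "identity", "alignedLength",
               "matches", "strand")

.emptyHits <- function() {
  data.frame(queryId = character(), subjectId = character(),
             queryStart = integer(), queryEnd = integer(),
             subjectStart = integer(), subjectEnd = integer(),
             identity = numeric(), alignedLength = integer(),
             matches = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

# numeric k-mer codes (base-4); NA where the window holds a non-ACGT base.
# k <= 26 keeps codes exactly representable as doubles.
.kmerCodes <- function(ints, k) {
  n <- length(ints)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  Reduce(`+`, lapply(0:(k - 1L), function(j)
    ints[(1L + j):(m + j)] * 4^(k - 1L - j)))
}

# Pre-computed subject index, reusable across queries.
.subjectIndex <- function(subject, k) {
  ints <- .seqToInt(subject)
  codes <- .kmerCodes(ints, k)
  ok <- which(!is.na(codes))
  sc <- codes[ok]
  ord <- order(sc, ok)  # position as tie-break keeps ordering total
  list(ints = ints, n = length(ints), k = k,
       sortedCodes = sc[ord], sortedPos = ok[ord])
}

# X-drop ungapped extension of one exact seed along one diagonal.
# s: +1/-2 score vector over the diagonal overlap; r: seed start (relative);
# returns c(start, end) relative indices of the extended segment.
.extendSeed <- function(s, r, k, xDrop) {
  len <- length(s)
  e0 <- r + k - 1L
  right <- 0L
  if (e0 < len) {
    cs <- cumsum(s[(e0 + 1L):len])
    cm <- cummax(cs)
    stop <- which(cm - cs > xDrop)
    lim <- if (length(stop)) stop[1L] else length(cs)
    j <- which.max(cs[seq_len(lim)])
    if (cs[j] > 0) right <- j
  }
  left <- 0L
  if (r > 1L) {
    cs <- cumsum(s[(r - 1L):1L])
    cm <- cummax(cs)
    stop <- which(cm - cs > xDrop)
    lim <- if (length(stop)) stop[1L] else length(cs)
    j <- which.max(cs[seq_len(lim)])
    if (cs[j] > 0) left <- j
  }
  c(r - left, e0 + right)
}

#' Align a query to a subject by exact k-mer seeding and ungapped extension
#'
#' Finds exact k-mer seeds shared by query and subject, extends each seed
#' without gaps in both directions under an X-drop rule (match +1,
#' mismatch -2, abandon when the running score falls `xDrop` below its
#' maximum, then trim back to the maximum), and merges overlapping
#' extensions on the same diagonal. Hits failing `minIdentity` or `minLen`
#' are dropped. The procedure is fully deterministic.
#'
#' @param query,subject sequences (character scalars over A/C/G/T;
#'   other letters can never seed or match).
#' @param k seed length (>= 8, <= 26; default 15).
#' @param minIdentity minimum hit identity fraction (default 0.70).
#' @param minLen minimum hit length in bases (default 100).
#' @param xDrop X-drop score threshold (default 20).
#' @param queryId,subjectId ids recorded in the output.
#' @param index optional pre-built subject index (internal reuse).
#' @param maxSeedsPerKmer cap on subject positions considered per query
#'   k-mer (lowest positions kept; guards repetitive sequence).
#' @return data.frame of hits with 0-based half-open `queryStart/End`,
#'   `subjectStart/End`, `identity` (fraction), `alignedLength`, `matches`
#'   and `strand`, sorted by query start. Empty input yields zero rows.
#' @export
seedExtendAlign <- function(query, subject, k = 15L, minIdentity = 0.70,
                            minLen = 100L, xDrop = 20L,
                            queryId = "query", subjectId = "subject",
                            index = NULL, maxSeedsPerKmer = 50L) {
  stopifnot(k >= 8L, k <= 26L)
  if (!nzchar(query) || (is.null(index) && !nzchar(subject)))
    return(.emptyHits())
  if (is.null(index)) index <- .subjectIndex(subject, k)
  stopifnot(index$k == k)
  qints <- .seqToInt(query)
  nq <- length(qints)
  if (nq < k || index$n < k) return(.emptyHits())
  qcodes <- .kmerCodes(qints, k)
  qok <- which(!is.na(qcodes))
  if (!length(qok)) return(.emptyHits())
  qc <- qcodes[qok]
  hi <- findInterval(qc, index$sortedCodes)
  lo <- findInterval(qc - 0.5, index$sortedCodes) + 1L
  cnt <- pmin(hi - lo + 1L, maxSeedsPerKmer)
  keep <- which(cnt > 0L)
  if (!length(keep)) return(.emptyHits())
  qpos <- rep(qok[keep], cnt[keep])
  spos <- index$sortedPos[sequence(cnt[keep], from = lo[keep])]
  diag <- spos - qpos

  sints <- index$ints
  ns <- index$n
  out <- list()
  for (d in unique(diag)) {
    qlo <- max(1L, 1L - d)
    qhi <- min(nq, ns - d)
    if (qhi - qlo + 1L < k) next
    qi <- qlo:qhi
    mism <- qints[qi] != sints[qi + d]
    mism[is.na(mism)] <- TRUE
    s <- ifelse(mism, -2L, 1L)
    seeds <- sort(unique(qpos[diag == d])) - qlo + 1L
    segs <- list()
    covered_to <- 0L
    for (r in seeds) {
      if (r + k - 1L <= covered_to) next
      seg <- .extendSeed(s, r, k, xDrop)
      segs[[length(segs) + 1L]] <- seg
      covered_to <- max(covered_to, seg[2L])
    }
    if (!length(segs)) next
    m <- do.call(rbind, segs)
    m <- m[order(m[, 1L]), , drop = FALSE]
    # merge overlapping segments on this diagonal
    merged <- list(m[1L, ])
    if (nrow(m) > 1L) for (i in 2:nrow(m)) {
      last <- merged[[length(merged)]]
      if (m[i, 1L] <= last[2L] + 1L) {
        merged[[length(merged)]] <- c(last[1L], max(last[2L], m[i, 2L]))
      } else merged[[length(merged) + 1L]] <- m[i, ]
    }
    for (seg in merged) {
      len <- seg[2L] - seg[1L] + 1L
      matches <- sum(!mism[seg[1L]:seg[2L]])
      ident <- matches / len
      if (len >= minLen && ident >= minIdentity) {
        qs <- qlo + seg[1L] - 2L  # 0-based start
        out[[length(out) + 1L]] <- data.frame(
          queryId = queryId, subjectId = subjectId,
          queryStart = qs, queryEnd = qs + len,
          subjectStart = qs + d, subjectEnd = qs + d + len,
          identity = ident, alignedLength = len, matches = matches,
          strand = "+", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.emptyHits())
  res <- do.call(rbind, out)
  res[order(res$queryId, res$queryStart, res$subjectStart), , drop = FALSE]
}

#' Align many queries against many subjects
#'
#' Convenience driver over [seedExtendAlign()]: builds each subject index
#' once and aligns every query against every subject, optionally also in
#' reverse complement (minus-strand hits get `strand = "-"` with query
#' coordinates mapped back to the forward query).
#'
#' @param queries named character vector of query sequences, or a
#'   [ContigSet-class].
#' @param subjects named character vector of subject sequences.
#' @param revComp also search the reverse complement of each query
#'   (default FALSE; synthetic data is strand-consistent).
#' @inheritParams seedExtendAlign
#' @return Combined hits data.frame sorted by query id then query start.
#' @export
alignContigs <- function(queries, subjects, k = 15L, minIdentity = 0.70,
                         minLen = 100L, xDrop = 20L, revComp = FALSE) {
  if (is(queries, "ContigSet")) queries <- contigSeqs(queries)
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  res <- list()
  for (sid in names(subjects)) {
    idx <- .subjectIndex(subjects[[sid]], k)
    for (qid in names(queries)) {
      h <- seedExtendAlign(queries[[qid]], "", k, minIdentity, minLen,
                           xDrop, queryId = qid, subjectId = sid,
                           index = idx)
      res[[length(res) + 1L]] <- h
      if (revComp) {
        rc <- .revComp(queries[[qid]])
        hr <- seedExtendAlign(rc, "", k, minIdentity, minLen, xDrop,
                              queryId = qid, subjectId = sid, index = idx)
        if (nrow(hr)) {
          L <- nchar(queries[[qid]])
          qs <- L - hr$queryEnd
          hr$queryEnd <- L - hr$queryStart
          hr$queryStart <- qs
          hr$strand <- "-"
          res[[length(res) + 1L]] <- hr
        }
      }
    }
  }
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res)) return(.emptyHits())
  res <- res[order(res$queryId, res$queryStart, res$subjectId), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read an alignment hit table (BLAST tabular dialect)
#'
#' Parses the 12-column tab-separated dialect (query, subject, %identity,
#' length, mismatches, gapopens, qstart, qend, sstart, send, evalue,
#' bitscore; 1-based inclusive coordinates). Coordinates are converted to
#' 0-based half-open; percent identity to a fraction; rows with
#' `qstart > qend` or `sstart > send` (minus strand) are normalised to
#' ascending intervals with `strand = "-"`.
#'
#' @param path file path.
#' @return Hits data.frame as produced by [seedExtendAlign()]; `matches`
#'   is reconstructed as `length - mismatches` (gapped external hits keep
#'   `alignedLength` from the file).
#' @export
readHitTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(.emptyHits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed hit-table row at line ", bad[1L], ": expected 12 ",
         "tab-separated fields, got ", lengths(parts)[bad[1L]])
  m <- do.call(rbind, parts)
  num <- function(j, line0 = TRUE) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("malformed hit-table row at line ", which(is.na(v))[1L],
           ": non-numeric field ", j)
    v
  }
  qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
  strand <- ifelse(qs > qe | ss > se, "-", "+")
  qlo <- pmin(qs, qe); qhi <- pmax(qs, qe)
  slo <- pmin(ss, se); shi <- pmax(ss, se)
  len <- as.integer(num(4))
  mism <- as.integer(num(5))
  ident <- num(3) / 100
  # ungapped rows: recover the exact match-count ratio (lossless round trip)
  exact <- abs(ident - (len - mism) / len) < 1e-6
  ident[exact] <- ((len - mism) / len)[exact]
  data.frame(queryId = m[, 1L], subjectId = m[, 2L],
             queryStart = as.integer(qlo) - 1L, queryEnd = as.integer(qhi),
             subjectStart = as.integer(slo) - 1L,
             subjectEnd = as.integer(shi),
             identity = ident, alignedLength = len,
             matches = len - mism, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write hits in the BLAST tabular dialect
#'
#' Inverse of [readHitTable()]: 1-based inclusive coordinates, percent
#' identity (printed at full precision so a round trip is lossless),
#' mismatches = alignedLength - matches, gapopens 0. Minus-strand hits are
#' written with descending subject coordinates. E-value is written as 0 and
#' bitscore as 2*matches (the native aligner computes no E-value
#' statistics).
#'
#' @param hits hits data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  ss <- ifelse(hits$strand == "-", hits$subjectEnd, hits$subjectStart + 1L)
  se <- ifelse(hits$strand == "-", hits$subjectStart + 1L, hits$subjectEnd)
  lines <- sprintf("%s\t%s\t%.10g\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g",
                   hits$queryId, hits$subjectId, hits$identity * 100,
                   hits$alignedLength,
                   hits$alignedLength - hits$matches, 0L,
                   hits$queryStart + 1L, hits$queryEnd,
                   ss, se, 0, 2 * hits$matches)
  writeLines(lines, path)
  invisible(path)
}
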