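# Internal sequence utilities. Sequences are plain upper-case character
# scalars over {A,C,G,T} (ambiguity codes tolerated only where stated);
# FASTA I/O goes through Biostrings.

.BASES <- c("A", "C", "G", "T")

# lookup: UTF-8 code -> 0..3, NA for anything else (incl. lower case is
# normalised by callers via toupper)
.BASE_CODE <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L
  v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L
  v[utf8ToInt("T")] <- 3L
  v
})

.seqToInt <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  .BASE_CODE[utf8ToInt(s)]
}

.intToSeq <- function(v) {
  intToUtf8(utf8ToInt("ACGT")[v + 1L])
}

.revComp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# Run expr with a locally-set RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' Generate a random genome sequence with a target GC content
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2 and P(A) = P(T) =
#' (1 - gc)/2, so the realised GC fraction concentrates around `gc` as
#' length grows.
#'
#' @param length genome length in bases (>= 1).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed; the result is a pure function of it.
#' @return A single character string over {A,C,G,T}.
#' @export
randomGenome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1, gc > 0, gc < 1)
  .withSeed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

# i.i.d. substitutions at per-site rate `rate`; a substituted site receives
# one of the three other bases uniformly. No indels.
.mutateSeq <- function(s, rate, seed) {
  stopifnot(rate >= 0, rate < 0.5)
  if (rate == 0) return(s)
  .withSeed(seed, {
    v <- .seqToInt(s)
    n <- length(v)
    hit <- which(stats::runif(n) < rate)
    if (length(hit)) {
      # uniform over the 3 non-identical bases via modular shift
      shift <- sample.int(3L, length(hit), replace = TRUE)
      v[hit] <- (v[hit] + shift) %% 4L
    }
    .intToSeq(v)
  })
}

#' Apply i.i.d. substitutions to a sequence at a fixed per-site rate
#'
#' Each site is substituted independently with probability `rate`, to one
#' of the three other bases uniformly; no indels. The workhorse behind
#' [evolveGenomeSet()], exposed for constructing ad-hoc diverged genomes.
#'
#' @param sequence character scalar over {A,C,G,T}.
#' @param rate per-site substitution probability in [0, 0.5).
#' @param seed integer seed.
#' @return The mutated sequence.
#' @export
mutateSequence <- function(sequence, rate, seed = 1L) {
  .mutateSeq(sequence, rate, seed)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector (upper case). Header text after the first whitespace is
#' preserved in the names so `cov=`/`src=` tokens survive a round trip.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path; lines wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
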