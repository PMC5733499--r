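#' Reverse complement of nucleotide sequences
#'
#' Vectorized reverse complement over the DNA alphabet `A,C,G,T,N`.
#' `N` maps to `N`. The operation is an involution: `revcomp(revcomp(x)) == x`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length, each element reverse
#'   complemented.
#' @examples
#' revcomp("ACGT")   # "ACGT" (palindrome)
#' revcomp("AAAC")   # "GTTT"
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  if (any(is.na(seq))) stop("revcomp: NA sequence")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("revcomp: non-ACGTN character in sequence ", which(bad)[1L])
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE), function(x) {
    paste(rev(x), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequences
#'
#' Uniform i.i.d. sequences over `A,C,G,T`, using the current RNG state.
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (scalar or vector of length `n`).
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b Character scalars (or equal-length vectors) of equal string
#'   length.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("hamming: length mismatch")
  mapply(function(x, y) {
    if (nchar(x) != nchar(y)) stop("hamming: sequences differ in length")
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Vectorized mismatch counts between string vectors `a` and `b` where within
# each call all strings of a pair have equal nchar (pairs may differ).
.mismatch_counts <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  lens <- nchar(a)
  if (any(lens != nchar(b))) stop("mismatch_counts: unequal pair lengths")
  for (L in unique(lens)) {
    i <- which(lens == L)
    A <- matrix(unlist(strsplit(a[i], "", fixed = TRUE), use.names = FALSE),
                nrow = L)
    B <- matrix(unlist(strsplit(b[i], "", fixed = TRUE), use.names = FALSE),
                nrow = L)
    out[i] <- colSums(A != B)
  }
  out
}

# Uniform per-base substitution errors at rate `rate`; keeps lengths.
.mutate_reads <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # substitute with one of the three other bases
    cur <- flat[hit]
    sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    flat[hit] <- sub
  }
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "", USE.NAMES = FALSE)
}
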