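#' k-mer composition of a nucleotide sequence
#'
#' Relative frequency of every length-`k` substring over all overlapping
#' (stride-1) windows, in lexicographic A < C < G < T index order, so `k = 4`
#' gives the standard 256-dimensional four-nucleotide composition. Counts are
#' normalized by the number of counted windows, so the entries sum to 1; a
#' sequence shorter than `k` (or with no window free of `N`) yields the
#' all-zero vector with a warning. Windows containing `N` (permissive
#' canonicalization) are dropped from both numerator and denominator.
#'
#' Reverse complements are *not* folded: `kmer_composition` of a sequence and
#' of its reverse complement generally differ.
#'
#' @param seq Canonical nucleotide sequence (A/C/G/T, optionally N).
#' @param k Window size (default 4).
#' @return Named numeric vector of length `4^k`.
#' @export
kmer_composition <- function(seq, k = 4L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  counts <- .kmer_counts(seq, k)
  total <- sum(counts)
  if (total == 0) {
    warning(sprintf("sequence of length %d has no valid window of size %d; returning zeros",
                    nchar(seq), k), call. = FALSE)
    return(counts * 0)
  }
  counts / total
}

.kmer_counts <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < k) {
    kmers <- Biostrings::mkAllStrings(NUC_ALPHABET, k)
    return(stats::setNames(numeric(4^k), kmers))
  }
  x <- Biostrings::DNAString(seq)
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
  stats::setNames(as.numeric(cnt), names(cnt))
}

#' Batch k-mer featurization
#'
#' @param seqs A record `data.frame` (`id`, `sequence`) as from [read_fasta()]
#'   or a character vector of canonical nucleotide sequences (optionally
#'   named).
#' @param k Window size (default 4).
#' @return Numeric matrix, one row per sequence in input order, `4^k` columns
#'   named by k-mer; rownames are the sequence ids when available.
#' @export
kmer_featurize <- function(seqs, k = 4L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    seqs <- seqs$sequence
  } else {
    ids <- names(seqs)
  }
  M <- t(vapply(seqs, function(s) suppressWarnings(kmer_composition(s, k)),
                numeric(4^k)))
  rownames(M) <- ids
  M
}
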