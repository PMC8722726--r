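## Small sequence utilities shared across modules.  Sequences are plain
## uppercase character strings over A,C,G,T,N; coordinates are 0-based
## half-open unless a function says otherwise.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` complements to `N`.
#'
#' @param x character vector of DNA sequences (A,C,G,T,N).
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("AACG") # "CGTT"
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

## substring with 0-based half-open coordinates
subseq0 <- function(s, start, end) substr(s, start + 1L, end)

## 0-based position -> 1-based printed position
pos1 <- function(p) as.integer(p) + 1L

## deterministic random DNA under the caller's RNG state
random_dna <- function(n, gc = 0.42) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

## first base in ACGT differing from every base in `avoid`
other_base <- function(avoid) {
  cand <- setdiff(c("A", "C", "G", "T"), avoid)
  cand[1]
}

assert_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(what, " must be a single character string", call. = FALSE)
  if (nchar(s) > 0 && grepl("[^ACGTN]", s))
    stop(what, " contains characters outside A,C,G,T,N", call. = FALSE)
  invisible(s)
}

## count exact occurrences of a k-mer on both strands of a set of contigs
count_occurrences <- function(kmer, contigs) {
  pat <- Biostrings::DNAString(kmer)
  n <- 0L
  for (s in contigs) {
    subj <- Biostrings::DNAString(s)
    n <- n + Biostrings::countPattern(pat, subj) +
      Biostrings::countPattern(Biostrings::reverseComplement(pat), subj)
  }
  n
}

## number of mismatching positions between two equal-length strings;
## 'N' mismatches everything
hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) stop("hamming: unequal lengths", call. = FALSE)
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(y, "", fixed = TRUE)[[1]]
  sum(a != b | a == "N" | b == "N")
}
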