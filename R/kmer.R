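#' Pack a 16-mer into its 32-bit integer code
#'
#' Encodes a 16-base DNA string into an integer in `[0, 2^32)` using 2 bits
#' per base (A=00, C=01, G=10, T=11, first base in the most significant bit
#' pair). The mapping is a bijection, and numeric order of codes coincides
#' with lexicographic order of 16-mers. Codes are returned as doubles
#' because R has no unsigned 32-bit integer; they are exact.
#'
#' @param seq character vector of 16-base A/C/G/T strings.
#' @return numeric vector of codes in `[0, 2^32)`.
#' @examples
#' encodeKmer("AAAAAAAAAAAAAAAT")  # 3
#' decodeKmer(encodeKmer("ACGTACGTACGTACGT"))
#' @seealso [decodeKmer()], [enumerateKmers()]
#' @export
encodeKmer <- function(seq) {
  vapply(as.character(seq), encode_kmer_cpp, numeric(1), USE.NAMES = FALSE)
}

#' Unpack a 32-bit integer code into its 16-mer
#'
#' Inverse of [encodeKmer()]: `decodeKmer(encodeKmer(s)) == s` for every
#' valid 16-mer `s`.
#'
#' @param code numeric vector of codes in `[0, 2^32)`.
#' @return character vector of 16-mers.
#' @export
decodeKmer <- function(code) {
  vapply(as.numeric(code), decode_kmer_cpp, character(1), USE.NAMES = FALSE)
}

#' Enumerate overlapping k-mer windows of a sequence
#'
#' Slides a window of width `k` with step 1 (so adjacent 16-mers overlap by
#' 15 bases) over the sequence and returns each window's 0-based start and
#' packed 2-bit code. Windows containing any non-ACGT character (e.g. N)
#' are skipped; the start position still advances by 1, so a clean sequence
#' of length L yields `L - k + 1` windows.
#'
#' @param seq a single sequence (character, `DNAString`, or 1-element set).
#' @param k window width (default 16, the host-exclusion unit).
#' @return a [S4Vectors::DataFrame] with columns `start` (0-based integer)
#'   and `code` (numeric).
#' @export
enumerateKmers <- function(seq, k = 16L) {
  s <- asResidues(seq)
  res <- enumerate_kmers_cpp(s, as.integer(k))
  S4Vectors::DataFrame(start = res$start, code = res$code)
}
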