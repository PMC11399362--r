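#' Build an exact-membership index over host 16-mers
#'
#' Enumerates every 16-mer of every host sequence (overlap 15, i.e. step 1)
#' and records its 2-bit-packed 32-bit code. With the default `"bitmap"`
#' backend the presence bits live in a fixed 2^32-bit bitmap: exactly
#' 536,870,912 bytes (512 MB), a size that does not change however many
#' sequences are indexed. The `"set"` backend keeps the sorted distinct
#' codes instead and answers membership identically; use it when the host
#' is small and the half-gigabyte allocation is unwanted.
#'
#' Windows containing non-ACGT characters (ambiguity codes such as N) are
#' skipped, so real transcriptome FASTA files are usable as-is. Only the
#' given (sense) strand is indexed.
#'
#' @param seqs host sequences: a `DNAStringSet` (e.g. from [readFasta()])
#'   or a character vector.
#' @param backend `"bitmap"` (default) or `"set"`.
#' @return a [HostIndex-class] object.
#' @examples
#' idx <- buildHostIndex(c(host1 = "ACGTACGTACGTACGTACGT"), backend = "set")
#' hostContains(idx, "ACGTACGTACGTACGT")
#' @export
buildHostIndex <- function(seqs, backend = c("bitmap", "set")) {
  backend <- match.arg(backend)
  residues <- asResidueSet(seqs)
  if (length(residues) == 0L)
    configError("at least one host sequence is required")
  if (backend == "bitmap") {
    bits <- raw(BITMAP_BYTES)
    nset <- 0
    for (s in residues) {
      codes <- enumerate_kmers_cpp(s, KMER_K)$code
      nset <- nset + bitmap_set_codes(bits, codes)
    }
    methods::new("HostIndex",
      k = KMER_K, backend = "bitmap", bits = bits, codes = numeric(0),
      nKmersSet = nset, nSequences = length(residues))
  } else {
    codes <- sort(unique(unlist(
      lapply(residues, function(s) enumerate_kmers_cpp(s, KMER_K)$code),
      use.names = FALSE
    )))
    methods::new("HostIndex",
      k = KMER_K, backend = "set", bits = raw(0), codes = as.numeric(codes),
      nKmersSet = length(codes), nSequences = length(residues))
  }
}

#' Add host sequences to an existing index
#'
#' Returns a new index whose k-mer set is the union of the old content and
#' the new sequences' 16-mers. Growth is monotone: no bit is ever cleared,
#' and for the bitmap backend the capacity (512 MB) is unchanged.
#'
#' @param index a [HostIndex-class].
#' @param seqs sequences to add (as in [buildHostIndex()]).
#' @return an updated [HostIndex-class].
#' @export
setMethod("addSequences", "HostIndex", function(index, seqs) {
  residues <- asResidueSet(seqs)
  if (length(residues) == 0L)
    configError("no sequences to add")
  if (index@backend == "bitmap") {
    bits <- bitmap_clone(index@bits)
    nset <- index@nKmersSet
    for (s in residues) {
      codes <- enumerate_kmers_cpp(s, KMER_K)$code
      nset <- nset + bitmap_set_codes(bits, codes)
    }
    methods::initialize(index, bits = bits, nKmersSet = nset,
                        nSequences = index@nSequences + length(residues))
  } else {
    codes <- sort(unique(c(index@codes, unlist(
      lapply(residues, function(s) enumerate_kmers_cpp(s, KMER_K)$code),
      use.names = FALSE
    ))))
    methods::initialize(index, codes = as.numeric(codes),
                        nKmersSet = length(codes),
                        nSequences = index@nSequences + length(residues))
  }
})

validateCodes <- function(codes) {
  codes <- as.numeric(codes)
  bad <- is.na(codes) | codes < 0 | codes >= 2^32 | codes != floor(codes)
  if (any(bad))
    inputError("k-mer codes must be integers in [0, 2^32)")
  codes
}

#' Query an index for 16-mer membership
#'
#' @param index a [HostIndex-class].
#' @param query either a numeric vector of codes in `[0, 2^32)` or a
#'   character vector of 16-mers (encoded with [encodeKmer()] first).
#' @return logical vector: `TRUE` where the 16-mer is present in the host.
#' @export
setMethod("hostContains", "HostIndex", function(index, query) {
  codes <- if (is.character(query)) encodeKmer(query) else validateCodes(query)
  if (index@backend == "bitmap") {
    bitmap_get_codes(index@bits, codes)
  } else {
    i <- findInterval(codes, index@codes)
    i > 0L & index@codes[pmax(i, 1L)] == codes
  }
})

## ---- persistence ------------------------------------------------------
## Layout: magic "ROAIDX" (6 bytes) | version (1) | k (1) |
##         n_sequences (4, LE) | n_kmers_set (8, LE) | body.
## version 1: body is the raw bitmap, bit j of byte i <-> code i*8 + j.
## version 2: body is n_kmers_set sorted 4-byte LE codes (set backend).

INDEX_MAGIC <- "ROAIDX"

uintToRaw <- function(x, width) {
  out <- integer(width)
  for (i in seq_len(width)) {
    out[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(out)
}

rawToUint <- function(r) {
  sum(as.numeric(r) * 256^(seq_along(r) - 1))
}

#' Save a host index to disk
#'
#' Writes a binary file: 6-byte magic `"ROAIDX"`, a 1-byte format version,
#' 1-byte k, 4-byte little-endian sequence count, 8-byte little-endian
#' distinct-k-mer count, then the body. For the bitmap backend (version 1)
#' the body is the raw 536,870,912-byte bitmap, bit `j` of byte `i` holding
#' code `i*8 + j`; round trips are bit-exact. The set backend is written as
#' version 2 (sorted 4-byte little-endian codes).
#'
#' @param index a [HostIndex-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [loadIndex()]
#' @export
setMethod("saveIndex", "HostIndex", function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  version <- if (index@backend == "bitmap") 1L else 2L
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(as.raw(c(version, index@k)), con)
  writeBin(uintToRaw(index@nSequences, 4L), con)
  writeBin(uintToRaw(index@nKmersSet, 8L), con)
  if (index@backend == "bitmap") {
    writeBin(index@bits, con)
  } else {
    writeBin(codes_to_raw_cpp(index@codes), con)
  }
  invisible(path)
})

#' Load a host index from disk
#'
#' @param path an index file written by [saveIndex()].
#' @return a [HostIndex-class].
#' @export
loadIndex <- function(path) {
  if (!file.exists(path)) inputError(sprintf("index file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 20L)
  if (length(header) < 20L)
    formatError("index file truncated: incomplete header")
  if (rawToChar(header[1:6]) != INDEX_MAGIC)
    formatError("not a host index file (bad magic)")
  version <- as.integer(header[7])
  if (!version %in% c(1L, 2L))
    formatError(sprintf("unsupported index format version %d", version))
  k <- as.integer(header[8])
  if (k != KMER_K)
    formatError(sprintf("unsupported k-mer length %d (expected 16)", k))
  nSeq <- rawToUint(header[9:12])
  nKmers <- rawToUint(header[13:20])
  if (version == 1L) {
    bits <- readBin(con, "raw", n = BITMAP_BYTES)
    if (length(bits) != BITMAP_BYTES)
      formatError("index file corrupt: bitmap body truncated")
    if (bitmap_popcount(bits) != nKmers)
      formatError("index file corrupt: popcount does not match header")
    methods::new("HostIndex", k = KMER_K, backend = "bitmap", bits = bits,
                 codes = numeric(0), nKmersSet = nKmers,
                 nSequences = as.integer(nSeq))
  } else {
    body <- readBin(con, "raw", n = nKmers * 4)
    if (length(body) != nKmers * 4)
      formatError("index file corrupt: code body truncated")
    codes <- raw_to_codes_cpp(body)
    if (is.unsorted(codes, strictly = TRUE))
      formatError("index file corrupt: codes not sorted")
    methods::new("HostIndex", k = KMER_K, backend = "set", bits = raw(0),
                 codes = codes, nKmersSet = nKmers,
                 nSequences = as.integer(nSeq))
  }
}

## ---- accessors --------------------------------------------------------

#' @describeIn HostIndex number of distinct 16-mers present.
#' @param x a `HostIndex`.
#' @export
setMethod("nKmersSet", "HostIndex", function(x) x@nKmersSet)

#' @describeIn HostIndex number of sequences indexed.
#' @export
setMethod("nSequences", "HostIndex", function(x) x@nSequences)

#' @describeIn HostIndex backend name, `"bitmap"` or `"set"`.
#' @export
setMethod("indexBackend", "HostIndex", function(x) x@backend)

#' @describeIn HostIndex bitmap capacity in bytes (0 for the set backend).
#' @export
setMethod("bitmapBytes", "HostIndex", function(x) length(x@bits))

setMethod("show", "HostIndex", function(object) {
  cat("HostIndex (", object@backend, " backend)\n", sep = "")
  cat("  k:           ", object@k, "\n", sep = "")
  cat("  sequences:   ", object@nSequences, "\n", sep = "")
  cat("  16-mers set: ", format(object@nKmersSet, big.mark = ","), "\n", sep = "")
  if (object@backend == "bitmap")
    cat("  capacity:    ", length(object@bits), " bytes (",
        length(object@bits) / 2^20, " MB)\n", sep = "")
})
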