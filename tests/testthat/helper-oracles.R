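# Independent brute-force oracles used to cross-check the implementation.
# They work purely on strings and never touch the package's encoding or
# bitmap machinery.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(len, gc = 0.5) {
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomKmers <- function(n, k = 16) {
  vapply(seq_len(n), function(i) randomSeq(k), character(1))
}

# Digit-accumulation encoding oracle: value = value*4 + code(base).
oracleEncode <- function(s) {
  codes <- c(A = 0, C = 1, G = 2, T = 3)
  Reduce(function(v, b) v * 4 + codes[[b]], strsplit(s, "")[[1]], accumulate = FALSE, init = 0)
}

# All clean k-mer windows of a sequence: 0-based starts and strings.
oracleWindows <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(data.frame(start = integer(0), kmer = character(0)))
  starts <- 0:(L - k)
  kmers <- substring(s, starts + 1, starts + k)
  clean <- !grepl("[^ACGT]", kmers)
  data.frame(start = starts[clean], kmer = kmers[clean],
             stringsAsFactors = FALSE)
}

# The set of 16-mer strings occurring in any of the sequences.
oracleKmerSet <- function(seqs, k = 16) {
  unique(unlist(lapply(seqs, function(s) oracleWindows(s, k)$kmer),
                use.names = FALSE))
}

oracleHostClean <- function(kset, seq20) {
  subs <- substring(seq20, 1:5, 16:20)
  !any(subs %in% kset)
}

oracleJunctionClean <- function(kset, left, right, mode) {
  joined <- paste0(left, right)
  starts <- if (mode == "all") 5:19 else 12
  !any(substring(joined, starts + 1, starts + 16) %in% kset)
}

# Exhaustive 4-subset search for the even-site selection objective:
# lexicographically minimal (d1, s1, d2, s2, d3, s3, d4, s4) over ascending
# non-overlapping 4-subsets with all four junctions (incl. wrap-around)
# clean by string search.
oracleSelect <- function(sites, targetLength, kset, mode) {
  anchors <- ((0:3) + 0.5) / 4 * targetLength
  n <- nrow(sites)
  best <- NULL
  bestKey <- NULL
  for (combo in utils::combn(n, 4, simplify = FALSE)) {
    st <- sites$start[combo]
    if (any(diff(st) < 20)) next
    sq <- sites$sequence[combo]
    pairsOk <- all(vapply(1:4, function(i) {
      j <- if (i == 4) 1 else i + 1
      oracleJunctionClean(kset, sq[i], sq[j], mode)
    }, logical(1)))
    if (!pairsOk) next
    d <- abs(st + 10 - anchors)
    key <- as.vector(rbind(d, st))
    if (is.null(bestKey) || isTRUE(keyLess(key, bestKey))) {
      best <- combo
      bestKey <- key
    }
  }
  best
}

keyLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}
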