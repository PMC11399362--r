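#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# Fixed parameters of the indexing scheme: 16-mers packed 2 bits/base into a
# 32-bit code; one presence bit per possible code.
KMER_K <- 16L
BITMAP_BYTES <- 2^32 / 8  # 536,870,912

#' HostIndex: exact-membership index over host 16-mers
#'
#' An exact-membership structure answering "does this 16-mer occur anywhere
#' in the indexed host sequences". The default `"bitmap"` backend holds one
#' presence bit for each of the \eqn{2^{32}} possible 2-bit-packed 16-mer
#' codes, so it occupies exactly 536,870,912 bytes (512 MB) no matter how
#' many sequences are indexed. The `"set"` backend stores the sorted distinct
#' codes instead; it answers membership identically and is convenient for
#' small hosts, but its size grows with content.
#'
#' @slot k k-mer length; always 16.
#' @slot backend `"bitmap"` or `"set"`.
#' @slot bits raw presence bitmap (bit `j` of byte `i` is code `i*8 + j`);
#'   length 0 for the set backend.
#' @slot codes sorted distinct k-mer codes (set backend); length 0 for bitmap.
#' @slot nKmersSet number of distinct 16-mer codes present.
#' @slot nSequences number of sequences indexed.
#'
#' @seealso [buildHostIndex()], [hostContains()], [saveIndex()]
#' @export
setClass("HostIndex",
  slots = c(
    k = "integer",
    backend = "character",
    bits = "raw",
    codes = "numeric",
    nKmersSet = "numeric",
    nSequences = "integer"
  )
)

setValidity("HostIndex", function(object) {
  msg <- character()
  if (!identical(object@k, KMER_K))
    msg <- c(msg, "k must be 16")
  if (!object@backend %in% c("bitmap", "set"))
    msg <- c(msg, "backend must be 'bitmap' or 'set'")
  if (object@backend == "bitmap") {
    if (length(object@bits) != BITMAP_BYTES)
      msg <- c(msg, sprintf("bitmap must be exactly %.0f bytes", BITMAP_BYTES))
    if (length(object@codes) != 0)
      msg <- c(msg, "bitmap backend must not carry a code set")
  } else {
    if (length(object@bits) != 0)
      msg <- c(msg, "set backend must not carry a bitmap")
    if (is.unsorted(object@codes, strictly = TRUE) && length(object@codes) > 1)
      msg <- c(msg, "codes must be strictly sorted (distinct)")
    if (length(object@codes) && (min(object@codes) < 0 || max(object@codes) >= 2^32))
      msg <- c(msg, "codes must lie in [0, 2^32)")
    if (object@nKmersSet != length(object@codes))
      msg <- c(msg, "nKmersSet must equal the number of stored codes")
  }
  if (object@nSequences < 0L)
    msg <- c(msg, "nSequences must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FilterConfig: tunable thresholds for candidate screening
#'
#' Holds every tunable threshold applied to candidate 20-mer sites and
#' junctions. Construct with [filterConfig()], which documents the defaults.
#'
#' @slot gcMin,gcMax allowed GC fraction range (0..1).
#' @slot tmMethod `"gc_adjusted"` or `"wallace"`.
#' @slot tmMin,tmMax allowed annealing temperature range (degrees Celsius).
#' @slot maxHomopolymerRun longest allowed single-base run.
#' @slot requireStrong3Prime require a G/C clamp at the 3' terminal base.
#' @slot junctionMode `"all"` (check all 15 junction-spanning 16-mers) or
#'   `"center"` (check only the centred 8+8 16-mer).
#' @export
setClass("FilterConfig",
  slots = c(
    gcMin = "numeric", gcMax = "numeric",
    tmMethod = "character",
    tmMin = "numeric", tmMax = "numeric",
    maxHomopolymerRun = "integer",
    requireStrong3Prime = "logical",
    junctionMode = "character"
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (!(object@gcMin >= 0 && object@gcMin <= object@gcMax && object@gcMax <= 1))
    msg <- c(msg, "need 0 <= gcMin <= gcMax <= 1")
  if (!object@tmMethod %in% c("gc_adjusted", "wallace"))
    msg <- c(msg, "tmMethod must be 'gc_adjusted' or 'wallace'")
  if (object@tmMin > object@tmMax)
    msg <- c(msg, "need tmMin <= tmMax")
  if (object@maxHomopolymerRun < 1L)
    msg <- c(msg, "maxHomopolymerRun must be >= 1")
  if (!object@junctionMode %in% c("all", "center"))
    msg <- c(msg, "junctionMode must be 'all' or 'center'")
  if (length(msg)) msg else TRUE
})

#' ProbeDesign: a completed four-arm circular probe
#'
#' The result of a successful design: four non-overlapping 20-mer target
#' sites in ascending genomic order, the 80-nt probe sequence (their
#' concatenation), its reverse complement (the strand to synthesise and
#' ligate, since it is the one that hybridises the target), the four per-arm
#' reverse complements, and the four validated junctions (three internal
#' plus the wrap-around closing the circle).
#'
#' @slot targetId identifier of the target sequence.
#' @slot targetLength length of the target in nt.
#' @slot sites a [S4Vectors::DataFrame] of the 4 selected sites (columns
#'   `target_id`, `start`, `end`, `sequence`, `gc`, `tm`, `max_run`);
#'   0-based half-open coordinates.
#' @slot probeSeq 80-nt target-sense probe sequence.
#' @slot probeRevcomp reverse complement of `probeSeq`.
#' @slot armRevcomps reverse complements of the four arm sequences.
#' @slot junctions DataFrame of junction checks (columns `left_start`,
#'   `right_start`, `mode`, `n_checked`, `clean`).
#' @export
setClass("ProbeDesign",
  slots = c(
    targetId = "character",
    targetLength = "integer",
    sites = "DataFrame",
    probeSeq = "character",
    probeRevcomp = "character",
    armRevcomps = "character",
    junctions = "DataFrame"
  )
)

setValidity("ProbeDesign", function(object) {
  msg <- character()
  if (nrow(object@sites) != 4L)
    msg <- c(msg, "a design has exactly 4 sites")
  if (nchar(object@probeSeq) != 80L)
    msg <- c(msg, "probe sequence must be 80 nt (4 x 20)")
  if (!identical(revComp(object@probeRevcomp), object@probeSeq))
    msg <- c(msg, "probeRevcomp must be the reverse complement of probeSeq")
  if (length(object@armRevcomps) != 4L)
    msg <- c(msg, "need 4 arm reverse complements")
  st <- object@sites$start
  if (nrow(object@sites) == 4L && any(diff(st) < 20L))
    msg <- c(msg, "sites must be ascending and non-overlapping (start gap >= 20)")
  if (nrow(object@junctions) != 4L)
    msg <- c(msg, "a circular design has 4 junctions (3 internal + wrap-around)")
  if (nrow(object@junctions) == 4L && !all(object@junctions$clean))
    msg <- c(msg, "all junctions must be clean")
  if (length(msg)) msg else TRUE
})
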