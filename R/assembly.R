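#' Reverse complement of DNA sequences
#'
#' Standard Watson-Crick reverse complement (an involution:
#' `revComp(revComp(s)) == s`). U is accepted and treated as T.
#'
#' @param seq character vector of A/C/G/T(/U) strings.
#' @return character vector of reverse complements.
#' @export
revComp <- function(seq) {
  seq <- chartr("U", "T", toupper(as.character(seq)))
  if (any(grepl("[^ACGT]", seq)))
    inputError("reverse complement requires A/C/G/T sequences")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Junction 16-mer starts within the 40-nt head-to-tail concatenation:
# "all" checks every 16-mer spanning the boundary at offset 20 (starts
# 5..19); "center" checks only the centred 8+8 16-mer (start 12).
junctionStarts <- function(mode) {
  if (mode == "all") 5:19 else 12L
}

#' Validate the head-to-tail junction between two 20-mers
#'
#' Joining two 20-mers head-to-tail creates new 16-mers spanning the
#' boundary that exist in neither site alone; if such a 16-mer occurs in
#' the host, the joining order is invalid. In mode `"all"` every 16-mer of
#' the 40-nt concatenation that crosses the boundary is checked (15 codes,
#' starts 5..19); in mode `"center"` only the 16-mer centred on the
#' boundary (8 bases each side, start 12).
#'
#' @param index a [HostIndex-class].
#' @param left,right the two 20-mer sequences (character), in joining
#'   order.
#' @param mode `"all"` (default, conservative superset) or `"center"`.
#' @param leftStart,rightStart optional 0-based site offsets recorded in
#'   the result.
#' @return a list with elements `left_start`, `right_start`, `mode`,
#'   `checked_starts`, `checked_codes`, and `clean` (`TRUE` iff no checked
#'   16-mer is present in the host).
#' @export
junctionClean <- function(index, left, right, mode = c("all", "center"),
                          leftStart = NA_integer_, rightStart = NA_integer_) {
  mode <- match.arg(mode)
  left <- asResidues(left); right <- asResidues(right)
  if (nchar(left) != 20L || nchar(right) != 20L)
    inputError("junction validation expects two 20-mers")
  joined <- paste0(left, right)
  starts <- junctionStarts(mode)
  codes <- vapply(starts, function(s) encode_kmer_cpp(substr(joined, s + 1L, s + 16L)),
                  numeric(1))
  list(left_start = leftStart, right_start = rightStart, mode = mode,
       checked_starts = as.integer(starts), checked_codes = codes,
       clean = !any(hostContains(index, codes)))
}

# DFS over per-anchor ranked sites; returns row indices of the first
# (lexicographically best) feasible 4-assignment, or NULL.
evenSiteSearch <- function(index, sites, targetLength, mode) {
  anchors <- ((0:3) + 0.5) / 4 * targetLength
  centers <- sites$start + 10
  ranks <- lapply(anchors, function(a) order(abs(centers - a), sites$start))
  seqs <- sites$sequence
  starts <- sites$start
  jClean <- function(i, j) {
    junctionClean(index, seqs[i], seqs[j], mode)$clean
  }
  recurse <- function(level, chosen) {
    for (j in ranks[[level]]) {
      if (level > 1L) {
        prev <- chosen[level - 1L]
        if (starts[j] < starts[prev] + 20L) next
        if (!jClean(prev, j)) next
      }
      if (level == 4L) {
        if (!jClean(j, chosen[1L])) next  # wrap-around closes the circle
        return(c(chosen, j))
      }
      res <- recurse(level + 1L, c(chosen, j))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recurse(1L, integer(0))
}

#' Select four evenly distributed sites and assemble the probe
#'
#' Places four ideal anchor points at the quartile centres of the target
#' (`(i + 0.5)/4 * L` for `i = 0..3`) and, for each anchor, ranks the valid
#' sites by distance from site centre to anchor (leftmost start breaking
#' ties). A deterministic depth-first search over these rankings — requiring
#' ascending starts, pairwise non-overlap (start gap >= 20) and a clean
#' junction at every join, including the wrap-around from the fourth site
#' back to the first — returns the first complete assignment, i.e. the
#' lexicographically best feasible distance vector.
#'
#' @param index a [HostIndex-class].
#' @param sites valid candidate sites (e.g. from [filterCandidates()]),
#'   sorted by start.
#' @param targetLength length of the target sequence in nt.
#' @param mode junction mode, `"all"` or `"center"`.
#' @return a [ProbeDesign-class].
#' @export
selectEvenSites <- function(index, sites, targetLength,
                            mode = c("all", "center")) {
  mode <- match.arg(mode)
  if (nrow(sites) < 4L)
    designFailure(sprintf(
      "only %d valid candidate site(s); four non-overlapping sites are required",
      nrow(sites)))
  pick <- evenSiteSearch(index, sites, targetLength, mode)
  if (is.null(pick))
    designFailure(paste(
      "no combination of four non-overlapping valid sites has four clean",
      "junctions (including the wrap-around)"))
  assembleProbe(index, sites[pick, , drop = FALSE], mode = mode,
                targetLength = as.integer(targetLength))
}

#' Assemble a circular probe from four validated sites
#'
#' Concatenates the four 20-mers in genomic order into the 80-nt probe
#' (within the 80-100 nt window that single-stranded circularisation
#' ligases accept), re-validates all four junctions against the host index
#' (assembly is refused if any junction 16-mer is present), and generates
#' the probe reverse complement plus the four per-arm reverse complements.
#'
#' @param index a [HostIndex-class].
#' @param sites a 4-row site table (columns as from [filterCandidates()])
#'   in ascending start order.
#' @param mode junction mode.
#' @param targetLength target length in nt (recorded in the design).
#' @return a [ProbeDesign-class].
#' @export
assembleProbe <- function(index, sites, mode = c("all", "center"),
                          targetLength = NA_integer_) {
  mode <- match.arg(mode)
  if (nrow(sites) != 4L)
    inputError("probe assembly requires exactly 4 sites")
  if (any(diff(sites$start) < 20L))
    inputError("sites must be in ascending order and non-overlapping")
  pairs <- cbind(1:4, c(2:4, 1L))  # 3 internal joins + wrap-around
  checks <- lapply(seq_len(4L), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    junctionClean(index, sites$sequence[i], sites$sequence[j], mode,
                  leftStart = sites$start[i], rightStart = sites$start[j])
  })
  if (!all(vapply(checks, `[[`, logical(1), "clean")))
    designFailure("assembly refused: a junction 16-mer is present in the host")
  junctions <- S4Vectors::DataFrame(
    left_start = vapply(checks, `[[`, integer(1), "left_start"),
    right_start = vapply(checks, `[[`, integer(1), "right_start"),
    mode = rep(mode, 4L),
    n_checked = vapply(checks, function(x) length(x$checked_codes), integer(1)),
    clean = vapply(checks, `[[`, logical(1), "clean"))
  probeSeq <- paste(sites$sequence, collapse = "")
  methods::new("ProbeDesign",
    targetId = as.character(sites$target_id[1L]),
    targetLength = as.integer(targetLength),
    sites = sites,
    probeSeq = probeSeq,
    probeRevcomp = revComp(probeSeq),
    armRevcomps = revComp(sites$sequence),
    junctions = junctions)
}

#' Design a circular probe for a target against a host index
#'
#' The full pipeline: enumerate target 20-mers, drop every 20-mer any of
#' whose five constituent 16-mers occurs in the host, apply the
#' composition filters, select four evenly distributed sites with clean
#' head-to-tail junctions, and assemble the 80-nt circular probe with its
#' reverse-complement outputs.
#'
#' @param index a [HostIndex-class] over the host transcriptome.
#' @param target the target (e.g. viral) mRNA sequence.
#' @param cfg a [FilterConfig-class].
#' @param targetId identifier recorded in the design.
#' @return a [ProbeDesign-class]; signals a design-failure error (condition
#'   class `"circProbe_design_failure"`) when fewer than four compatible
#'   sites exist.
#' @examples
#' fx <- generateFixturePair(hostLength = 2000, targetLength = 400, seed = 7)
#' idx <- buildHostIndex(fx$host, backend = "set")
#' pd <- designProbe(idx, fx$target)
#' probeSequence(pd)
#' @export
designProbe <- function(index, target, cfg = filterConfig(), targetId = NULL) {
  valid <- filterCandidates(index, target, cfg, targetId)
  selectEvenSites(index, valid, nchar(asResidues(target)),
                  mode = cfg@junctionMode)
}

#' Convert a mass concentration of an oligonucleotide to molarity
#'
#' Converts micrograms per millilitre to picomoles per microlitre using the
#' average nucleotide molecular weight of 330 pg/pmol:
#' `conc / 1000 * 1/330 * 1e6 / nNt`.
#'
#' @param concUgPerMl concentration in micrograms per millilitre (>= 0).
#' @param nNt number of nucleotides in the molecule (>= 1).
#' @return pmol per microlitre.
#' @examples
#' molesPerMicroliter(3.3, 100)  # 0.1 pmol/uL
#' @export
molesPerMicroliter <- function(concUgPerMl, nNt) {
  if (any(is.na(concUgPerMl)) || any(concUgPerMl < 0))
    inputError("concentration must be >= 0")
  if (any(is.na(nNt)) || any(nNt < 1))
    inputError("nucleotide count must be >= 1")
  (concUgPerMl / 1000) * (1 / 330) * 1e6 / nNt
}

## ---- ProbeDesign accessors -------------------------------------------

#' @describeIn ProbeDesign the 80-nt target-sense probe sequence.
#' @param x a `ProbeDesign`.
#' @export
setMethod("probeSequence", "ProbeDesign", function(x) x@probeSeq)

#' @describeIn ProbeDesign reverse complement of the probe (the strand to
#'   synthesise and ligate).
#' @export
setMethod("probeRevcomp", "ProbeDesign", function(x) x@probeRevcomp)

#' @describeIn ProbeDesign the four arm (site) sequences, genomic order.
#' @export
setMethod("armSequences", "ProbeDesign", function(x) x@sites$sequence)

#' @describeIn ProbeDesign reverse complements of the four arms.
#' @export
setMethod("armRevcomps", "ProbeDesign", function(x) x@armRevcomps)

#' @describeIn ProbeDesign the selected site table.
#' @export
setMethod("probeSites", "ProbeDesign", function(x) x@sites)

#' @describeIn ProbeDesign the junction-check table (3 internal +
#'   wrap-around).
#' @export
setMethod("probeJunctions", "ProbeDesign", function(x) x@junctions)

setMethod("show", "ProbeDesign", function(object) {
  cat("ProbeDesign for '", object@targetId, "' (", object@targetLength,
      " nt target)\n", sep = "")
  cat("  arms (0-based [start, end)):\n")
  for (i in seq_len(4L)) {
    cat(sprintf("    arm_%d  [%4d, %4d)  %s  gc=%.2f tm=%.1f\n",
                i, object@sites$start[i], object@sites$end[i],
                object@sites$sequence[i], object@sites$gc[i],
                object@sites$tm[i]))
  }
  cat("  probe (80 nt):  ", object@probeSeq, "\n", sep = "")
  cat("  probe revcomp:  ", object@probeRevcomp, "\n", sep = "")
  cat("  junctions clean: ", all(object@junctions$clean),
      " (mode ", object@junctions$mode[1L], ")\n", sep = "")
})
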