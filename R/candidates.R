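#' Construct a filter configuration
#'
#' Defaults: GC fraction in \[0.40, 0.60\]; annealing temperature by the
#' GC-adjusted formula `64.9 + 41 * (nGC - 16.4) / N` constrained to
#' \[50, 65\] degrees C (bracketing the 57-60 degrees C working temperature of the
#' isothermal reaction; the Wallace rule `2*(nA+nT) + 4*(nG+nC)` is the
#' alternative); homopolymer runs capped at 4; a G/C clamp required at the
#' 3' terminal base; junction mode `"all"` (check all 15 16-mers spanning a
#' head-to-tail junction, the conservative superset of the single centred
#' 16-mer that `"center"` checks).
#'
#' @param gcMin,gcMax allowed GC fraction range.
#' @param tmMethod `"gc_adjusted"` or `"wallace"`.
#' @param tmMin,tmMax allowed annealing temperature range (degrees C).
#' @param maxHomopolymerRun longest allowed single-base run.
#' @param requireStrong3Prime require G or C at the 3' end.
#' @param junctionMode `"all"` or `"center"`.
#' @return a [FilterConfig-class].
#' @export
filterConfig <- function(gcMin = 0.40, gcMax = 0.60,
                         tmMethod = c("gc_adjusted", "wallace"),
                         tmMin = 50, tmMax = 65,
                         maxHomopolymerRun = 4L,
                         requireStrong3Prime = TRUE,
                         junctionMode = c("all", "center")) {
  tmMethod <- match.arg(tmMethod)
  junctionMode <- match.arg(junctionMode)
  methods::new("FilterConfig",
    gcMin = as.numeric(gcMin), gcMax = as.numeric(gcMax),
    tmMethod = tmMethod,
    tmMin = as.numeric(tmMin), tmMax = as.numeric(tmMax),
    maxHomopolymerRun = as.integer(maxHomopolymerRun),
    requireStrong3Prime = isTRUE(requireStrong3Prime),
    junctionMode = junctionMode)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  GC fraction:     [%.2f, %.2f]\n", object@gcMin, object@gcMax))
  cat(sprintf("  Tm (%s): [%.1f, %.1f] C\n", object@tmMethod,
              object@tmMin, object@tmMax))
  cat(sprintf("  max homopolymer: %d\n", object@maxHomopolymerRun))
  cat(sprintf("  3' G/C clamp:    %s\n", object@requireStrong3Prime))
  cat(sprintf("  junction mode:   %s\n", object@junctionMode))
})

#' GC fraction of a sequence
#'
#' @param seq character vector of non-empty A/C/G/T strings.
#' @return numeric vector: `(#G + #C) / length`.
#' @export
gcFraction <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (any(n == 0L)) inputError("cannot compute GC fraction of an empty sequence")
  nchar(gsub("[^GC]", "", seq)) / n
}

#' Oligo annealing temperature
#'
#' Two standard short-oligo estimates: `"gc_adjusted"` is
#' `64.9 + 41 * (nGC - 16.4) / N`; `"wallace"` is the Wallace rule
#' `2 * (nA + nT) + 4 * (nG + nC)` (degrees Celsius).
#'
#' @param seq character vector of non-empty A/C/G/T strings.
#' @param method `"gc_adjusted"` (default) or `"wallace"`.
#' @return numeric vector of temperatures in degrees Celsius.
#' @export
meltingTemperature <- function(seq, method = c("gc_adjusted", "wallace")) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("gc_adjusted", "wallace"))
    configError(sprintf("unknown Tm method '%s'", method))
  method <- match.arg(method)
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (any(n == 0L)) inputError("cannot compute Tm of an empty sequence")
  ngc <- nchar(gsub("[^GC]", "", seq))
  if (method == "gc_adjusted") {
    64.9 + 41 * (ngc - 16.4) / n
  } else {
    2 * (n - ngc) + 4 * ngc
  }
}

#' Longest homopolymer run
#'
#' @param seq character vector of non-empty strings.
#' @return integer vector: length of the longest run of one repeated base.
#' @export
maxHomopolymerRun <- function(seq) {
  seq <- as.character(seq)
  if (any(nchar(seq) == 0L)) inputError("empty sequence")
  max_run_cpp(seq)
}

# The five constituent 16-mers of a 20-mer (starts 0..4), as codes.
subKmerCodes <- function(seq20) {
  vapply(0:4, function(s) encode_kmer_cpp(substr(seq20, s + 1L, s + 16L)),
         numeric(1))
}

#' Host-exclusion test for one 20-mer
#'
#' Decomposes a 20-mer into its five constituent 16-mers (starts 0..4) and
#' checks each against the host index; the site is host-clean only if none
#' of the five is present. A 16-mer shared with the host at target position
#' `p` therefore invalidates exactly the 20-mer starts in `[p-4, p]`.
#'
#' @param index a [HostIndex-class].
#' @param seq a 20-base A/C/G/T string.
#' @return `TRUE` if no constituent 16-mer occurs in the host.
#' @export
isHostClean <- function(index, seq) {
  seq <- asResidues(seq)
  if (nchar(seq) != 20L) inputError("host-exclusion screening expects a 20-mer")
  !any(hostContains(index, subKmerCodes(seq)))
}

#' Enumerate candidate 20-mer sites of a target
#'
#' Cuts the target into 20-mers with an overlap of 19 bases (step 1): one
#' candidate per 0-based start in `[0, L-20]`, skipping windows that
#' contain non-ACGT characters. Each candidate is annotated with GC
#' fraction, annealing temperature (method from `cfg`) and longest
#' homopolymer run.
#'
#' @param target a single sequence of length >= 20.
#' @param cfg a [FilterConfig-class] (controls the Tm method).
#' @param targetId identifier recorded per site; defaults to the sequence
#'   name, else `"target"`.
#' @return a [S4Vectors::DataFrame] with columns `target_id`, `start`,
#'   `end` (0-based half-open), `sequence`, `gc`, `tm`, `max_run`.
#' @export
enumerateCandidates <- function(target, cfg = filterConfig(), targetId = NULL) {
  if (is.null(targetId)) {
    nm <- if (methods::is(target, "XStringSet")) names(target) else names(target)
    targetId <- if (length(nm) && nzchar(nm[1L])) nm[1L] else "target"
  }
  s <- asResidues(target)
  L <- nchar(s)
  if (L < 20L)
    inputError(sprintf("target '%s' is shorter than 20 nt (%d)", targetId, L))
  win <- enumerate_kmers_cpp(s, 20L)
  starts <- win$start
  seqs <- substring(s, starts + 1L, starts + 20L)
  S4Vectors::DataFrame(
    target_id = rep(targetId, length(starts)),
    start = starts,
    end = starts + 20L,
    sequence = seqs,
    gc = gcFraction(seqs),
    tm = meltingTemperature(seqs, cfg@tmMethod),
    max_run = maxHomopolymerRun(seqs)
  )
}

# Vectorised composition check; returns pass flag and comma-separated
# failed-check names ("gc", "tm", "homopolymer", "3prime") per sequence.
compositionFlags <- function(gc, tm, maxRun, seqs, cfg) {
  failGc <- gc < cfg@gcMin | gc > cfg@gcMax
  failTm <- tm < cfg@tmMin | tm > cfg@tmMax
  failRun <- maxRun > cfg@maxHomopolymerRun
  fail3p <- if (cfg@requireStrong3Prime) {
    !substr(seqs, nchar(seqs), nchar(seqs)) %in% c("G", "C")
  } else rep(FALSE, length(seqs))
  reasons <- mapply(function(a, b, c, d) {
    paste(c("gc", "tm", "homopolymer", "3prime")[c(a, b, c, d)], collapse = ",")
  }, failGc, failTm, failRun, fail3p, USE.NAMES = FALSE)
  list(pass = !(failGc | failTm | failRun | fail3p), reasons = reasons)
}

#' Composition check for one candidate 20-mer
#'
#' @param seq a 20-base A/C/G/T string.
#' @param cfg a [FilterConfig-class].
#' @return `TRUE` if GC, Tm, homopolymer and 3'-end checks all pass; the
#'   names of failed checks are attached as attribute `"fail_reasons"`.
#' @export
passesComposition <- function(seq, cfg = filterConfig()) {
  seq <- asResidues(seq)
  flags <- compositionFlags(gcFraction(seq),
                            meltingTemperature(seq, cfg@tmMethod),
                            maxHomopolymerRun(seq), seq, cfg)
  structure(flags$pass, fail_reasons = flags$reasons)
}

#' Screen all candidate sites of a target against a host index
#'
#' Runs the full candidate stage: enumerate 20-mers, apply the
#' five-16-mer host-exclusion test, and apply the composition checks.
#' Returns every window with its verdicts, for reporting; use
#' [filterCandidates()] for just the survivors.
#'
#' @inheritParams enumerateCandidates
#' @param index a [HostIndex-class] built from the host transcriptome.
#' @return a [S4Vectors::DataFrame]: the columns of [enumerateCandidates()]
#'   plus `host_clean`, `composition_pass`, `fail_reasons`.
#' @export
screenCandidates <- function(index, target, cfg = filterConfig(),
                             targetId = NULL) {
  cand <- enumerateCandidates(target, cfg, targetId)
  s <- asResidues(target)
  # membership of every valid 16-mer window of the target, by start
  k16 <- enumerate_kmers_cpp(s, 16L)
  present <- logical(nchar(s))  # FALSE where window invalid/absent
  present[k16$start + 1L] <- as.logical(hostContains(index, k16$code))
  hostClean <- vapply(cand$start, function(st) {
    !any(present[st + 1:5])
  }, logical(1))
  flags <- compositionFlags(cand$gc, cand$tm, cand$max_run, cand$sequence, cfg)
  reasons <- flags$reasons
  reasons <- ifelse(hostClean, reasons,
                    ifelse(nzchar(reasons), paste0("host,", reasons), "host"))
  cand$host_clean <- hostClean
  cand$composition_pass <- flags$pass
  cand$fail_reasons <- reasons
  cand
}

#' Valid candidate sites of a target
#'
#' The candidates that survive both the host-exclusion and the composition
#' filters, ordered by start. Zero survivors is not an error at this stage;
#' [designProbe()] reports it as a design failure.
#'
#' @inheritParams screenCandidates
#' @return a [S4Vectors::DataFrame] of surviving sites.
#' @export
filterCandidates <- function(index, target, cfg = filterConfig(),
                             targetId = NULL) {
  cand <- screenCandidates(index, target, cfg, targetId)
  cand[cand$host_clean & cand$composition_pass, , drop = FALSE]
}
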