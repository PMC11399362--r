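# Condition helpers: distinct classes so callers (and the CLI) can separate
# bad input / bad configuration from a genuine design failure.
circStop <- function(msg, class) {
  cond <- structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

inputError <- function(msg) circStop(msg, "circProbe_input_error")
configError <- function(msg) circStop(msg, "circProbe_config_error")
formatError <- function(msg) circStop(msg, c("circProbe_format_error", "circProbe_input_error"))
designFailure <- function(msg) circStop(msg, "circProbe_design_failure")

# Normalise residues the way FASTA ingest does: upper case, U -> T.
# Other letters (IUPAC ambiguity codes such as N) are retained; windows
# containing them are skipped downstream rather than erroring.
normalizeResidues <- function(x) {
  chartr("U", "T", toupper(x))
}

# Coerce a sequence argument (character, DNAString/BString, or a
# single-element XStringSet) to one normalised character string.
asResidues <- function(seq) {
  if (methods::is(seq, "XStringSet")) {
    if (length(seq) != 1L)
      inputError("expected a single sequence, got a set of length != 1")
    seq <- as.character(seq[[1L]])
  } else if (methods::is(seq, "XString")) {
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    inputError("sequence must be a single character string")
  normalizeResidues(seq)
}

# Coerce a collection of sequences to a named character vector.
asResidueSet <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    out <- normalizeResidues(as.character(seqs))
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out), recycle0 = TRUE)
    return(out)
  }
  if (methods::is(seqs, "XString")) seqs <- as.character(seqs)
  if (!is.character(seqs)) inputError("sequences must be character or XStringSet")
  out <- normalizeResidues(seqs)
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out), recycle0 = TRUE)
  out
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
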