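#' Read sequences from a FASTA file
#'
#' Multi-record FASTA ingest with the normalisation the design pipeline
#' expects: residues are upper-cased and U is mapped to T (one DNA alphabet
#' for RNA and DNA inputs); IUPAC ambiguity codes such as N are retained,
#' and windows containing them are skipped during k-mer enumeration rather
#' than raising an error. Record order is preserved; names are the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) inputError(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) formatError(sprintf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e))))
  if (length(seqs) == 0L)
    inputError(sprintf("FASTA file '%s' contains no records", path))
  residues <- normalizeResidues(as.character(seqs))
  ids <- sub("\\s.*$", "", names(seqs))
  out <- tryCatch(
    Biostrings::DNAStringSet(residues),
    error = function(e) formatError(sprintf(
      "FASTA '%s' contains non-nucleotide characters: %s",
      path, conditionMessage(e))))
  names(out) <- ids
  out
}

writeFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a completed probe design to FASTA and TSV
#'
#' The FASTA holds records `probe`, `probe_revcomp`, `arm_1..4` and
#' `arm_revcomp_1..4`. The TSV design report has one row per arm with its
#' 0-based half-open target coordinates, sequence, reverse complement,
#' composition metrics, and the result of the junction check to the next
#' arm (the fourth row's junction is the wrap-around back to arm 1).
#' Rewriting the same design is byte-identical.
#'
#' @param design a [ProbeDesign-class].
#' @param fastaPath,tsvPath output paths.
#' @return invisibly, a list of the two paths.
#' @export
writeDesign <- function(design, fastaPath, tsvPath) {
  arms <- armSequences(design)
  recs <- c(
    probe = probeSequence(design),
    probe_revcomp = probeRevcomp(design),
    stats::setNames(arms, paste0("arm_", 1:4)),
    stats::setNames(armRevcomps(design), paste0("arm_revcomp_", 1:4)))
  writeFasta(recs, fastaPath)
  st <- probeSites(design)
  jn <- probeJunctions(design)
  tab <- data.frame(
    arm = paste0("arm_", 1:4),
    target_id = as.character(st$target_id),
    start = st$start,
    end = st$end,
    sequence = st$sequence,
    revcomp = armRevcomps(design),
    gc = sprintf("%.4f", st$gc),
    tm = sprintf("%.2f", st$tm),
    max_run = st$max_run,
    junction_mode = jn$mode,
    junction_n_checked = jn$n_checked,
    junction_to_next_clean = jn$clean,
    stringsAsFactors = FALSE)
  utils::write.table(tab, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(list(fasta = fastaPath, tsv = tsvPath))
}

#' Write the candidate screening report
#'
#' One row per enumerated 20-mer window with its metrics and verdicts,
#' including the comma-separated names of failed checks (`host`, `gc`,
#' `tm`, `homopolymer`, `3prime`). Coordinates are 0-based half-open.
#'
#' @param candidates table from [screenCandidates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCandidateReport <- function(candidates, path) {
  tab <- as.data.frame(candidates)
  tab$gc <- sprintf("%.4f", tab$gc)
  tab$tm <- sprintf("%.2f", tab$tm)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

CONFIG_KEYS <- c(gc_min = "gcMin", gc_max = "gcMax", tm_method = "tmMethod",
                 tm_min = "tmMin", tm_max = "tmMax",
                 max_homopolymer_run = "maxHomopolymerRun",
                 require_strong_3prime = "requireStrong3Prime",
                 junction_mode = "junctionMode")

applyConfigOverrides <- function(cfg, overrides) {
  unknown <- setdiff(names(overrides), names(CONFIG_KEYS))
  if (length(unknown))
    configError(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  args <- list(gcMin = cfg@gcMin, gcMax = cfg@gcMax, tmMethod = cfg@tmMethod,
               tmMin = cfg@tmMin, tmMax = cfg@tmMax,
               maxHomopolymerRun = cfg@maxHomopolymerRun,
               requireStrong3Prime = cfg@requireStrong3Prime,
               junctionMode = cfg@junctionMode)
  for (key in names(overrides)) args[[CONFIG_KEYS[[key]]]] <- overrides[[key]]
  tryCatch(do.call(filterConfig, args),
           error = function(e) configError(conditionMessage(e)))
}

#' Read filter thresholds from a YAML config file
#'
#' Flat keys mirroring [filterConfig()]: `gc_min`, `gc_max`, `tm_method`,
#' `tm_min`, `tm_max`, `max_homopolymer_run`, `require_strong_3prime`,
#' `junction_mode`. Unknown keys are rejected. Values not present keep the
#' defaults of `base`.
#'
#' @param path YAML file path.
#' @param base the configuration to override (default [filterConfig()]).
#' @return a [FilterConfig-class].
#' @export
readFilterConfigFile <- function(path, base = filterConfig()) {
  if (!file.exists(path)) inputError(sprintf("config file not found: %s", path))
  overrides <- tryCatch(yaml::read_yaml(path),
                        error = function(e) formatError(sprintf(
                          "malformed YAML '%s': %s", path,
                          conditionMessage(e))))
  if (is.null(overrides)) return(base)
  if (!is.list(overrides)) configError("config must be a YAML mapping")
  applyConfigOverrides(base, overrides)
}
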