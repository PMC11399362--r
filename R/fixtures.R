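#' Generate a seeded host/target sequence pair with planted shared 16-mers
#'
#' Emulates the inputs of the design workflow — a host transcriptome
#' sequence and a target (e.g. viral) mRNA — with fully known ground truth:
#' both sequences are i.i.d. random bases at the requested GC bias, except
#' that `nPlanted` 16-mers copied verbatim from random host positions are
#' spliced into the target at recorded, non-overlapping positions. Planted
#' positions are kept at least 36 nt apart (16-mer length plus the 20-mer
#' window) so each plant's rejection window `[p-4, p]` is disjoint and no
#' candidate 20-mer overlaps two plants. Output is byte-identical for
#' identical arguments and independent of the caller's RNG state.
#'
#' @param hostLength,targetLength sequence lengths in nt (>= 20). Defaults
#'   (10 kb host, 1 kb target) give hundreds of candidate windows while
#'   keeping brute-force verification fast.
#' @param nPlanted number of host 16-mers copied into the target.
#' @param gcBias GC fraction of the random background (default 0.5).
#' @param seed RNG seed; fixtures are reproducible given the seed.
#' @return a list with `host` and `target` (named character vectors) and
#'   `truth`: a list recording the arguments plus `plantedPositions`
#'   (0-based target offsets), `plantedHostPositions` and `plantedKmers`.
#' @export
generateFixturePair <- function(hostLength = 10000L, targetLength = 1000L,
                                nPlanted = 0L, gcBias = 0.5, seed = 1L) {
  hostLength <- as.integer(hostLength); targetLength <- as.integer(targetLength)
  nPlanted <- as.integer(nPlanted)
  if (hostLength < 20L || targetLength < 20L)
    inputError("fixture sequences must be at least 20 nt")
  if (gcBias < 0 || gcBias > 1) inputError("gcBias must be in [0, 1]")
  if (nPlanted < 0L) inputError("nPlanted must be >= 0")
  if (nPlanted > 0L && (nPlanted - 1L) * 36L + 16L > targetLength)
    inputError(sprintf(
      "cannot place %d plants >= 36 nt apart in a %d nt target",
      nPlanted, targetLength))
  prob <- c((1 - gcBias) / 2, gcBias / 2, gcBias / 2, (1 - gcBias) / 2)
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    host <- paste(sample(bases, hostLength, replace = TRUE, prob = prob),
                  collapse = "")
    target <- paste(sample(bases, targetLength, replace = TRUE, prob = prob),
                    collapse = "")
    plantedPositions <- integer(0)
    plantedHostPositions <- integer(0)
    plantedKmers <- character(0)
    if (nPlanted > 0L) {
      ok <- FALSE
      for (attempt in seq_len(10000L)) {
        pos <- sort(sample.int(targetLength - 16L + 1L, nPlanted) - 1L)
        if (nPlanted == 1L || all(diff(pos) >= 36L)) { ok <- TRUE; break }
      }
      if (!ok)
        inputError("could not place plants >= 36 nt apart; reduce nPlanted")
      plantedPositions <- pos
      plantedHostPositions <-
        sort(sample.int(hostLength - 16L + 1L, nPlanted) - 1L)
      plantedKmers <- substring(host, plantedHostPositions + 1L,
                                plantedHostPositions + 16L)
      for (i in seq_len(nPlanted)) {
        substr(target, plantedPositions[i] + 1L,
               plantedPositions[i] + 16L) <- plantedKmers[i]
      }
    }
    list(
      host = c(host = host),
      target = c(target = target),
      truth = list(
        hostLength = hostLength, targetLength = targetLength,
        nPlanted = nPlanted, gcBias = gcBias, seed = as.integer(seed),
        plantedPositions = plantedPositions,
        plantedHostPositions = plantedHostPositions,
        plantedKmers = plantedKmers)
    )
  })
}

# 20-mer starts whose window contains a 16-mer planted at p: [p-4, p],
# clipped to the valid start range [0, L-20].
plantRejectionStarts <- function(p, targetLength) {
  seq.int(max(p - 4L, 0L), min(p, targetLength - 20L))
}

#' Score screened candidates against fixture ground truth
#'
#' Compares the host-exclusion verdicts of screened candidates with the
#' rejection windows implied by the planted 16-mers: a plant at target
#' position `p` should invalidate exactly the 20-mer starts in
#' `[p-4, p]`. By soundness of the exact index, `falsely_retained` (a
#' window overlapping a plant that was nevertheless called host-clean)
#' must always be 0; `falsely_rejected` counts windows rejected without an
#' overlapping plant, which can only arise from incidental random 16-mer
#' sharing between the generated sequences.
#'
#' @param truth the `truth` element of [generateFixturePair()].
#' @param candidates the table from [screenCandidates()] for the generated
#'   pair (must carry `host_clean`).
#' @return named integer vector with elements `correctly_rejected`,
#'   `falsely_rejected`, `correctly_retained`, `falsely_retained`.
#' @export
truthEval <- function(truth, candidates) {
  if (is.null(candidates$host_clean))
    inputError("candidates must carry a host_clean column (use screenCandidates)")
  expected <- unique(unlist(lapply(truth$plantedPositions,
                                   plantRejectionStarts,
                                   targetLength = truth$targetLength)))
  inWindow <- candidates$start %in% expected
  rejected <- !candidates$host_clean
  c(correctly_rejected = sum(rejected & inWindow),
    falsely_rejected = sum(rejected & !inWindow),
    correctly_retained = sum(!rejected & !inWindow),
    falsely_retained = sum(!rejected & inWindow))
}
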