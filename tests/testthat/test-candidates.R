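test_that("candidate enumeration uses 19-base overlap and skips dirty windows", {
  set.seed(101)
  cfg <- filterConfig()
  expect_equal(nrow(enumerateCandidates(randomSeq(20), cfg)), 1L)
  cand <- enumerateCandidates(randomSeq(100), cfg)
  expect_equal(nrow(cand), 81L)  # 100 - 20 + 1
  expect_identical(cand$start, 0:80)
  expect_identical(cand$end, cand$start + 20L)
  expect_true(all(nchar(cand$sequence) == 20L))

  # one N at position 20 (0-based) of a 40-nt target: window starts 1..20
  # all touch it; brute force gives the same survivors
  s <- randomSeq(40)
  substr(s, 21, 21) <- "N"
  cand <- enumerateCandidates(s, cfg)
  ref <- oracleWindows(s, 20)
  expect_identical(cand$start, ref$start)
  expect_identical(cand$sequence, ref$kmer)
  expect_identical(cand$start, 0L)

  expect_error(enumerateCandidates(randomSeq(19), cfg), "shorter than 20")
})

test_that("composition metrics match their closed forms", {
  expect_equal(gcFraction(strrep("AT", 10)), 0)
  expect_equal(gcFraction(strrep("GC", 10)), 1)
  s <- paste0(strrep("AG", 10))  # 10 G, 10 A
  expect_equal(gcFraction(s), 0.5)
  expect_equal(meltingTemperature(s, "gc_adjusted"), 64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(meltingTemperature(s, "gc_adjusted"), 51.78)
  expect_equal(meltingTemperature(s, "wallace"), 2 * 10 + 4 * 10)
  expect_equal(meltingTemperature(strrep("AT", 10), "wallace"), 40)
  expect_error(meltingTemperature(s, "nearest_neighbor"), "unknown Tm method")
  expect_error(gcFraction(""), "empty")

  expect_equal(maxHomopolymerRun("ACGT"), 1L)
  expect_equal(maxHomopolymerRun("AAAAG"), 4L)
  expect_equal(maxHomopolymerRun("GATTTTTACA"), 5L)
  # linear-scan oracle on random strings
  set.seed(102)
  for (s in replicate(20, randomSeq(50))) {
    r <- rle(strsplit(s, "")[[1]])
    expect_equal(maxHomopolymerRun(s), max(r$lengths))
  }
})

test_that("composition filter applies GC, Tm, homopolymer and 3'-clamp rules", {
  cfg <- filterConfig()
  good <- "ATCGTACGATCGTACGATCG"  # gc 0.5, tm 51.78, run 1, ends G
  expect_true(passesComposition(good, cfg))
  expect_identical(attr(passesComposition(good, cfg), "fail_reasons"), "")

  poly <- "ATCGTACGATAAAAAAGTCG"  # 6-base homopolymer
  res <- passesComposition(poly, cfg)
  expect_false(as.logical(res))
  expect_match(attr(res, "fail_reasons"), "homopolymer")

  lowgc <- "ATATATACGATATACGGTCG"  # gc 0.35 < 0.40
  expect_equal(gcFraction(lowgc), 0.35)
  res <- passesComposition(lowgc, cfg)
  expect_false(as.logical(res))
  expect_match(attr(res, "fail_reasons"), "gc")

  endsA <- "ATCGTACGATCGTACGGTCA"
  res <- passesComposition(endsA, cfg)
  expect_false(as.logical(res))
  expect_match(attr(res, "fail_reasons"), "3prime")
  relaxed <- filterConfig(requireStrong3Prime = FALSE)
  expect_true(passesComposition(endsA, relaxed))
})

test_that("host-exclusion screens each 20-mer through its five 16-mers", {
  set.seed(111)
  host <- randomSeq(500)
  idx <- buildHostIndex(c(h = host), backend = "set")
  empty <- buildHostIndex(c(e = strrep("A", 16)), backend = "set")

  expect_true(isHostClean(empty, "ACGTACGTACGTACGTACGT"))

  # a 20-mer lifted straight from the host: all five 16-mers present
  inside <- substr(host, 101, 120)
  expect_false(isHostClean(idx, inside))

  # a 20-mer sharing only its central 16-mer (offset 2) with the host
  core <- substr(host, 201, 216)
  probe <- paste0("CA", core, "AC")
  madeClean <- function(s) !any(substring(s, 1:5, 16:20) %in% oracleKmerSet(host))
  expect_false(isHostClean(idx, probe))
  expect_identical(isHostClean(idx, probe), madeClean(probe))

  expect_length(circProbe:::subKmerCodes(probe), 5L)
})

test_that("planted shared 16-mers invalidate exactly the starts in [p-4, p]", {
  fx <- generateFixturePair(hostLength = 3000, targetLength = 600,
                            nPlanted = 3, seed = 123)
  idx <- buildHostIndex(fx$host, backend = "set")
  scr <- screenCandidates(idx, fx$target)
  kset <- oracleKmerSet(fx$host)

  # survivor set matches the brute-force string oracle
  oracle <- vapply(scr$sequence, oracleHostClean, logical(1),
                   kset = kset, USE.NAMES = FALSE)
  expect_identical(scr$host_clean, oracle)

  # every rejected start is within [p-4, p] of a plant unless explained by
  # an incidental real shared 16-mer (which the oracle check above catches)
  expected <- unlist(lapply(fx$truth$plantedPositions, function(p) {
    seq.int(max(p - 4L, 0L), min(p, fx$truth$targetLength - 20L))
  }))
  expect_true(all(expected %in% scr$start[!scr$host_clean]))
})

test_that("no returned candidate shares any 16-mer with the host (soundness)", {
  fx <- generateFixturePair(hostLength = 2000, targetLength = 500,
                            nPlanted = 2, seed = 131)
  idx <- buildHostIndex(fx$host, backend = "set")
  valid <- filterCandidates(idx, fx$target)
  kset <- oracleKmerSet(fx$host)
  for (s in valid$sequence) {
    expect_false(any(substring(s, 1:5, 16:20) %in% kset))
  }
  expect_false(is.unsorted(valid$start))
})

test_that("widening thresholds never removes a valid candidate; runs are deterministic", {
  fx <- generateFixturePair(hostLength = 2000, targetLength = 500,
                            nPlanted = 1, seed = 141)
  idx <- buildHostIndex(fx$host, backend = "set")
  base <- filterCandidates(idx, fx$target, filterConfig())
  wide <- filterCandidates(idx, fx$target, filterConfig(
    gcMin = 0.30, gcMax = 0.70, tmMin = 40, tmMax = 75,
    maxHomopolymerRun = 6L, requireStrong3Prime = FALSE))
  expect_true(all(base$start %in% wide$start))
  expect_gte(nrow(wide), nrow(base))

  again <- filterCandidates(idx, fx$target, filterConfig())
  expect_identical(as.data.frame(base), as.data.frame(again))

  # target identical to an indexed host sequence -> nothing survives
  self <- filterCandidates(idx, fx$host, filterConfig())
  expect_equal(nrow(self), 0L)
})
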