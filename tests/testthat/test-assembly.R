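test_that("reverse complement is the Watson-Crick involution", {
  expect_identical(revComp("ACGT"), "ACGT")  # palindrome
  expect_identical(revComp("AAAA"), "TTTT")
  expect_identical(revComp("AACGTT"), "AACGTT")
  expect_error(revComp("ACGX"), "A/C/G/T")
  set.seed(201)
  for (s in replicate(100, randomSeq(sample(1:60, 1)))) {
    expect_identical(revComp(revComp(s)), s)
  }
})

test_that("junction validation checks the 16-mers spanning the head-to-tail boundary", {
  set.seed(211)
  left <- randomSeq(20); right <- randomSeq(20)
  empty <- buildHostIndex(c(e = strrep("A", 16)), backend = "set")
  expect_true(junctionClean(empty, left, right, "all")$clean)
  expect_true(junctionClean(empty, left, right, "center")$clean)

  joined <- paste0(left, right)
  # host containing the centred 8+8 straddling 16-mer: dirty in both modes
  straddle <- substr(joined, 13, 28)
  idx <- buildHostIndex(c(h = straddle), backend = "set")
  expect_false(junctionClean(idx, left, right, "all")$clean)
  expect_false(junctionClean(idx, left, right, "center")$clean)

  # host 16-mer at concatenation offset 6: dirty in "all", clean in "center"
  side <- substr(joined, 7, 22)
  idx <- buildHostIndex(c(h = side), backend = "set")
  jAll <- junctionClean(idx, left, right, "all")
  jCen <- junctionClean(idx, left, right, "center")
  expect_false(jAll$clean)
  expect_true(jCen$clean)

  # structural contract: 15 spanning codes (starts 5..19) vs 1 (start 12)
  expect_length(jAll$checked_codes, 15L)
  expect_identical(jAll$checked_starts, 5:19)
  expect_length(jCen$checked_codes, 1L)
  expect_identical(jCen$checked_starts, 12L)

  # decisions agree with the string-set oracle for random hosts
  host <- randomSeq(3000)
  idx <- buildHostIndex(c(h = host), backend = "set")
  kset <- oracleKmerSet(host)
  for (i in 1:25) {
    l <- randomSeq(20); r <- randomSeq(20)
    for (mode in c("all", "center")) {
      expect_identical(junctionClean(idx, l, r, mode)$clean,
                       oracleJunctionClean(kset, l, r, mode))
    }
  }
})

test_that("site selection needs four compatible sites and honours anchors", {
  fx <- generateFixturePair(hostLength = 2000, targetLength = 400, seed = 221)
  idx <- buildHostIndex(fx$host, backend = "set")
  valid <- filterCandidates(idx, fx$target)
  expect_gte(nrow(valid), 4L)

  # exactly 4 well-separated sites with clean junctions -> those 4 chosen
  four <- valid[c(1L, which(valid$start >= valid$start[1L] + 20L)[1L],
                  which(valid$start >= 200L)[1L],
                  which(valid$start >= 300L)[1L]), , drop = FALSE]
  pd <- selectEvenSites(idx, four, 400)
  expect_identical(probeSites(pd)$start, four$start)

  expect_error(selectEvenSites(idx, four[1:3, ], 400),
               class = "circProbe_design_failure")
  expect_error(selectEvenSites(idx, four[0, ], 400),
               class = "circProbe_design_failure")
})

test_that("selection equals the exhaustive lexicographic-distance oracle", {
  for (seed in c(231, 232, 233)) {
    fx <- generateFixturePair(hostLength = 2000, targetLength = 400,
                              seed = seed)
    idx <- buildHostIndex(fx$host, backend = "set")
    valid <- filterCandidates(idx, fx$target)
    # at most 12 sites, spread across the target
    keep <- unique(round(seq(1, nrow(valid), length.out = min(12, nrow(valid)))))
    sites <- valid[keep, , drop = FALSE]
    pd <- selectEvenSites(idx, sites, 400)
    ref <- oracleSelect(as.data.frame(sites), 400, oracleKmerSet(fx$host), "all")
    expect_identical(probeSites(pd)$start, sites$start[ref])
  }
})

test_that("assembled probes have 4 arms, 80 nt, matching revcomps and clean junctions", {
  fx <- generateFixturePair(hostLength = 3000, targetLength = 500,
                            nPlanted = 2, seed = 241)
  idx <- buildHostIndex(fx$host, backend = "set")
  pd <- designProbe(idx, fx$target)

  sites <- probeSites(pd)
  expect_equal(nrow(sites), 4L)
  expect_equal(nchar(probeSequence(pd)), 80L)
  expect_true(nchar(probeSequence(pd)) >= 80 && nchar(probeSequence(pd)) <= 100)
  expect_identical(probeSequence(pd),
                   paste(sites$sequence, collapse = ""))
  expect_identical(revComp(probeRevcomp(pd)), probeSequence(pd))
  expect_identical(armRevcomps(pd), revComp(sites$sequence))
  # the probe revcomp read 5'->3' contains the arm revcomps in reverse order
  expect_identical(probeRevcomp(pd),
                   paste(rev(armRevcomps(pd)), collapse = ""))
  expect_true(all(diff(sites$start) >= 20L))

  jn <- probeJunctions(pd)
  expect_equal(nrow(jn), 4L)  # 3 internal + wrap-around
  expect_true(all(jn$clean))
  expect_identical(jn$left_start, sites$start[c(1, 2, 3, 4)])
  expect_identical(jn$right_start, sites$start[c(2, 3, 4, 1)])

  # no 16-mer inside an arm or spanning a checked junction occurs in the host
  kset <- oracleKmerSet(fx$host)
  probeKmers <- substring(probeSequence(pd), 1:65, 16:80)
  expect_false(any(probeKmers %in% kset))
})

test_that("assembly is refused when a junction 16-mer occurs in the host", {
  fx <- generateFixturePair(hostLength = 2000, targetLength = 400, seed = 251)
  idx <- buildHostIndex(fx$host, backend = "set")
  valid <- filterCandidates(idx, fx$target)
  pd <- designProbe(idx, fx$target)
  sites <- probeSites(pd)
  # poison the host with the 16-mer straddling the first junction
  joined <- paste0(sites$sequence[1], sites$sequence[2])
  poisoned <- addSequences(idx, c(p = substr(joined, 13, 28)))
  expect_error(assembleProbe(poisoned, sites),
               class = "circProbe_design_failure")
  expect_error(assembleProbe(idx, sites[c(2, 1, 3, 4), ]), "ascending")
})

test_that("mass-to-moles conversion follows the 330 pg/pmol rule and inverts", {
  expect_equal(molesPerMicroliter(0, 100), 0)
  expect_equal(molesPerMicroliter(3.3, 100), 0.1)
  set.seed(261)
  conc <- runif(500, 0, 1000)
  n <- sample(20:10000, 500, replace = TRUE)
  v <- molesPerMicroliter(conc, n)
  expect_equal(v * n * 330 * 1000 / 1e6, conc, tolerance = 1e-12)
  expect_error(molesPerMicroliter(1, 0), "nucleotide count")
  expect_error(molesPerMicroliter(-1, 10), ">= 0")
})
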