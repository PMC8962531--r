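test_that("exon padding is strand-aware and merges overlaps", {
  # a plus-strand exon spanning 0-based [1000,1100) is GRanges 1001..1100;
  # padded -15 upstream / +6 downstream it becomes [985,1106) = 986..1106
  plus <- TranscriptModel("G1", "region", "+",
                          IRanges::IRanges(1001, 1100))
  pp <- padExons(plus)
  expect_equal(GenomicRanges::start(pp), 986)
  expect_equal(GenomicRanges::end(pp), 1106)

  minus <- TranscriptModel("G1", "region", "-",
                           IRanges::IRanges(1001, 1100))
  pm <- padExons(minus)
  expect_equal(GenomicRanges::start(pm), 995)
  expect_equal(GenomicRanges::end(pm), 1115)

  two <- TranscriptModel("G1", "region", "+",
                         IRanges::IRanges(c(101, 140), c(120, 160)))
  merged <- padExons(two)
  expect_length(merged, 1)
  expect_equal(GenomicRanges::start(merged), 86)
  expect_equal(GenomicRanges::end(merged), 166)

  nearZero <- TranscriptModel("G1", "region", "+",
                              IRanges::IRanges(5, 30))
  expect_equal(GenomicRanges::start(padExons(nearZero)), 1)
})

test_that("site augmentation adds only uncovered sites as single bases", {
  base <- GenomicRanges::GRanges("region", IRanges::IRanges(100, 200))
  inside <- addSites(base, plpSites = 150)
  expect_equal(sum(GenomicRanges::width(inside)), 101)

  outside <- addSites(base, plpSites = 500)
  expect_equal(sum(GenomicRanges::width(outside)), 102)
  added <- outside[outside$annotation == "plp_site"]
  expect_equal(GenomicRanges::start(added), 500)
  expect_equal(GenomicRanges::width(added), 1)

  sites43 <- seq(1000, by = 10, length.out = 43)
  aug <- addSites(base, pgxSites = sites43)
  expect_equal(sum(GenomicRanges::width(aug)), 101 + 43)
})

test_that("exclusion scanning finds GC windows, homopolymers and micro-repeats", {
  set.seed(12)
  frag <- generateReferenceFragment(
    1200, gcTarget = 0.30,
    homopolymerInserts = list(list(base = "A", runLength = 12,
                                   position = 150),
                              list(base = "T", runLength = 9,
                                   position = 400)),
    repeatInserts = list(list(unit = "AT", nUnits = 10, position = 600),
                         list(unit = "AT", nUnits = 5, position = 800),
                         list(unit = "G", nUnits = 120, position = 1000)),
    seed = 7)
  ex <- scanExclusions(frag, exclusionConfig())
  mask <- grToMask(ex, 1200)
  # 12-base homopolymer excluded, 9-base kept
  expect_true(all(mask[150:161]))
  expect_false(any(mask[400:408]))
  # AT x10 excluded, AT x5 kept (background AT-rich noise aside, the exact
  # 5-unit tract must not be excluded by the repeat rule alone unless the
  # flanks happen to extend it; check the pure windows)
  expect_true(all(mask[600:619]))
  # 120 G bases: both a homopolymer and a >75% GC window
  expect_true(all(mask[1000:1119]))
  expect_true(any(ex$rule == "high_gc"))
})

test_that("exclusion scanning equals the brute-force per-position oracle", {
  set.seed(13)
  frag <- generateReferenceFragment(
    2000, gcTarget = 0.55,
    homopolymerInserts = list(list(base = "C", runLength = 15,
                                   position = 300)),
    repeatInserts = list(list(unit = "TA", nUnits = 8, position = 700),
                         list(unit = "CAG", nUnits = 7, position = 1200)),
    seed = 8)
  chars <- strsplit(as.character(frag), "")[[1]]
  cfg <- exclusionConfig(gcThreshold = 0.75, gcWindow = 100,
                         homopolymerMinRun = 10,
                         microrepeatUnits = c(2, 3),
                         microrepeatMinUnits = 6)
  got <- grToMask(scanExclusions(frag, cfg), 2000)
  want <- oracleGCScan(chars, 100, 0.75) |
    oracleRepeatScan(chars, 10, c(2, 3), 6)
  expect_equal(got, want)
})

test_that("named exclusions pass through the scanner", {
  frag <- generateReferenceFragment(500, gcTarget = 0.5, seed = 9)
  named <- GenomicRanges::GRanges("region", IRanges::IRanges(50, 80))
  ex <- scanExclusions(frag, exclusionConfig(namedExclusions = named))
  expect_true(any(ex$rule == "named" &
                  GenomicRanges::start(ex) == 50 &
                  GenomicRanges::end(ex) == 80))
  expect_error(scanExclusions(Biostrings::DNAString("ACGT"),
                              exclusionConfig(gcWindow = 100)),
               "longer than the reference")
})

test_that("coverage flagging equals per-position fraction counting", {
  set.seed(14)
  m <- matrix(rpois(300 * 10, 35), nrow = 300)
  m[40:60, 1:3] <- 4        # 30% of samples low: flagged
  m[100:110, 1:2] <- 4      # exactly 20%: flagged (rule is >=)
  m[200:210, 1] <- 4        # 10%: not flagged by the pocket alone
  flags <- coverageFlag(m, 20, 0.20)
  want <- rowMeans(m < 20) >= 0.20
  expect_equal(grToMask(flags, 300), want)
  expect_true(all(grToMask(flags, 300)[40:60]))
  expect_true(all(grToMask(flags, 300)[100:110]))
  expect_error(coverageFlag(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("the builder reproduces a hand-computed toy-gene BED", {
  # toy gene, plus strand, two exons at 1-based 201..260 and 401..460 on an
  # alternating-AT background (0% GC) with a 100-base G block at 431..530.
  # padded exons: 186..266 and 386..466. One P/LP site at 600 (outside).
  # GC rule (>75% over 100 bp, step 1): a window starting at s holds
  # overlap(s) G bases and zero flanking GC, so windows s in [407,455] pass
  # and the exclusion mask is exactly [407,554].
  # hand-computed result: [186,266], [386,406], [600,600]
  chars <- rep(c("A", "T"), 400)
  chars[431:530] <- "G"
  frag <- Biostrings::DNAString(paste(chars, collapse = ""))
  tx <- TranscriptModel("TOY", "region", "+",
                        IRanges::IRanges(c(201, 401), c(260, 460)))
  rr <- buildReportableRange(list(tx), plpSites = 600, reference = frag,
                             config = exclusionConfig(homopolymerMinRun = 200,
                                                      microrepeatMinUnits = 500))
  got <- rangeIntervals(rr)
  expect_equal(GenomicRanges::start(got), c(186, 386, 600))
  expect_equal(GenomicRanges::end(got), c(266, 406, 600))
  expect_equal(got$annotation, c("exon_padded", "exon_padded", "plp_site"))
  expect_equal(totalBases(rr), 81 + 21 + 1)
  # totalBases equals an independent per-position membership count
  expect_equal(totalBases(rr), sum(grToMask(got, 800)))
})

test_that("builder without exclusions or sites returns merged padded exons", {
  tx <- TranscriptModel("TOY", "region", "+",
                        IRanges::IRanges(c(100, 130), c(120, 150)))
  rr <- buildReportableRange(list(tx))
  expect_length(rangeIntervals(rr), 1)
  expect_equal(GenomicRanges::start(rangeIntervals(rr)), 85)
  expect_equal(GenomicRanges::end(rangeIntervals(rr)), 156)
})

test_that("rebuilding from its own output with zero pads is a fixpoint", {
  frag <- generateReferenceFragment(
    800, gcTarget = 0.35,
    repeatInserts = list(list(unit = "G", nUnits = 100, position = 431)),
    seed = 15)
  tx <- TranscriptModel("TOY", "region", "+",
                        IRanges::IRanges(c(201, 401), c(260, 460)))
  cfg <- exclusionConfig(homopolymerMinRun = 200, microrepeatMinUnits = 500)
  rr <- buildReportableRange(list(tx), reference = frag, config = cfg)
  asTx <- TranscriptModel("TOY", "region", "+",
                          IRanges::ranges(rangeIntervals(rr)))
  rr2 <- buildReportableRange(list(asTx), reference = frag, config = cfg,
                              upstreamPad = 0, downstreamPad = 0)
  expect_equal(IRanges::ranges(rangeIntervals(rr2)),
               IRanges::ranges(rangeIntervals(rr)))
})

test_that("sites inside exclusions surface as conflicts, not silently kept", {
  frag <- generateReferenceFragment(
    600, gcTarget = 0.35,
    repeatInserts = list(list(unit = "G", nUnits = 100, position = 301)),
    seed = 16)
  tx <- TranscriptModel("TOY", "region", "+", IRanges::IRanges(50, 80))
  rr <- buildReportableRange(list(tx), plpSites = 350, reference = frag,
                             config = exclusionConfig(homopolymerMinRun = 200,
                                                      microrepeatMinUnits = 500))
  expect_equal(nrow(rangeConflicts(rr)), 1)
  expect_equal(rangeConflicts(rr)$pos, 350)
  # the conflicted site is not in the final range
  expect_false(any(GenomicRanges::start(rangeIntervals(rr)) == 350))
})

test_that("strand reflection mirrors the padded range", {
  L <- 1000L
  tx <- TranscriptModel("TOY", "region", "+",
                        IRanges::IRanges(c(201, 401), c(260, 460)))
  fwd <- padExons(tx)
  # reflect: exon [s,e] maps to [L-e+1, L-s+1] on the minus strand
  refl <- TranscriptModel("TOY", "region", "-",
                          IRanges::IRanges(L - c(460, 260) + 1,
                                           L - c(401, 201) + 1))
  rev <- padExons(refl)
  expect_equal(sort(L - GenomicRanges::end(rev) + 1),
               sort(GenomicRanges::start(fwd)))
  expect_equal(sort(L - GenomicRanges::start(rev) + 1),
               sort(GenomicRanges::end(fwd)))
})
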