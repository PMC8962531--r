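test_that("normalization leaves SNVs alone and decomposes substitutions", {
  refChars <- c("G", "G", "A", "C", "G", "G")
  ref <- paste(refChars, collapse = "")
  snv <- data.frame(chrom = "r", pos = 3L, ref = "A", alt = "G",
                    genotype = "het", stringsAsFactors = FALSE)
  expect_equal(normalizeVariants(snv, ref), snv)

  mnv <- data.frame(chrom = "r", pos = 3L, ref = "AC", alt = "GT",
                    genotype = "hom_alt", stringsAsFactors = FALSE)
  out <- normalizeVariants(mnv, ref)
  expect_equal(out$pos, c(3L, 4L))
  expect_equal(out$ref, c("A", "C"))
  expect_equal(out$alt, c("G", "T"))
  expect_true(all(out$genotype == "hom_alt"))
})

test_that("equivalent indel representations normalize to the leftmost anchor", {
  # deletion of one AT unit inside an (AT)n tract is representable at many
  # anchors; all must collapse to the same leftmost form
  refChars <- strsplit("GGCATATATATGGC", "")[[1]]
  ref <- paste(refChars, collapse = "")
  for (p in c(4L, 6L, 8L)) {
    del <- data.frame(chrom = "r", pos = p,
                      ref = paste(refChars[p:(p + 2)], collapse = ""),
                      alt = refChars[p], genotype = "het",
                      stringsAsFactors = FALSE)
    out <- normalizeVariants(del, ref)
    oracle <- oracleLeftAlign(del$pos, del$ref, del$alt, refChars)
    expect_equal(out$pos, oracle[[1]])
    expect_equal(out$ref, oracle[[2]])
    expect_equal(out$alt, oracle[[3]])
  }
})

test_that("normalization is idempotent and matches the left-shift oracle on random indels", {
  set.seed(42)
  refChars <- randomRefChars(300)
  ref <- paste(refChars, collapse = "")
  for (i in 1:40) {
    p <- sample(5:280, 1)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)
      v <- data.frame(chrom = "r", pos = p,
                      ref = paste(refChars[p:(p + len)], collapse = ""),
                      alt = refChars[p], genotype = "het",
                      stringsAsFactors = FALSE)
    } else {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                          replace = TRUE), collapse = "")
      v <- data.frame(chrom = "r", pos = p, ref = refChars[p],
                      alt = paste0(refChars[p], ins), genotype = "het",
                      stringsAsFactors = FALSE)
    }
    once <- normalizeVariants(v, ref)
    twice <- normalizeVariants(once, ref)
    expect_equal(once, twice)
    oracle <- oracleLeftAlign(v$pos, v$ref, v$alt, refChars)
    expect_equal(once$pos, oracle[[1]])
    expect_equal(once$ref, oracle[[2]])
  }
})

test_that("normalization rejects ref alleles that contradict the reference", {
  expect_error(normalizeVariants(
    data.frame(chrom = "r", pos = 2L, ref = "T", alt = "C",
               genotype = "het", stringsAsFactors = FALSE), "AAAA"),
    "does not match")
})

test_that("classification handles exact matches, mismatches and region limits", {
  region <- wholeRegion(1000)
  t1 <- CallSet("s", data.frame(chrom = "region", pos = 100L, ref = "A",
                                alt = "G", genotype = "het",
                                stringsAsFactors = FALSE))
  e1 <- CallSet("s", data.frame(chrom = "region", pos = 100L, ref = "A",
                                alt = "G", genotype = "het",
                                stringsAsFactors = FALSE))
  cl <- classifyCalls(t1, e1, region)
  expect_equal(unname(countVector(cl)), c(1, 0, 0, 999))

  e2 <- CallSet("s", data.frame(chrom = "region", pos = 100L, ref = "A",
                                alt = "G", genotype = "hom_alt",
                                stringsAsFactors = FALSE))
  cl2 <- classifyCalls(t1, e2, region)
  expect_equal(unname(countVector(cl2))[1:3], c(0, 1, 1))

  cl2b <- classifyCalls(t1, e2, region, gtMismatch = "fp_only")
  expect_equal(unname(countVector(cl2b))[1:3], c(0, 1, 0))

  e3 <- CallSet("s", data.frame(chrom = "region", pos = 5000L, ref = "A",
                                alt = "G", genotype = "het",
                                stringsAsFactors = FALSE))
  cl3 <- classifyCalls(t1, e3, region)
  expect_equal(unname(countVector(cl3))[1:3], c(0, 0, 1))

  expect_error(classifyCalls(t1, CallSet("other", variants(e1)), region),
               "same sample")
  expect_error(classifyCalls(t1, e1, GenomicRanges::GRanges()), "empty")
})

test_that("classification equals the exhaustive enumeration oracle on random cohorts", {
  set.seed(7)
  regionLen <- 400L
  region <- wholeRegion(regionLen)
  for (i in 1:50) {
    refChars <- randomRefChars(regionLen)
    tv <- randomVariantTable(sample(5:30, 1), regionLen, refChars)
    ev <- perturbVariantTable(tv, regionLen, refChars)
    got <- countVector(classifyCalls(CallSet("s", tv), CallSet("s", ev),
                                     region))
    want <- oracleClassify(tv, ev, regionLen)
    expect_equal(unname(got), unname(want))
  }
})

test_that("conservation and truth/eval symmetry hold", {
  set.seed(8)
  regionLen <- 400L
  region <- wholeRegion(regionLen)
  refChars <- randomRefChars(regionLen)
  tv <- randomVariantTable(20, regionLen, refChars)
  ev <- perturbVariantTable(tv, regionLen, refChars)
  fwd <- countVector(classifyCalls(CallSet("s", tv), CallSet("s", ev),
                                   region))
  expect_equal(unname(fwd[["tp"]] + fwd[["fn"]]), nrow(tv))
  rev <- countVector(classifyCalls(CallSet("s", ev), CallSet("s", tv),
                                   region))
  expect_equal(rev[["tp"]], fwd[["tp"]])
  expect_equal(rev[["fp"]], fwd[["fn"]])
  expect_equal(rev[["fn"]], fwd[["fp"]])
  expect_equal(rev[["tn"]], fwd[["tn"]])
})

test_that("stratification assigns records to every overlapping stratum", {
  region <- wholeRegion(1000)
  tv <- data.frame(chrom = "region", pos = c(100L, 300L),
                   ref = c("A", "ACGT"), alt = c("G", "A"),
                   genotype = c("het", "hom_alt"), stringsAsFactors = FALSE)
  cl <- classifyCalls(CallSet("s", tv), CallSet("s", tv), region)
  contexts <- list(segdup = GenomicRanges::GRanges(
    "region", IRanges::IRanges(90, 110)),
    spanned = GenomicRanges::GRanges("region", IRanges::IRanges(302, 305)))
  st <- stratifyCalls(cl, contexts = contexts,
                      predicates = c("deletion", "het"))
  expect_equal(countVector(st$segdup)[["tp"]], 1)
  # the deletion footprint (300-303) overlaps the "spanned" context and the
  # deletion predicate simultaneously
  expect_equal(countVector(st$spanned)[["tp"]], 1)
  expect_equal(countVector(st$deletion)[["tp"]], 1)
  expect_equal(countVector(st$het)[["tp"]], 1)
  expect_error(stratifyCalls(cl, predicates = "nonsense"),
               "unknown predicate")
})

test_that("stratum counts equal a brute-force membership scan", {
  set.seed(9)
  regionLen <- 500L
  region <- wholeRegion(regionLen)
  refChars <- randomRefChars(regionLen)
  tv <- randomVariantTable(25, regionLen, refChars)
  ev <- perturbVariantTable(tv, regionLen, refChars)
  cl <- classifyCalls(CallSet("s", tv), CallSet("s", ev), region)
  ctx <- GenomicRanges::GRanges("region", IRanges::IRanges(
    c(50, 300), c(150, 420)))
  st <- stratifyCalls(cl, contexts = list(ctx = ctx))
  inCtx <- function(v) {
    vapply(seq_len(nrow(v)), function(i) {
      span <- v$pos[i]:(v$pos[i] + nchar(v$ref[i]) - 1L)
      any((span >= 50 & span <= 150) | (span >= 300 & span <= 420))
    }, TRUE)
  }
  expect_equal(countVector(st$ctx)[["tp"]], sum(inCtx(truePositives(cl))))
  expect_equal(countVector(st$ctx)[["fp"]], sum(inCtx(falsePositives(cl))))
  expect_equal(countVector(st$ctx)[["fn"]], sum(inCtx(falseNegatives(cl))))
})

test_that("recurrent artifacts are flagged at and above the sample fraction", {
  region <- wholeRegion(1000)
  mkClassified <- function(withFP) {
    tv <- data.frame(chrom = "region", pos = 10L, ref = "A", alt = "G",
                     genotype = "het", stringsAsFactors = FALSE)
    ev <- if (withFP) {
      rbind(tv, data.frame(chrom = "region", pos = 500L, ref = "C",
                           alt = "T", genotype = "het",
                           stringsAsFactors = FALSE))
    } else tv
    classifyCalls(CallSet("s", tv), CallSet("s", ev), region)
  }
  # recurrent FP in 2 of 10 samples: flagged at minFraction 0.2 (rule is >=)
  cls <- c(lapply(1:2, function(i) mkClassified(TRUE)),
           lapply(1:8, function(i) mkClassified(FALSE)))
  hits <- detectRecurrentArtifacts(cls, minFraction = 0.2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pos, 500L)
  # 1 of 10: not flagged
  cls1 <- c(lapply(1, function(i) mkClassified(TRUE)),
            lapply(1:9, function(i) mkClassified(FALSE)))
  expect_equal(nrow(detectRecurrentArtifacts(cls1, 0.2)), 0)
  expect_error(detectRecurrentArtifacts(cls, 0), "minFraction")
  expect_error(detectRecurrentArtifacts(cls[1], 0.2), "2 samples")
})
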