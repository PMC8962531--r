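test_that("the genotype caller is the binomial-likelihood argmax", {
  cfg <- genotypeCallerConfig(0.01)
  expect_equal(callGenotype(30, 15, cfg), "het")
  expect_equal(callGenotype(30, 0, cfg), "hom_ref")
  expect_equal(callGenotype(30, 30, cfg), "hom_alt")
  expect_true(is.na(callGenotype(0, 0, cfg)))
  expect_error(callGenotype(10, 11, cfg), "altReads")
  expect_error(genotypeCallerConfig(0.6), "baseError")

  # direct pmf comparison at an off-balance count
  for (alt in c(3, 5, 8, 12, 25)) {
    ll <- c(hom_ref = dbinom(alt, 30, 0.01),
            het = dbinom(alt, 30, 0.5),
            hom_alt = dbinom(alt, 30, 0.99))
    expect_equal(callGenotype(30, alt, cfg), names(which.max(ll)))
  }
})

test_that("downsampling keeps baselines at f=1 and degrades monotonically", {
  obs <- simulateSiteObservations(2000, meanDepth = 40, seed = 51)
  base <- downsampleCurve(obs, fractions = 1, replicates = 2, seed = 52)
  called <- callGenotype(obs$depth, obs$altReads)
  pos <- obs$truthGenotype != "hom_ref"
  expect_equal(curveValues(base),
               mean(called[pos] == obs$truthGenotype[pos]))

  curve <- downsampleCurve(obs, fractions = seq(0.05, 0.5, by = 0.05),
                           replicates = 20, seed = 53)
  expect_false(is.unsorted(curveValues(curve)))  # decreasing with less data
  expect_lt(curveValues(curve)[1], 0.7)
  expect_error(downsampleCurve(obs[0, ], 0.5), "empty")
  expect_error(downsampleCurve(obs, 1.2), "fractions")
})

test_that("duplicate injection is downsampling at the complementary fraction", {
  obs <- simulateSiteObservations(1000, meanDepth = 40, seed = 54)
  dup <- duplicateInjectionCurve(obs, duplicateRates = c(0, 0.5),
                                 replicates = 3, seed = 55)
  down <- downsampleCurve(obs, fractions = c(0.5, 1), replicates = 3,
                          seed = 55)
  expect_equal(curveValues(dup)[curveLevels(dup) == 0.5],
               curveValues(down)[curveLevels(down) == 0.5])
  expect_equal(curveValues(dup)[curveLevels(dup) == 0],
               curveValues(down)[curveLevels(down) == 1])
  expect_error(duplicateInjectionCurve(obs, 1), "duplicate rates")
})

test_that("contamination shifts allele fractions as the mixture predicts", {
  n <- 4000
  host <- data.frame(chrom = "region", pos = seq_len(n), ref = "A",
                     alt = "G", depth = 40L, altReads = 0L,
                     truthGenotype = "hom_ref", stringsAsFactors = FALSE)
  cont <- rep("hom_alt", n)
  mixed <- contaminate(host, cont, alpha = 0.5, seed = 56)
  expect_equal(mean(mixed$altReads / mixed$depth), 0.5, tolerance = 0.01)
  # determinism and validation
  expect_identical(contaminate(host, cont, 0.5, seed = 56), mixed)
  expect_error(contaminate(host, cont, 1), "alpha")
  expect_error(contaminate(host, cont[-1], 0.1), "align")

  # genotype error rate is non-decreasing in alpha
  errs <- vapply(seq(0, 0.2, by = 0.02), function(a) {
    m <- contaminate(host, rep("het", n), a, seed = 57)
    called <- callGenotype(m$depth, m$altReads)
    mean(called != m$truthGenotype)
  }, numeric(1))
  expect_true(all(diff(errs) >= -0.005))
  expect_gt(errs[length(errs)], errs[1])
})

test_that("the contamination estimator recovers injected fractions", {
  n <- 5000
  host <- data.frame(chrom = "region", pos = seq_len(n), ref = "A",
                     alt = "G", depth = 40L, altReads = 0L,
                     truthGenotype = "hom_ref", stringsAsFactors = FALSE)
  clean <- contaminate(host, rep("hom_ref", n), 0, seed = 58)
  expect_lte(estimateContamination(clean), 0.01)

  hot <- contaminate(host, rep("het", n), 0.10, seed = 59)
  est <- estimateContamination(hot)
  expect_lt(abs(est - 0.10), 0.03)

  expect_error(estimateContamination(host[1:50, ]), "at least 100")
})

test_that("sequential thinning composes multiplicatively in distribution", {
  n <- 10000
  obs <- data.frame(chrom = "region", pos = seq_len(n), ref = "A",
                    alt = "G", depth = 100L, altReads = 50L,
                    truthGenotype = "het", stringsAsFactors = FALSE)
  two <- VariantAgreement:::.withSeed(60, {
    VariantAgreement:::.thinObservations(
      VariantAgreement:::.thinObservations(obs, 0.8), 0.5)
  })
  one <- VariantAgreement:::.withSeed(61, {
    VariantAgreement:::.thinObservations(obs, 0.4)
  })
  ks <- suppressWarnings(stats::ks.test(two$depth, one$depth))
  expect_gt(ks$p.value, 0.01)
  ksAlt <- suppressWarnings(stats::ks.test(two$altReads, one$altReads))
  expect_gt(ksAlt$p.value, 0.01)
})

test_that("limit-of-detection bands bracket balanced allele fractions", {
  lod <- lodAlleleFraction(30, seq(0.05, 0.95, by = 0.05), nSites = 3000,
                           seed = 62)
  grid <- curveLevels(lod)
  acc <- curveValues(lod)
  expect_gt(acc[grid == 0.5], 0.99)
  expect_lt(acc[grid == 0.05], 0.05)  # called hom-ref, not het
  band <- curveBand(lod)
  expect_true(band[1] <= 0.5 && 0.5 <= band[2])
  for (depth in c(20, 40)) {
    b <- curveBand(lodAlleleFraction(depth, nSites = 2000, seed = 63))
    expect_true(b[1] <= 0.5 && 0.5 <= b[2])
  }
  expect_error(lodAlleleFraction(30, numeric(0)), "empty")
})

test_that("threshold selection scans from least degraded and stops at failure", {
  mk <- function(axis, levels, values) {
    new("DegradationCurve", axis = axis, levels = levels,
        metric = "sensitivity", values = values,
        perReplicate = matrix(values, nrow = 1), replicates = 1L,
        seed = 1L, band = numeric(0))
  }
  # monotone downsampling curve crossing 0.98 between 0.3 and 0.5
  c1 <- mk("downsample_fraction", c(0.1, 0.3, 0.5, 0.8, 1),
           c(0.80, 0.95, 0.985, 0.99, 0.999))
  expect_equal(selectThreshold(c1, 0.98), 0.5)
  # nothing qualifies
  expect_true(is.na(selectThreshold(c1, 0.9999)))
  # non-monotone: the dip at 0.7 stops the scan even though 0.5 would pass
  c2 <- mk("downsample_fraction", c(0.5, 0.7, 0.9),
           c(0.985, 0.97, 0.99))
  expect_equal(selectThreshold(c2, 0.98), 0.9)
  # contamination curves degrade upward
  c3 <- mk("contamination_fraction", c(0, 0.05, 0.1, 0.2),
           c(0.999, 0.99, 0.97, 0.9))
  expect_equal(selectThreshold(c3, 0.98), 0.05)
})
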