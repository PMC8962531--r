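#' Assemble a validation report from a synthetic cohort
#'
#' Runs the full validation pipeline on a generated cohort and collects the
#' results into one structure mirroring a validation summary: a
#' stratified agreement table, the inter-lab Jaccard precision section, a
#' reportable-range summary, QC degradation curves with selected thresholds
#' and the limit-of-detection band, a PGx concordance section when a PGx
#' cohort is supplied, and provenance (config and seed).
#'
#' @param cohort a \code{\link{SyntheticCohort}}.
#' @param region comparison region \code{GRanges}; defaults to the whole
#'   generated region.
#' @param reportableRange optional \code{\link{ReportableRange}} to
#'   summarize.
#' @param pgx optional list with elements \code{truth} (named list of
#'   \code{DiplotypeCall}s) and \code{methodCalls} (see
#'   \code{\link{tabulateConcordance}}).
#' @param minMetric sensitivity floor handed to
#'   \code{\link{selectThreshold}} (a required study input; no published
#'   default exists).
#' @param lodDepth depth for the limit-of-detection analysis.
#' @param nPermutations permutations for the inter-lab equivalence test.
#' @return list of class \code{"ValidationReport"} with sections
#'   \code{agreement}, \code{precision}, \code{reportableRange}, \code{qc},
#'   \code{pgx}, \code{provenance}.
#' @export
validationReport <- function(cohort, region = NULL, reportableRange = NULL,
                             pgx = NULL, minMetric = 0.98, lodDepth = 30L,
                             nPermutations = 499L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  cfg <- cohort@config
  if (is.null(region)) {
    region <- GenomicRanges::GRanges(
      "region", IRanges::IRanges(1, cfg@regionLength))
  }

  # agreement: classify every eval set against its truth, pool per stratum
  perSample <- list()
  classifiedAll <- list()
  for (key in names(cohort@evalSets)) {
    ev <- cohort@evalSets[[key]]
    cl <- classifyCalls(cohort@truth[[sampleId(ev)]], ev, region)
    classifiedAll[[key]] <- cl
    strata <- c(list(all = cl@counts),
                stratifyCalls(cl, contexts = cohort@contexts,
                              predicates = c("snv", "insertion", "deletion",
                                             "het", "hom_alt")))
    perSample[[key]] <- strata
  }
  strataNames <- names(perSample[[1]])
  pooled <- lapply(strataNames, function(nm) {
    sumCounts(lapply(perSample, `[[`, nm))
  })
  names(pooled) <- strataNames
  agreement <- agreementTable(pooled, perSampleStrata = perSample)

  # precision: pairwise Jaccard and the lab-equivalence permutation test
  precision <- NULL
  if (cfg@nLabs >= 2 && cfg@nReplicatesPerLab >= 2) {
    jm <- pairwiseJaccard(cohort@evalSets, region = region)
    eq <- testInterlabEquivalence(jm, nPermutations = nPermutations,
                                  seed = cfg@seed + 2L)
    precision <- list(jaccard = jm, equivalence = eq)
  }

  # reportable-range summary
  rr <- NULL
  if (!is.null(reportableRange)) {
    rr <- list(totalBases = totalBases(reportableRange),
               nIntervals = length(rangeIntervals(reportableRange)),
               nExclusions = length(exclusionsApplied(reportableRange)),
               nCoverageFlags = length(coverageFlags(reportableRange)),
               nConflicts = nrow(rangeConflicts(reportableRange)))
  }

  # QC curves on a simulated site panel
  obs <- simulateSiteObservations(2000L, meanDepth = 40,
                                  seed = cfg@seed + 3L)
  down <- downsampleCurve(obs, fractions = seq(0.1, 1, by = 0.1),
                          replicates = 3L, seed = cfg@seed + 4L)
  lod <- lodAlleleFraction(lodDepth, seed = cfg@seed + 5L)
  qc <- list(downsampling = down,
             downsampleThreshold = selectThreshold(down, minMetric),
             lod = lod, lodBand = curveBand(lod))

  pgxSection <- NULL
  if (!is.null(pgx)) {
    pgxSection <- tabulateConcordance(pgx$truth, pgx$methodCalls)
  }

  structure(list(agreement = agreement, precision = precision,
                 reportableRange = rr, qc = qc, pgx = pgxSection,
                 classified = classifiedAll,
                 provenance = list(config = cfg, seed = cfg@seed)),
            class = "ValidationReport")
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Validation report (seed", x$provenance$seed, ")\n")
  cat("Sections:", paste(names(Filter(Negate(is.null), x[1:5])),
                         collapse = ", "), "\n")
  allRow <- x$agreement[x$agreement$stratum == "all", ]
  if (nrow(allRow)) {
    cat(sprintf("  pooled PPA %.2f%%, NPA %.4f%% over all strata\n",
                100 * allRow$ppa, 100 * allRow$npa))
  }
  if (!is.null(x$precision)) {
    cat(sprintf("  inter-lab equivalence p = %.3f\n",
                x$precision$equivalence@pValue))
  }
  if (length(x$qc$lodBand) == 2) {
    cat(sprintf("  het-call LoD band: %.0f%%-%.0f%% allele fraction\n",
                100 * x$qc$lodBand[1], 100 * x$qc$lodBand[2]))
  }
  invisible(x)
}
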