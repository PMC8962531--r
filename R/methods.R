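# Accessors and show methods.

#' Variant records of a CallSet
#' @param x a \code{CallSet}.
#' @return data.frame of variant records.
#' @export
variants <- function(x) {
  stopifnot(is(x, "CallSet"))
  x@variants
}

#' Sample identifier of a CallSet or ClassifiedCalls
#' @param x a \code{CallSet} or \code{ClassifiedCalls}.
#' @return character sample identifier.
#' @export
sampleId <- function(x) x@sample

#' Lab and replicate provenance of a CallSet
#' @param x a \code{CallSet}.
#' @return named list with lab and replicate (possibly NULL).
#' @export
provenance <- function(x) {
  stopifnot(is(x, "CallSet"))
  list(lab = x@lab, replicate = x@replicate)
}

#' Contingency counts of a classification result
#'
#' Method on the \code{BiocGenerics} \code{counts} generic.
#'
#' @param object a \code{ClassifiedCalls} or \code{ContingencyCounts}.
#' @param ... ignored.
#' @return a \code{ContingencyCounts}.
#' @aliases counts,ClassifiedCalls-method counts,ContingencyCounts-method
#' @importFrom BiocGenerics counts
#' @exportMethod counts
#' @name counts
NULL

setMethod("counts", "ClassifiedCalls", function(object, ...) object@counts)
setMethod("counts", "ContingencyCounts", function(object, ...) object)

#' Counts as a named numeric vector
#' @param x a \code{ContingencyCounts} or \code{ClassifiedCalls}.
#' @return named numeric vector (tp, fp, fn, tn).
#' @export
countVector <- function(x) {
  x <- counts(x)
  c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn)
}

#' True/false positive and false negative records
#' @param x a \code{ClassifiedCalls}.
#' @return data.frame of variant records.
#' @name classified-accessors
NULL

#' @rdname classified-accessors
#' @export
truePositives <- function(x) x@tp

#' @rdname classified-accessors
#' @export
falsePositives <- function(x) x@fp

#' @rdname classified-accessors
#' @export
falseNegatives <- function(x) x@fn

#' Reportable-range accessors
#' @param x a \code{ReportableRange}.
#' @return see individual accessors.
#' @name reportable-accessors
NULL

#' @rdname reportable-accessors
#' @export
rangeIntervals <- function(x) x@intervals

#' @rdname reportable-accessors
#' @export
exclusionsApplied <- function(x) x@exclusionsApplied

#' @rdname reportable-accessors
#' @export
coverageFlags <- function(x) x@coverageFlags

#' @rdname reportable-accessors
#' @export
totalBases <- function(x) x@totalBases

#' @rdname reportable-accessors
#' @export
rangeConflicts <- function(x) x@conflicts

#' Degradation-curve accessors
#' @param x a \code{DegradationCurve}.
#' @return see individual accessors.
#' @name curve-accessors
NULL

#' @rdname curve-accessors
#' @export
curveLevels <- function(x) x@levels

#' @rdname curve-accessors
#' @export
curveValues <- function(x) x@values

#' @rdname curve-accessors
#' @export
curveBand <- function(x) x@band

#' Diplotype-call accessors
#' @param x a \code{DiplotypeCall}.
#' @return see individual accessors.
#' @name diplotype-accessors
NULL

#' @rdname diplotype-accessors
#' @export
dipAlleles <- function(x) x@alleles

#' @rdname diplotype-accessors
#' @export
isAmbiguous <- function(x) x@ambiguous

#' @rdname diplotype-accessors
#' @export
dipConflicts <- function(x) x@conflicts

setMethod("show", "CallSet", function(object) {
  cat("CallSet for sample", object@sample)
  if (!is.null(object@lab)) cat(" [lab", object@lab, "]")
  if (!is.null(object@replicate)) cat(" [replicate", object@replicate, "]")
  cat("\n ", nrow(object@variants), "variant calls\n")
})

setMethod("show", "ContingencyCounts", function(object) {
  cat("ContingencyCounts [", object@stratum, "] TP=", object@tp,
      " FP=", object@fp, " FN=", object@fn, " TN=", object@tn, "\n", sep = "")
})

setMethod("show", "ClassifiedCalls", function(object) {
  cat("ClassifiedCalls for sample", object@sample, "\n")
  show(object@counts)
})

setMethod("show", "JaccardMatrix", function(object) {
  cat("JaccardMatrix over", nrow(object@labels), "call sets (",
      sum(!is.na(object@values[upper.tri(object@values)])),
      "defined pairs )\n")
})

setMethod("show", "EquivalenceTestResult", function(object) {
  cat("Inter-lab equivalence permutation test\n",
      " mean within-lab Jaccard: ", format(object@meanWithin, digits = 6),
      "\n  mean between-lab Jaccard:", format(object@meanBetween, digits = 6),
      "\n  difference (within - between):",
      format(object@difference, digits = 6),
      "\n  one-sided p (between worse):", format(object@pValue, digits = 4),
      " (", object@nPermutations, "permutations )\n")
})

setMethod("show", "ReportableRange", function(object) {
  cat("ReportableRange:", length(object@intervals), "intervals,",
      object@totalBases, "bases\n ",
      length(object@exclusionsApplied), "exclusions applied;",
      length(object@coverageFlags), "low-coverage flags;",
      nrow(object@conflicts), "site conflicts\n")
})

setMethod("show", "DegradationCurve", function(object) {
  cat("DegradationCurve:", object@metric, "vs", object@axis, "over",
      length(object@levels), "levels x", object@replicates, "replicates\n")
  if (length(object@band) == 2) {
    cat("  band: [", object@band[1], ",", object@band[2], "]\n")
  }
})

setMethod("show", "DiplotypeCall", function(object) {
  cat(object@gene, paste(object@alleles, collapse = "/"),
      if (object@ambiguous) "(ambiguous)" else "", "\n")
  if (length(object@conflicts)) {
    cat("  conflicts:", paste(object@conflicts, collapse = "; "), "\n")
  }
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@truth), "samples,",
      length(object@evalSets), "evaluation call sets,",
      "region length", object@config@regionLength, "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSamples, "samples x", object@nLabs, "labs x",
      object@nReplicatesPerLab, "replicates; region",
      object@regionLength, "bp; seed", object@seed, "\n")
})
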