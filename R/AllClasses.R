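#' @import methods
#' @importFrom GenomicRanges GRanges seqnames
#' @importFrom IRanges IRanges
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' CallSet: one sample's variant calls with provenance
#'
#' A \code{CallSet} holds the normalized variant calls for a single sample,
#' optionally tagged with the laboratory and replicate that produced them.
#' Variants are stored as a data.frame with columns \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt} and \code{genotype} (\code{"het"} or
#' \code{"hom_alt"}); homozygous-reference positions are implicit.
#'
#' @slot sample sample identifier.
#' @slot lab laboratory identifier or \code{NULL}.
#' @slot replicate replicate identifier or \code{NULL}.
#' @slot variants data.frame of variant records (see Details).
#'
#' @export
setClass("CallSet",
  representation(
    sample = "character",
    lab = "characterOrNULL",
    replicate = "characterOrNULL",
    variants = "data.frame"
  )
)

setValidity("CallSet", function(object) {
  if (length(object@sample) != 1L) return("sample must be a single identifier")
  ok <- tryCatch({
    .checkVariantFrame(object@variants)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' @describeIn CallSet construct a CallSet
#' @param sample sample identifier.
#' @param variants variant data.frame (chrom, pos, ref, alt, genotype).
#' @param lab,replicate optional provenance identifiers.
#' @export
CallSet <- function(sample, variants = .emptyVariants(), lab = NULL,
                    replicate = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (nrow(variants)) {
    variants$pos <- as.integer(variants$pos)
    variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                               variants$alt), , drop = FALSE]
    rownames(variants) <- NULL
  }
  new("CallSet", sample = as.character(sample), lab = lab,
      replicate = replicate, variants = variants)
}

#' ContingencyCounts: TP/FP/FN/TN for one stratum
#'
#' @slot tp,fp,fn,tn non-negative counts.
#' @slot stratum stratum label.
#' @export
setClass("ContingencyCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric", stratum = "character")
)

setValidity("ContingencyCounts", function(object) {
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    return("tp, fp, fn, tn must all be non-negative")
  }
  TRUE
})

#' @describeIn ContingencyCounts construct contingency counts
#' @param tp,fp,fn,tn non-negative counts.
#' @param stratum stratum label.
#' @export
ContingencyCounts <- function(tp, fp, fn, tn, stratum = "all") {
  new("ContingencyCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn), stratum = stratum)
}

#' ClassifiedCalls: genotype-aware comparison of one sample against truth
#'
#' Result of \code{\link{classifyCalls}}: the true-positive, false-positive
#' and false-negative variant records, the summary counts (including the
#' true-negative base count over the comparison region), and the region the
#' comparison was restricted to.
#'
#' @slot sample sample identifier.
#' @slot tp,fp,fn variant data.frames.
#' @slot counts a \code{ContingencyCounts}.
#' @slot region comparison region (\code{GRanges}, 1-based closed intervals).
#' @export
setClass("ClassifiedCalls",
  representation(
    sample = "character",
    tp = "data.frame", fp = "data.frame", fn = "data.frame",
    counts = "ContingencyCounts",
    region = "GRanges"
  )
)

setValidity("ClassifiedCalls", function(object) {
  if (object@counts@tp != nrow(object@tp)) return("counts.tp != |tp|")
  if (object@counts@fp != nrow(object@fp)) return("counts.fp != |fp|")
  if (object@counts@fn != nrow(object@fn)) return("counts.fn != |fn|")
  if (nrow(object@tp) && nrow(object@fp) &&
      length(intersect(.variantKey(object@tp), .variantKey(object@fp)))) {
    return("tp and fp overlap on (site, alt, genotype) keys")
  }
  TRUE
})

#' JaccardMatrix: pairwise replicate concordance
#'
#' Symmetric matrix of Jaccard similarity coefficients over exact
#' (chrom, pos, ref, alt, genotype) keys between replicate call sets.
#' Cross-sample entries are undefined (\code{NA}).
#'
#' @slot labels data.frame with columns lab, replicate, sample (one row per
#'   matrix row/column).
#' @slot values symmetric numeric matrix in [0, 1] with unit diagonal.
#' @slot region comparison region used.
#' @export
setClass("JaccardMatrix",
  representation(labels = "data.frame", values = "matrix", region = "GRanges")
)

setValidity("JaccardMatrix", function(object) {
  v <- object@values
  if (nrow(v) != nrow(object@labels)) return("labels/matrix size mismatch")
  if (nrow(v)) {
    if (any(abs(diag(v) - 1) > 1e-12)) return("diagonal must be 1")
    if (any(!is.na(v) & (v < 0 | v > 1))) return("values must lie in [0,1]")
    if (!isTRUE(all.equal(v, t(v)))) return("matrix must be symmetric")
  }
  TRUE
})

#' EquivalenceTestResult: permutation test of inter-lab equivalence
#'
#' @slot meanWithin mean within-lab pairwise Jaccard.
#' @slot meanBetween mean between-lab pairwise Jaccard.
#' @slot difference meanWithin - meanBetween.
#' @slot pValue one-sided permutation p-value for "between labs worse than
#'   within labs".
#' @slot nPermutations number of label permutations.
#' @slot seed RNG seed used.
#' @export
setClass("EquivalenceTestResult",
  representation(meanWithin = "numeric", meanBetween = "numeric",
                 difference = "numeric", pValue = "numeric",
                 nPermutations = "integer", seed = "integer")
)

setValidity("EquivalenceTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0,1]")
  TRUE
})

#' TranscriptModel: exon structure of one transcript
#'
#' @slot gene gene symbol.
#' @slot chrom sequence name.
#' @slot strand "+" or "-".
#' @slot exons \code{IRanges} of exons, 1-based closed, sorted,
#'   non-overlapping.
#' @export
setClass("TranscriptModel",
  representation(gene = "character", chrom = "character", strand = "character",
                 exons = "IRanges")
)

setValidity("TranscriptModel", function(object) {
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  e <- object@exons
  if (length(e) > 1) {
    s <- IRanges::start(e)
    if (is.unsorted(s)) return("exons must be sorted by genomic coordinate")
    if (any(IRanges::start(e)[-1] <= IRanges::end(e)[-length(e)])) {
      return("exons must be non-overlapping")
    }
  }
  TRUE
})

#' @describeIn TranscriptModel construct a transcript model
#' @param gene gene symbol.
#' @param chrom sequence name.
#' @param strand "+" or "-".
#' @param exons an \code{IRanges} of exon intervals (1-based closed).
#' @export
TranscriptModel <- function(gene, chrom, strand, exons) {
  new("TranscriptModel", gene = gene, chrom = chrom, strand = strand,
      exons = exons)
}

#' ReportableRange: assay interval set with annotations and exclusions
#'
#' @slot intervals final reportable intervals (\code{GRanges}) with an
#'   \code{annotation} metadata column (exon_padded / plp_site / pgx_site).
#' @slot exclusionsApplied excluded intervals with a \code{rule} column.
#' @slot coverageFlags low-coverage intervals (annotation only, not excluded).
#' @slot conflicts data.frame of requested sites that fell inside exclusions.
#' @slot totalBases total interval length in bases.
#' @export
setClass("ReportableRange",
  representation(intervals = "GRanges", exclusionsApplied = "GRanges",
                 coverageFlags = "GRanges", conflicts = "data.frame",
                 totalBases = "numeric")
)

setValidity("ReportableRange", function(object) {
  gr <- object@intervals
  if (length(gr)) {
    if (sum(GenomicRanges::width(GenomicRanges::reduce(gr))) !=
        sum(GenomicRanges::width(gr))) {
      return("intervals must be non-overlapping after merging")
    }
    hits <- GenomicRanges::countOverlaps(gr, object@exclusionsApplied)
    if (any(hits > 0)) return("intervals must be disjoint from exclusions")
  }
  if (abs(object@totalBases - sum(GenomicRanges::width(gr))) > 0) {
    return("totalBases must equal the summed interval widths")
  }
  TRUE
})

#' DegradationCurve: a QC metric as a function of a degradation level
#'
#' @slot axis one of downsample_fraction, contamination_fraction,
#'   duplicate_rate, allele_fraction.
#' @slot levels sorted degradation levels.
#' @slot metric metric name (sensitivity, genotype_error_rate,
#'   het_call_accuracy).
#' @slot values per-level metric values (mean across replicates).
#' @slot perReplicate replicate-by-level matrix of metric values.
#' @slot replicates number of replicates.
#' @slot seed RNG seed.
#' @slot band for limit-of-detection curves, the (low, high) allele-fraction
#'   band where the metric stays above the band threshold; otherwise empty.
#' @export
setClass("DegradationCurve",
  representation(axis = "character", levels = "numeric", metric = "character",
                 values = "numeric", perReplicate = "matrix",
                 replicates = "integer", seed = "integer", band = "numeric")
)

setValidity("DegradationCurve", function(object) {
  if (length(object@levels) != length(object@values)) {
    return("levels and values must have equal length")
  }
  if (is.unsorted(object@levels)) return("levels must be sorted")
  v <- object@values[!is.na(object@values)]
  if (any(v < 0 | v > 1)) return("metric values must lie in [0,1]")
  TRUE
})

#' StarAlleleTable: star-allele definitions for one gene
#'
#' @slot gene gene symbol.
#' @slot alleles named list mapping allele name to a data.frame of defining
#'   variant keys (chrom, pos, ref, alt); the reference allele maps to an
#'   empty set.
#' @slot referenceAllele name of the reference (no-variant) allele.
#' @export
setClass("StarAlleleTable",
  representation(gene = "character", alleles = "list",
                 referenceAllele = "character")
)

setValidity("StarAlleleTable", function(object) {
  if (!object@referenceAllele %in% names(object@alleles)) {
    return("referenceAllele must be present in alleles")
  }
  if (nrow(object@alleles[[object@referenceAllele]]) != 0) {
    return("reference allele must map to an empty defining set")
  }
  for (nm in setdiff(names(object@alleles), object@referenceAllele)) {
    if (nrow(object@alleles[[nm]]) == 0) {
      return(paste0("non-reference allele ", nm, " has no defining variants"))
    }
  }
  TRUE
})

#' @describeIn StarAlleleTable construct a star-allele definition table
#' @param gene gene symbol.
#' @param alleles named list of data.frames (chrom, pos, ref, alt).
#' @param referenceAllele reference allele name (default "*1").
#' @export
StarAlleleTable <- function(gene, alleles, referenceAllele = "*1") {
  if (!referenceAllele %in% names(alleles)) {
    alleles[[referenceAllele]] <- data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), stringsAsFactors = FALSE)
  }
  new("StarAlleleTable", gene = gene, alleles = alleles,
      referenceAllele = referenceAllele)
}

#' DiplotypeCall: a called pair of star alleles
#'
#' @slot gene gene symbol.
#' @slot alleles character vector of allele names (two for diploid genes, one
#'   for haploid calls), sorted.
#' @slot ambiguous whether the call admits another explanation.
#' @slot conflicts diagnostic messages for partial or unexplained matches.
#' @export
setClass("DiplotypeCall",
  representation(gene = "character", alleles = "character",
                 ambiguous = "logical", conflicts = "character")
)

setValidity("DiplotypeCall", function(object) {
  if (!length(object@alleles) %in% 1:2) {
    return("a diplotype holds one (haploid) or two allele names")
  }
  TRUE
})

#' CohortConfig: parameters of the synthetic validation cohort
#'
#' Defines the study conditions a synthetic cohort is generated under:
#' sample count, region size, variant density and type mix, per-stratum
#' false-negative and false-positive rates, genotype-error rate, and the
#' lab/replicate structure.
#'
#' @slot nSamples number of samples.
#' @slot regionLength length of the simulated region in bases.
#' @slot variantRate expected truth variants per base.
#' @slot typeMix named proportions over snv, insertion, deletion (sums to 1).
#' @slot indelLengthProbs probabilities over indel lengths 1..50.
#' @slot hetFraction proportion of truth variants that are heterozygous.
#' @slot fnRateByStratum named per-type miss probabilities ("default" allowed).
#' @slot fpRateByStratum named per-type expected false calls per base.
#' @slot gtErrorRate probability a matched call has flipped zygosity.
#' @slot nLabs,nReplicatesPerLab lab/replicate structure of the eval sets.
#' @slot seed RNG seed; identical configs with identical seeds generate
#'   bit-identical cohorts.
#' @export
setClass("CohortConfig",
  representation(
    nSamples = "integer", regionLength = "integer", variantRate = "numeric",
    typeMix = "numeric", indelLengthProbs = "numeric", hetFraction = "numeric",
    fnRateByStratum = "numeric", fpRateByStratum = "numeric",
    gtErrorRate = "numeric", nLabs = "integer", nReplicatesPerLab = "integer",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  if (object@regionLength <= 0) return("regionLength must be positive")
  if (object@nSamples < 1) return("nSamples must be >= 1")
  if (abs(sum(object@typeMix) - 1) > 1e-8) return("typeMix must sum to 1")
  if (!all(sort(names(object@typeMix)) ==
           c("deletion", "insertion", "snv"))) {
    return("typeMix must be named snv, insertion, deletion")
  }
  for (nm in c("variantRate", "hetFraction", "gtErrorRate")) {
    x <- slot(object, nm)
    if (x < 0 || x > 1) return(paste(nm, "must lie in [0,1]"))
  }
  if (any(object@fnRateByStratum < 0) || any(object@fnRateByStratum > 1)) {
    return("fnRateByStratum entries must lie in [0,1]")
  }
  if (any(object@fpRateByStratum < 0)) {
    return("fpRateByStratum entries must be non-negative")
  }
  if (abs(sum(object@indelLengthProbs) - 1) > 1e-8) {
    return("indelLengthProbs must sum to 1")
  }
  TRUE
})

#' SyntheticCohort: a fully generated validation cohort
#'
#' @slot truth named list of truth \code{CallSet}s, one per sample.
#' @slot evalSets named list of evaluation \code{CallSet}s keyed
#'   "lab:replicate:sample".
#' @slot contexts named list of labeled context \code{GRanges}.
#' @slot reference the simulated reference fragment (\code{DNAString}).
#' @slot coverage per-site depth matrix (positions x samples).
#' @slot config the \code{CohortConfig} that produced the cohort.
#' @export
setClass("SyntheticCohort",
  representation(truth = "list", evalSets = "list", contexts = "list",
                 reference = "ANY", coverage = "matrix",
                 config = "CohortConfig")
)
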