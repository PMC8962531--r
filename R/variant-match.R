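#' Normalize variant representations
#'
#' Left-aligns and trims indels against the reference and decomposes
#' multi-base substitutions into per-base SNVs sharing the original genotype,
#' matching the comparison semantics of genotype-aware benchmarking engines.
#' SNVs pass through unchanged. Normalization is idempotent.
#'
#' The normalization loop is the standard one: repeatedly drop a shared
#' trailing base (extending left with the preceding reference base when an
#' allele would empty), then trim shared leading bases while both alleles
#' keep at least one base beyond the indel anchor.
#'
#' @param v variant data.frame (chrom, pos, ref, alt, genotype, ...).
#' @param reference a \code{DNAString} (or character) reference fragment the
#'   positions refer to; position 1 is the first base.
#' @return normalized variant data.frame (rows may increase through MNV
#'   decomposition); duplicate records after normalization are collapsed.
#' @export
normalizeVariants <- function(v, reference) {
  .checkVariantFrame(v)
  if (nrow(v) == 0) return(v)
  refChars <- strsplit(as.character(reference), "")[[1]]
  nRef <- length(refChars)

  refSpan <- function(pos, len) {
    paste(refChars[pos:(pos + len - 1L)], collapse = "")
  }

  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    chrom <- v$chrom[i]; pos <- as.integer(v$pos[i])
    ref <- v$ref[i]; alt <- v$alt[i]; gt <- v$genotype[i]
    if (pos + nchar(ref) - 1L > nRef ||
        refSpan(pos, nchar(ref)) != ref) {
      stop("ref allele does not match the reference at ", chrom, ":", pos)
    }
    if (nchar(ref) == nchar(alt)) {
      # SNV or MNV: decompose per base, dropping identical positions
      rc <- strsplit(ref, "")[[1]]
      ac <- strsplit(alt, "")[[1]]
      diffIdx <- which(rc != ac)
      rows[[i]] <- data.frame(
        chrom = chrom, pos = pos + diffIdx - 1L,
        ref = rc[diffIdx], alt = ac[diffIdx], genotype = gt,
        stringsAsFactors = FALSE)
      next
    }
    # indel: left-align then trim
    repeat {
      lr <- nchar(ref); la <- nchar(alt)
      if (lr > 0 && la > 0 &&
          substr(ref, lr, lr) == substr(alt, la, la) &&
          (lr > 1 || la > 1)) {
        ref <- substr(ref, 1, lr - 1L)
        alt <- substr(alt, 1, la - 1L)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1L) {
            # cannot extend further left; re-anchor on the first base
            ref <- paste0(refChars[1L], ref)
            alt <- paste0(refChars[1L], alt)
            break
          }
          pos <- pos - 1L
          ref <- paste0(refChars[pos], ref)
          alt <- paste0(refChars[pos], alt)
        }
      } else break
    }
    while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref))
      alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    rows[[i]] <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            genotype = gt, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(.variantKey(out)), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Positions (1-based) inside `region` (GRanges) for given chrom/pos vectors.
.inRegion <- function(chrom, pos, region) {
  if (length(pos) == 0) return(logical(0))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  GenomicRanges::countOverlaps(gr, region) > 0
}

# Distinct reference positions inside `region` touched by variant footprints
# (a variant's footprint is its ref-allele span).
.footprintPositions <- function(v, region) {
  if (nrow(v) == 0) return(GenomicRanges::GRanges())
  fp <- GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(v$pos, width = nchar(v$ref)))
  GenomicRanges::intersect(GenomicRanges::reduce(fp),
                           GenomicRanges::reduce(region))
}

#' Classify evaluation calls against a truth set
#'
#' Genotype-aware comparison of one sample's evaluation calls against its
#' truth calls, restricted to a comparison region. A true positive is an
#' exact (chrom, pos, ref, alt, genotype) match; a truth variant with no
#' matching evaluation record is a false negative; an evaluation variant with
#' no matching truth record is a false positive. A zygosity mismatch at a
#' shared site therefore yields one FN and one FP by default; set
#' \code{gtMismatch = "fp_only"} to count only the FP, reproducing the
#' stricter published reading.
#'
#' The true-negative count is the number of region bases minus the distinct
#' region positions covered by any truth or evaluation variant footprint.
#'
#' @param truth,eval \code{CallSet}s for the same sample.
#' @param region comparison region as a \code{GRanges} (1-based closed).
#' @param reference optional reference fragment; when supplied both call sets
#'   are normalized before comparison.
#' @param gtMismatch \code{"fp_and_fn"} (default) or \code{"fp_only"}.
#' @return a \code{\link{ClassifiedCalls}}.
#' @export
classifyCalls <- function(truth, eval, region, reference = NULL,
                          gtMismatch = c("fp_and_fn", "fp_only")) {
  gtMismatch <- match.arg(gtMismatch)
  stopifnot(is(truth, "CallSet"), is(eval, "CallSet"))
  if (sampleId(truth) != sampleId(eval)) {
    stop("truth and eval call sets must belong to the same sample")
  }
  if (length(region) == 0 || sum(GenomicRanges::width(region)) == 0) {
    stop("comparison region is empty")
  }
  tv <- variants(truth)
  ev <- variants(eval)
  if (!is.null(reference)) {
    if (nrow(tv)) tv <- normalizeVariants(tv, reference)
    if (nrow(ev)) ev <- normalizeVariants(ev, reference)
  }
  tv <- tv[.inRegion(tv$chrom, tv$pos, region), , drop = FALSE]
  ev <- ev[.inRegion(ev$chrom, ev$pos, region), , drop = FALSE]

  tKeys <- .variantKey(tv)
  eKeys <- .variantKey(ev)
  tp <- ev[eKeys %in% tKeys, , drop = FALSE]
  fp <- ev[!(eKeys %in% tKeys), , drop = FALSE]
  fn <- tv[!(tKeys %in% eKeys), , drop = FALSE]
  if (gtMismatch == "fp_only" && nrow(fn)) {
    # drop FN entries whose site/allele is present in eval with another
    # genotype: the mismatch is charged as a false positive only
    fn <- fn[!(.siteKey(fn) %in% .siteKey(ev)), , drop = FALSE]
  }

  touched <- sum(GenomicRanges::width(
    .footprintPositions(rbind(tv, ev), region)))
  tn <- sum(GenomicRanges::width(GenomicRanges::reduce(region))) - touched

  cc <- ContingencyCounts(tp = nrow(tp), fp = nrow(fp), fn = nrow(fn),
                          tn = tn)
  new("ClassifiedCalls", sample = sampleId(truth), tp = tp, fp = fp, fn = fn,
      counts = cc, region = region)
}

# Built-in variant predicates for stratification.
.PREDICATES <- list(
  snv = function(v) .variantType(v$ref, v$alt) == "snv",
  insertion = function(v) .variantType(v$ref, v$alt) == "insertion",
  deletion = function(v) .variantType(v$ref, v$alt) == "deletion",
  het = function(v) v$genotype == "het",
  hom_alt = function(v) v$genotype == "hom_alt"
)

#' Stratify classified calls by genomic context and variant predicates
#'
#' Assigns each TP/FP/FN record to every context interval its footprint
#' overlaps and to every predicate it satisfies. Strata are not mutually
#' exclusive: a heterozygous deletion inside a segmental duplication counts
#' in the "deletion", "het" and "segdup" strata simultaneously. The
#' per-stratum TN is recomputed over the context-and-region intersection; for
#' predicate strata the TN of the whole region is reported.
#'
#' @param classified a \code{\link{ClassifiedCalls}}.
#' @param contexts named list of context \code{GRanges}.
#' @param predicates character vector naming built-in predicates
#'   (snv, insertion, deletion, het, hom_alt), or a named list of functions
#'   taking a variant data.frame and returning a logical vector.
#' @return named list of \code{\link{ContingencyCounts}}, one per stratum.
#' @export
stratifyCalls <- function(classified, contexts = list(),
                          predicates = character(0)) {
  stopifnot(is(classified, "ClassifiedCalls"))
  if (is.character(predicates)) {
    unknown <- setdiff(predicates, names(.PREDICATES))
    if (length(unknown)) {
      stop("unknown predicate name(s): ", paste(unknown, collapse = ", "))
    }
    predicates <- .PREDICATES[predicates]
  }
  region <- classified@region
  res <- list()

  overlapsContext <- function(v, ctx) {
    if (nrow(v) == 0) return(logical(0))
    fp <- GenomicRanges::GRanges(
      v$chrom, IRanges::IRanges(v$pos, width = nchar(v$ref)))
    GenomicRanges::countOverlaps(fp, ctx) > 0
  }

  for (nm in names(contexts)) {
    ctx <- contexts[[nm]]
    sub <- GenomicRanges::intersect(GenomicRanges::reduce(ctx),
                                    GenomicRanges::reduce(region))
    tp <- classified@tp[overlapsContext(classified@tp, ctx), , drop = FALSE]
    fp <- classified@fp[overlapsContext(classified@fp, ctx), , drop = FALSE]
    fn <- classified@fn[overlapsContext(classified@fn, ctx), , drop = FALSE]
    touched <- sum(GenomicRanges::width(
      .footprintPositions(rbind(tp, fp, fn), sub)))
    tn <- sum(GenomicRanges::width(sub)) - touched
    res[[nm]] <- ContingencyCounts(nrow(tp), nrow(fp), nrow(fn), tn,
                                   stratum = nm)
  }
  for (nm in names(predicates)) {
    f <- predicates[[nm]]
    pick <- function(v) v[which(f(v)), , drop = FALSE]
    tp <- pick(classified@tp); fp <- pick(classified@fp)
    fn <- pick(classified@fn)
    res[[nm]] <- ContingencyCounts(nrow(tp), nrow(fp), nrow(fn),
                                   classified@counts@tn, stratum = nm)
  }
  res
}

#' Detect recurrent discordant variants across samples
#'
#' Flags variant keys that are discordant (false positive or false negative)
#' in at least \code{minFraction} of the classified samples; such recurrent
#' artifacts can then be excluded and the classification re-run.
#'
#' @param classifiedPerSample list of \code{\link{ClassifiedCalls}} (>= 2).
#' @param minFraction flagging threshold in (0, 1]; the rule is
#'   at-least (>=).
#' @return data.frame of flagged keys (chrom, pos, ref, alt) with the
#'   fraction of samples each was discordant in.
#' @export
detectRecurrentArtifacts <- function(classifiedPerSample, minFraction = 0.20) {
  if (length(classifiedPerSample) < 2) stop("need at least 2 samples")
  if (minFraction <= 0 || minFraction > 1) {
    stop("minFraction must lie in (0, 1]")
  }
  n <- length(classifiedPerSample)
  perSample <- lapply(classifiedPerSample, function(cc) {
    disc <- rbind(cc@fp[, c("chrom", "pos", "ref", "alt")],
                  cc@fn[, c("chrom", "pos", "ref", "alt")])
    unique(paste(disc$chrom, disc$pos, disc$ref, disc$alt, sep = "\r"))
  })
  tab <- table(unlist(perSample))
  frac <- as.numeric(tab) / n
  keep <- frac >= minFraction - 1e-12
  if (!any(keep)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(tab)[keep], "\r", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4),
    fraction = frac[keep],
    stringsAsFactors = FALSE)
}
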