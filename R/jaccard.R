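#' Jaccard similarity between two call sets
#'
#' |A intersect B| / |A union B| over exact (chrom, pos, ref, alt, genotype)
#' keys, restricted to a comparison region. Two call sets that both call
#' nothing in the region agree perfectly (Jaccard 1).
#'
#' @param a,b \code{CallSet}s (replicates of the same sample).
#' @param region comparison region \code{GRanges}; \code{NULL} for no
#'   restriction.
#' @return proportion in [0, 1].
#' @export
jaccard <- function(a, b, region = NULL) {
  va <- variants(a); vb <- variants(b)
  if (!is.null(region)) {
    va <- va[.inRegion(va$chrom, va$pos, region), , drop = FALSE]
    vb <- vb[.inRegion(vb$chrom, vb$pos, region), , drop = FALSE]
  }
  ka <- .variantKey(va); kb <- .variantKey(vb)
  u <- length(union(ka, kb))
  if (u == 0) return(1)
  length(intersect(ka, kb)) / u
}

#' Pairwise Jaccard matrix over replicate call sets
#'
#' Computes the Jaccard similarity for every pair of call sets that share a
#' sample; pairs of different samples are left undefined (\code{NA}).
#'
#' @param evalSets named list of \code{CallSet}s keyed
#'   \code{"lab:replicate:sample"} (as produced by
#'   \code{\link{generateCohort}}); lab/replicate/sample are read from the
#'   call sets themselves.
#' @param region optional comparison region \code{GRanges}.
#' @return a \code{\link{JaccardMatrix}}.
#' @export
pairwiseJaccard <- function(evalSets, region = NULL) {
  n <- length(evalSets)
  labels <- data.frame(
    lab = vapply(evalSets, function(cs) cs@lab %||% NA_character_, ""),
    replicate = vapply(evalSets, function(cs) cs@replicate %||%
                         NA_character_, ""),
    sample = vapply(evalSets, sampleId, ""),
    stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  if (max(table(labels$sample)) < 2) {
    stop("need at least 2 call sets for some sample")
  }
  keys <- lapply(evalSets, function(cs) {
    v <- variants(cs)
    if (!is.null(region)) {
      v <- v[.inRegion(v$chrom, v$pos, region), , drop = FALSE]
    }
    .variantKey(v)
  })
  m <- matrix(NA_real_, n, n)
  diag(m) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels$sample[i] != labels$sample[j]) next
      u <- length(union(keys[[i]], keys[[j]]))
      m[i, j] <- m[j, i] <-
        if (u == 0) 1 else length(intersect(keys[[i]], keys[[j]])) / u
    }
  }
  rn <- paste(labels$lab, labels$replicate, labels$sample, sep = ":")
  dimnames(m) <- list(rn, rn)
  new("JaccardMatrix", labels = labels, values = m,
      region = if (is.null(region)) GenomicRanges::GRanges() else region)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Defined same-sample pairs of a JaccardMatrix as (i, j, value, sample).
.jaccardPairs <- function(jm) {
  idx <- which(upper.tri(jm@values) & !is.na(jm@values), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             value = jm@values[idx],
             sample = jm@labels$sample[idx[, 1]],
             stringsAsFactors = FALSE)
}

#' Permutation test of inter-laboratory equivalence
#'
#' Tests whether between-lab variability exceeds within-lab variability. The
#' statistic is mean(within-lab pairwise Jaccard) minus mean(between-lab
#' pairwise Jaccard); the null distribution is obtained by permuting lab
#' labels across the (lab, replicate) units within each sample. The reported
#' p-value is one-sided for "between labs worse than within labs"
#' (large positive statistic).
#'
#' @param jm a \code{\link{JaccardMatrix}}.
#' @param nPermutations number of label permutations (> 0).
#' @param seed integer RNG seed.
#' @return an \code{\link{EquivalenceTestResult}}.
#' @export
testInterlabEquivalence <- function(jm, nPermutations = 999L, seed = 1L) {
  stopifnot(is(jm, "JaccardMatrix"))
  if (nPermutations < 1) stop("nPermutations must be positive")
  labs <- jm@labels$lab
  samples <- jm@labels$sample
  if (length(unique(labs)) < 2) stop("need call sets from at least 2 labs")
  pairs <- .jaccardPairs(jm)
  if (nrow(pairs) == 0) stop("no defined same-sample pairs")

  statFor <- function(labVec) {
    within <- labVec[pairs$i] == labVec[pairs$j]
    if (!any(within) || all(within)) return(NA_real_)
    mean(pairs$value[within]) - mean(pairs$value[!within])
  }
  obsWithin <- labs[pairs$i] == labs[pairs$j]
  if (!any(obsWithin)) {
    stop("no within-lab pairs: need >= 2 replicates in at least one lab")
  }
  mw <- mean(pairs$value[obsWithin])
  mb <- mean(pairs$value[!obsWithin])
  obs <- mw - mb

  perms <- .withSeed(seed, {
    vapply(seq_len(nPermutations), function(k) {
      newLabs <- labs
      for (s in unique(samples)) {
        u <- which(samples == s)
        newLabs[u] <- labs[u][sample.int(length(u))]
      }
      statFor(newLabs)
    }, numeric(1))
  })
  perms <- perms[!is.na(perms)]
  p <- (1 + sum(perms >= obs - 1e-12)) / (length(perms) + 1)
  new("EquivalenceTestResult", meanWithin = mw, meanBetween = mb,
      difference = obs, pValue = p,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}
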