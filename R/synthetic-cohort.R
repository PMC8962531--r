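#' Configure a synthetic validation cohort
#'
#' Builds a validated \code{\link{CohortConfig}}. The defaults emulate a
#' multi-lab clinical validation cohort at desk scale: a single linear region,
#' human-like variant density, a 3:1:1 SNV/insertion/deletion mix, mostly
#' heterozygous variants, and small per-type miss/false-call rates.
#'
#' @param nSamples number of samples.
#' @param regionLength simulated region length in bases.
#' @param variantRate expected truth variants per base.
#' @param typeMix named proportions over snv, insertion, deletion.
#' @param indelLengthProbs probabilities over indel lengths 1..50; default a
#'   geometric profile truncated at 50 (most events a few bases long).
#' @param hetFraction proportion of truth variants that are heterozygous.
#' @param fnRateByStratum named per-type false-negative probabilities; a
#'   \code{"default"} entry covers unnamed types.
#' @param fpRateByStratum named per-type expected false calls per base.
#' @param gtErrorRate probability a retained call has its zygosity flipped.
#' @param nLabs number of labs.
#' @param nReplicatesPerLab replicates per lab.
#' @param seed integer RNG seed.
#' @return a \code{CohortConfig}.
#' @export
cohortConfig <- function(nSamples = 10L,
                         regionLength = 100000L,
                         variantRate = 0.001,
                         typeMix = c(snv = 0.6, insertion = 0.2,
                                     deletion = 0.2),
                         indelLengthProbs = NULL,
                         hetFraction = 0.6,
                         fnRateByStratum = c(default = 0),
                         fpRateByStratum = c(default = 0),
                         gtErrorRate = 0,
                         nLabs = 1L,
                         nReplicatesPerLab = 1L,
                         seed = 1L) {
  if (is.null(indelLengthProbs)) {
    indelLengthProbs <- stats::dgeom(0:49, prob = 0.35)
    indelLengthProbs <- indelLengthProbs / sum(indelLengthProbs)
  }
  new("CohortConfig",
      nSamples = as.integer(nSamples),
      regionLength = as.integer(regionLength),
      variantRate = variantRate,
      typeMix = typeMix[c("snv", "insertion", "deletion")],
      indelLengthProbs = indelLengthProbs,
      hetFraction = hetFraction,
      fnRateByStratum = fnRateByStratum,
      fpRateByStratum = fpRateByStratum,
      gtErrorRate = gtErrorRate,
      nLabs = as.integer(nLabs),
      nReplicatesPerLab = as.integer(nReplicatesPerLab),
      seed = as.integer(seed))
}

.BASES <- c("A", "C", "G", "T")

# Draw one random base sequence as a character vector, GC balanced per target.
.randomBases <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(.BASES, n, replace = TRUE, prob = p)
}

#' Generate a reference fragment with controlled sequence features
#'
#' Draws a random background sequence at a target GC composition and splices
#' in requested homopolymer runs and tandem micro-repeats at fixed positions,
#' so that exclusion-rule scanners can be exercised against known motifs.
#'
#' @param length fragment length in bases.
#' @param gcTarget background GC proportion.
#' @param homopolymerInserts list of \code{list(base=, runLength=, position=)}
#'   (positions 1-based).
#' @param repeatInserts list of \code{list(unit=, nUnits=, position=)}.
#' @param seed integer RNG seed.
#' @return a \code{\link[Biostrings]{DNAString}}.
#' @export
generateReferenceFragment <- function(length, gcTarget = 0.41,
                                      homopolymerInserts = list(),
                                      repeatInserts = list(),
                                      seed = 1L) {
  if (length <= 0) stop("length must be positive")
  .checkProb(gcTarget, "gcTarget")
  inserts <- c(
    lapply(homopolymerInserts, function(h) {
      if (!all(strsplit(h$base, "")[[1]] %in% .BASES)) {
        stop("invalid base symbol in homopolymer insert")
      }
      list(seq = strrep(h$base, h$runLength), position = h$position)
    }),
    lapply(repeatInserts, function(r) {
      if (!all(strsplit(r$unit, "")[[1]] %in% .BASES)) {
        stop("invalid base symbol in repeat insert")
      }
      list(seq = strrep(r$unit, r$nUnits), position = r$position)
    })
  )
  if (length(inserts)) {
    spans <- do.call(rbind, lapply(inserts, function(i) {
      c(i$position, i$position + nchar(i$seq) - 1L)
    }))
    if (any(spans[, 1] < 1) || any(spans[, 2] > length)) {
      stop("inserts must fit within the fragment")
    }
    o <- order(spans[, 1])
    spans <- spans[o, , drop = FALSE]
    if (nrow(spans) > 1 &&
        any(spans[-1, 1] <= spans[-nrow(spans), 2])) {
      stop("inserts must not overlap")
    }
  }
  .withSeed(seed, {
    chars <- .randomBases(length, gcTarget)
    for (i in inserts) {
      s <- strsplit(i$seq, "")[[1]]
      chars[i$position:(i$position + length(s) - 1L)] <- s
    }
    Biostrings::DNAString(paste(chars, collapse = ""))
  })
}

#' Generate a per-site coverage matrix with engineered low-coverage pockets
#'
#' Background depths are Poisson around \code{meanDepth}; each pocket fixes
#' the depth of a run of positions in a stated fraction of the samples, so
#' coverage-rule thresholds can be tripped by construction.
#'
#' @param nSamples number of samples (columns).
#' @param positions number of positions (rows).
#' @param meanDepth background mean depth.
#' @param lowPockets list of \code{list(start=, end=, depth=,
#'   sampleFraction=)} (1-based inclusive position runs).
#' @param seed integer RNG seed.
#' @return integer matrix, positions x samples.
#' @export
generateCoverageMatrix <- function(nSamples, positions, meanDepth = 35,
                                   lowPockets = list(), seed = 1L) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  if (positions < 1) stop("positions must be >= 1")
  if (meanDepth < 0) stop("meanDepth must be non-negative")
  for (p in lowPockets) {
    if (p$start < 1 || p$end > positions || p$start > p$end) {
      stop("pocket outside the position range")
    }
    if (p$depth < 0) stop("pocket depths must be non-negative")
  }
  .withSeed(seed, {
    m <- matrix(stats::rpois(positions * nSamples, meanDepth),
                nrow = positions, ncol = nSamples)
    for (p in lowPockets) {
      k <- max(1L, round(p$sampleFraction * nSamples))
      cols <- sample(nSamples, k)
      m[p$start:p$end, cols] <- as.integer(p$depth)
    }
    dimnames(m) <- list(NULL, paste0("sample", seq_len(nSamples)))
    m
  })
}

# Sample variant positions uniformly without footprint overlap.
# maxSpan is the widest ref-allele footprint a variant may occupy.
.samplePositions <- function(n, regionLength, maxSpan = 52L,
                             forbidden = integer(0)) {
  if (n == 0) return(integer(0))
  chosen <- integer(0)
  occupied <- forbidden
  tries <- 0L
  while (length(chosen) < n && tries < 50L) {
    need <- n - length(chosen)
    cand <- sort(unique(sample.int(regionLength - maxSpan,
                                   min(need * 2L, regionLength - maxSpan))))
    for (p in cand) {
      if (length(chosen) >= n) break
      near <- occupied[abs(occupied - p) <= maxSpan]
      if (length(near) == 0) {
        chosen <- c(chosen, p)
        occupied <- c(occupied, p)
      }
    }
    tries <- tries + 1L
  }
  if (length(chosen) < n) {
    stop("could not place ", n, " non-overlapping variants in ",
         regionLength, " bases")
  }
  sort(chosen)
}

# Build variant records at given positions against a reference char vector.
.makeVariants <- function(pos, refChars, config) {
  n <- length(pos)
  if (n == 0) return(.emptyVariants())
  type <- sample(names(config@typeMix), n, replace = TRUE,
                 prob = config@typeMix)
  genotype <- ifelse(stats::runif(n) < config@hetFraction, "het", "hom_alt")
  ref <- character(n)
  alt <- character(n)
  indelLen <- sample.int(50L, n, replace = TRUE,
                         prob = config@indelLengthProbs)
  for (i in seq_len(n)) {
    p <- pos[i]
    anchor <- refChars[p]
    if (type[i] == "snv") {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(.BASES, anchor), 1)
    } else if (type[i] == "insertion") {
      ref[i] <- anchor
      alt[i] <- paste(c(anchor, sample(.BASES, indelLen[i], replace = TRUE)),
                      collapse = "")
    } else {
      span <- refChars[p:(p + indelLen[i])]
      ref[i] <- paste(span, collapse = "")
      alt[i] <- anchor
    }
  }
  data.frame(chrom = "region", pos = as.integer(pos), ref = ref, alt = alt,
             genotype = genotype, stringsAsFactors = FALSE)
}

# Random labeled context intervals covering roughly `coverFraction` of the
# region each.
.makeContexts <- function(regionLength, coverFraction = 0.1) {
  labs <- c("segdup", "low_complexity", "high_gc")
  out <- list()
  for (lab in labs) {
    k <- 8L
    w <- max(10L, floor(regionLength * coverFraction / k))
    starts <- sort(sample.int(max(1L, regionLength - w), k))
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      "region", IRanges::IRanges(start = starts, width = w)))
    out[[lab]] <- gr
  }
  out
}

#' Generate a complete synthetic validation cohort
#'
#' Produces every input the validation pipeline consumes: a reference
#' fragment, per-sample truth call sets, per-(lab, replicate, sample)
#' evaluation call sets derived from truth by seeded error injection, labeled
#' genomic-context intervals, and a coverage matrix.
#'
#' Error injection follows the configured rates: each truth variant is
#' dropped with its per-type false-negative probability; retained calls have
#' their zygosity flipped (het to hom-alt and back) with probability
#' \code{gtErrorRate} while staying at the truth site with the truth alt
#' allele; false calls are added at reference positions not in truth, drawn
#' with the same type mix.
#'
#' @param config a \code{\link{CohortConfig}}.
#' @return a \code{\link{SyntheticCohort}}.
#' @export
generateCohort <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    refChars <- .randomBases(config@regionLength, gc = 0.41)
    reference <- Biostrings::DNAString(paste(refChars, collapse = ""))
    contexts <- .makeContexts(config@regionLength)

    sampleIds <- sprintf("S%03d", seq_len(config@nSamples))
    truth <- list()
    for (s in sampleIds) {
      nVar <- stats::rbinom(1L, config@regionLength, config@variantRate)
      pos <- .samplePositions(nVar, config@regionLength)
      truth[[s]] <- CallSet(s, .makeVariants(pos, refChars, config))
    }

    evalSets <- list()
    for (lab in sprintf("lab%d", seq_len(config@nLabs))) {
      for (rep in sprintf("r%d", seq_len(config@nReplicatesPerLab))) {
        for (s in sampleIds) {
          tv <- variants(truth[[s]])
          if (nrow(tv)) {
            type <- .variantType(tv$ref, tv$alt)
            fnp <- vapply(type, function(t) {
              .rateFor(config@fnRateByStratum, t)
            }, numeric(1))
            keep <- stats::runif(nrow(tv)) >= fnp
            ev <- tv[keep, , drop = FALSE]
            if (nrow(ev) && config@gtErrorRate > 0) {
              flip <- stats::runif(nrow(ev)) < config@gtErrorRate
              ev$genotype[flip] <- ifelse(ev$genotype[flip] == "het",
                                          "hom_alt", "het")
            }
          } else {
            ev <- tv
          }
          # false calls at positions clear of the truth footprints
          fpTotal <- 0L
          fpByType <- c(snv = 0L, insertion = 0L, deletion = 0L)
          for (t in names(fpByType)) {
            rate <- .rateFor(config@fpRateByStratum, t)
            fpByType[[t]] <- stats::rpois(1L, rate * config@regionLength)
          }
          fpTotal <- sum(fpByType)
          if (fpTotal > 0) {
            fpPos <- .samplePositions(fpTotal, config@regionLength,
                                      forbidden = tv$pos)
            fpCfg <- config
            fpCfg@typeMix <- (fpByType / fpTotal)[c("snv", "insertion",
                                                    "deletion")]
            fpv <- .makeVariants(fpPos, refChars, fpCfg)
            ev <- rbind(ev, fpv)
          }
          key <- paste(lab, rep, s, sep = ":")
          evalSets[[key]] <- CallSet(s, ev, lab = lab, replicate = rep)
        }
      }
    }

    covPositions <- min(config@regionLength, 2000L)
    coverage <- generateCoverageMatrix(config@nSamples, covPositions,
                                       meanDepth = 35,
                                       seed = config@seed + 1L)
    new("SyntheticCohort", truth = truth, evalSets = evalSets,
        contexts = contexts, reference = reference, coverage = coverage,
        config = config)
  })
}

#' Generate a synthetic PGx cohort from assigned diplotypes
#'
#' Each sample's call set contains exactly the defining variants of its two
#' assigned star alleles, homozygous where both haplotypes carry the variant
#' and heterozygous otherwise.
#'
#' @param table a \code{\link{StarAlleleTable}}.
#' @param diplotypeAssignments named list mapping sample to a character
#'   vector of two allele names.
#' @param seed integer RNG seed (reserved; generation is deterministic).
#' @return named list of \code{CallSet}s.
#' @export
generatePgxCohort <- function(table, diplotypeAssignments, seed = 1L) {
  validObject(table)
  out <- list()
  for (s in names(diplotypeAssignments)) {
    dip <- diplotypeAssignments[[s]]
    if (length(dip) != 2) stop("each assignment must name two alleles")
    unknown <- setdiff(dip, names(table@alleles))
    if (length(unknown)) {
      stop("unknown allele name(s): ", paste(unknown, collapse = ", "))
    }
    v1 <- table@alleles[[dip[1]]]
    v2 <- table@alleles[[dip[2]]]
    k1 <- paste(v1$chrom, v1$pos, v1$ref, v1$alt)
    k2 <- paste(v2$chrom, v2$pos, v2$ref, v2$alt)
    all <- rbind(v1, v2)
    keys <- c(k1, k2)
    if (nrow(all)) {
      uniq <- !duplicated(keys)
      gt <- ifelse(keys[uniq] %in% k1 & keys[uniq] %in% k2,
                   "hom_alt", "het")
      vr <- all[uniq, , drop = FALSE]
      vr$genotype <- gt
    } else {
      vr <- .emptyVariants()
    }
    out[[s]] <- CallSet(s, vr)
  }
  out
}
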