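#' Genotype-caller configuration
#'
#' A minimal binomial-likelihood diploid genotype caller over site-level
#' read counts: the alternate-allele fraction is modeled as
#' \code{baseError} under hom-ref, 0.5 under het and \code{1 - baseError}
#' under hom-alt, with a uniform genotype prior.
#'
#' @param baseError per-read error probability (0 < baseError < 0.5).
#' @return list of class \code{"GenotypeCallerConfig"}.
#' @export
genotypeCallerConfig <- function(baseError = 0.01) {
  if (baseError <= 0 || baseError >= 0.5) {
    stop("baseError must lie in (0, 0.5)")
  }
  structure(list(baseError = baseError,
                 afModels = c(hom_ref = baseError, het = 0.5,
                              hom_alt = 1 - baseError)),
            class = "GenotypeCallerConfig")
}

# Decision table: called genotype for each alt count 0..depth at this depth.
.callTable <- function(depth, config) {
  k <- 0:depth
  ll <- vapply(config$afModels, function(af) {
    stats::dbinom(k, depth, af, log = TRUE)
  }, numeric(depth + 1))
  # ties break toward the earliest column: hom_ref, then het, then hom_alt
  apply(ll, 1, function(row) names(config$afModels)[
    which(row >= max(row) - 1e-9)[1]])
}

#' Call a genotype from site-level read counts
#'
#' Argmax over the three binomial likelihoods; ties break toward hom-ref
#' (the call producing the fewest reportable variants). Depth 0 yields a
#' no-call (\code{NA}).
#'
#' @param depth total read depth (vectorized).
#' @param altReads alternate-supporting read count (vectorized).
#' @param config a \code{\link{genotypeCallerConfig}}.
#' @return character vector of calls (hom_ref / het / hom_alt, or \code{NA}
#'   for depth 0).
#' @export
callGenotype <- function(depth, altReads, config = genotypeCallerConfig()) {
  if (any(altReads > depth) || any(altReads < 0)) {
    stop("altReads must lie in [0, depth]")
  }
  out <- rep(NA_character_, length(depth))
  for (d in unique(depth[depth >= 1])) {
    tab <- .callTable(d, config)
    idx <- which(depth == d)
    out[idx] <- tab[altReads[idx] + 1L]
  }
  out
}

#' Simulate site observations for a sample
#'
#' Draws per-site read counts for a set of sites with known truth genotypes
#' at a given mean depth: depth is Poisson, alt reads are binomial at the
#' truth genotype's model allele fraction.
#'
#' @param nSites number of sites.
#' @param meanDepth mean sequencing depth.
#' @param genotypeProbs named probabilities over hom_ref, het, hom_alt truth
#'   genotypes.
#' @param config caller configuration (supplies the allele-fraction models).
#' @param seed integer RNG seed.
#' @return data.frame with columns chrom, pos, ref, alt, depth, altReads,
#'   truthGenotype.
#' @export
simulateSiteObservations <- function(nSites, meanDepth = 40,
                                     genotypeProbs = c(hom_ref = 0.25,
                                                       het = 0.5,
                                                       hom_alt = 0.25),
                                     config = genotypeCallerConfig(),
                                     seed = 1L) {
  if (nSites < 1) stop("nSites must be >= 1")
  .withSeed(seed, {
    gt <- sample(names(genotypeProbs), nSites, replace = TRUE,
                 prob = genotypeProbs)
    depth <- stats::rpois(nSites, meanDepth)
    af <- config$afModels[gt]
    alt <- stats::rbinom(nSites, depth, af)
    data.frame(chrom = "region", pos = seq_len(nSites), ref = "A", alt = "G",
               depth = depth, altReads = alt, truthGenotype = gt,
               stringsAsFactors = FALSE)
  })
}

# Sensitivity: fraction of non-hom-ref truth sites recalled with the exact
# truth genotype.
.sensitivity <- function(obs, config) {
  pos <- obs$truthGenotype != "hom_ref"
  if (!any(pos)) return(NA_real_)
  called <- callGenotype(obs$depth, obs$altReads, config)
  mean(!is.na(called[pos]) & called[pos] == obs$truthGenotype[pos])
}

# Genotype error rate: fraction of all sites whose call differs from truth
# (no-calls count as errors).
.gtErrorRate <- function(obs, config) {
  called <- callGenotype(obs$depth, obs$altReads, config)
  mean(is.na(called) | called != obs$truthGenotype)
}

# Joint thinning of (depth, alt) at retention fraction f: the retained total
# is Binomial(depth, f) and the retained alt count is hypergeometric given
# the total, which is exactly uniform read removal.
.thinObservations <- function(obs, f) {
  newDepth <- stats::rbinom(nrow(obs), obs$depth, f)
  newAlt <- integer(nrow(obs))
  nz <- newDepth > 0
  newAlt[nz] <- stats::rhyper(sum(nz), m = obs$altReads[nz],
                              n = obs$depth[nz] - obs$altReads[nz],
                              k = newDepth[nz])
  obs$depth <- newDepth
  obs$altReads <- newAlt
  obs
}

#' Sensitivity under coverage downsampling
#'
#' At each retention fraction, every site's reads are thinned uniformly
#' (binomial total, hypergeometric alt count) and the genotype caller is
#' re-run; the metric is the fraction of non-hom-ref truth sites recalled
#' with the correct genotype, averaged over replicates.
#'
#' @param observations site observation data.frame (see
#'   \code{\link{simulateSiteObservations}}).
#' @param fractions retention fractions in (0, 1].
#' @param config caller configuration.
#' @param replicates thinning replicates per fraction.
#' @param seed integer RNG seed.
#' @return a \code{\link{DegradationCurve}} (axis downsample_fraction).
#' @export
downsampleCurve <- function(observations, fractions,
                            config = genotypeCallerConfig(),
                            replicates = 5L, seed = 1L) {
  if (nrow(observations) == 0) stop("empty observation list")
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  fractions <- sort(fractions)
  .withSeed(seed, {
    per <- matrix(NA_real_, nrow = replicates, ncol = length(fractions))
    for (r in seq_len(replicates)) {
      for (i in seq_along(fractions)) {
        thinned <- if (fractions[i] == 1) observations else
          .thinObservations(observations, fractions[i])
        per[r, i] <- .sensitivity(thinned, config)
      }
    }
    new("DegradationCurve", axis = "downsample_fraction",
        levels = fractions, metric = "sensitivity",
        values = colMeans(per), perReplicate = per,
        replicates = as.integer(replicates), seed = as.integer(seed),
        band = numeric(0))
  })
}

#' Sensitivity under duplicate injection
#'
#' Adding duplicates at a fixed yield reduces the unique read depth: the
#' effective unique depth at duplicate rate r is Binomial(depth, 1 - r),
#' which is by construction the same degradation as downsampling at
#' retention 1 - r. The curve is computed through the same seeded pipeline,
#' so \code{duplicateRates = 0.5} and \code{fractions = 0.5} with the same
#' seed give identical curves.
#'
#' @param observations site observation data.frame.
#' @param duplicateRates duplicate rates in [0, 1).
#' @param config caller configuration.
#' @param replicates replicates per rate.
#' @param seed integer RNG seed.
#' @return a \code{\link{DegradationCurve}} (axis duplicate_rate).
#' @export
duplicateInjectionCurve <- function(observations, duplicateRates,
                                    config = genotypeCallerConfig(),
                                    replicates = 5L, seed = 1L) {
  if (any(duplicateRates < 0 | duplicateRates >= 1)) {
    stop("duplicate rates must lie in [0, 1)")
  }
  base <- downsampleCurve(observations, fractions = 1 - duplicateRates,
                          config = config, replicates = replicates,
                          seed = seed)
  # retention 1 - r sorts opposite to r: flip back to sorted rates
  ord <- order(1 - base@levels)
  new("DegradationCurve", axis = "duplicate_rate",
      levels = (1 - base@levels)[ord], metric = "sensitivity",
      values = base@values[ord],
      perReplicate = base@perReplicate[, ord, drop = FALSE],
      replicates = base@replicates, seed = base@seed, band = numeric(0))
}

#' Bioinformatic cross-sample contamination
#'
#' Redraws each site's alt count from a read-level mixture: a read reflects
#' the contaminant genotype's expected allele fraction with probability
#' \code{alpha} and the host's otherwise; depth is preserved.
#'
#' @param host site observation data.frame (truthGenotype = host genotype).
#' @param contaminantGenotypes character vector of contaminant genotypes,
#'   one per host site.
#' @param alpha contaminating fraction in [0, 1).
#' @param config caller configuration (supplies allele-fraction models).
#' @param seed integer RNG seed.
#' @return contaminated observation data.frame (truth genotypes unchanged).
#' @export
contaminate <- function(host, contaminantGenotypes, alpha,
                        config = genotypeCallerConfig(), seed = 1L) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)")
  if (length(contaminantGenotypes) != nrow(host)) {
    stop("contaminant genotypes must align with the host sites")
  }
  .withSeed(seed, {
    afHost <- config$afModels[host$truthGenotype]
    afCont <- config$afModels[contaminantGenotypes]
    p <- (1 - alpha) * afHost + alpha * afCont
    host$altReads <- stats::rbinom(nrow(host), host$depth, p)
    host
  })
}

#' Estimate the contaminating fraction from homozygous sites
#'
#' Over sites the caller labels homozygous, the non-consensus allele
#' fraction (alt fraction at hom-ref calls, ref fraction at hom-alt calls)
#' reflects half the contaminating fraction plus sequencing error; the
#' estimate is \code{max(0, 2 * (median_ncf - baseError))}.
#'
#' @param observations site observation data.frame.
#' @param config caller configuration.
#' @param minHomSites minimum homozygous-called sites required (default 100).
#' @return estimated contaminating fraction.
#' @export
estimateContamination <- function(observations,
                                  config = genotypeCallerConfig(),
                                  minHomSites = 100L) {
  called <- callGenotype(observations$depth, observations$altReads, config)
  hom <- !is.na(called) & called %in% c("hom_ref", "hom_alt")
  if (sum(hom) < minHomSites) {
    stop("need at least ", minHomSites, " homozygous-called sites")
  }
  o <- observations[hom, , drop = FALSE]
  g <- called[hom]
  ncf <- ifelse(g == "hom_ref", o$altReads / o$depth,
                (o$depth - o$altReads) / o$depth)
  max(0, 2 * (stats::median(ncf) - config$baseError))
}

#' Heterozygous-call accuracy across allele fractions (limit of detection)
#'
#' At each allele fraction, simulates het-truth sites with binomial alt
#' counts at fixed depth and records the fraction called heterozygous. The
#' reported band is the longest contiguous run of grid levels whose accuracy
#' stays at or above \code{bandThreshold}.
#'
#' @param depth read depth.
#' @param afGrid allele fractions in (0, 1).
#' @param nSites simulated sites per level.
#' @param config caller configuration.
#' @param bandThreshold accuracy the band must sustain (default 0.99).
#' @param seed integer RNG seed.
#' @return a \code{\link{DegradationCurve}} (axis allele_fraction, metric
#'   het_call_accuracy) with the band in \code{curveBand()}.
#' @export
lodAlleleFraction <- function(depth, afGrid = seq(0.05, 0.95, by = 0.05),
                              nSites = 2000L,
                              config = genotypeCallerConfig(),
                              bandThreshold = 0.99, seed = 1L) {
  if (length(afGrid) == 0) stop("empty allele-fraction grid")
  if (any(afGrid <= 0 | afGrid >= 1)) stop("afGrid must lie in (0, 1)")
  afGrid <- sort(afGrid)
  acc <- .withSeed(seed, {
    tab <- .callTable(depth, genotypeCallerConfig(config$baseError))
    vapply(afGrid, function(af) {
      alt <- stats::rbinom(nSites, depth, af)
      mean(tab[alt + 1L] == "het")
    }, numeric(1))
  })
  ok <- acc >= bandThreshold
  band <- numeric(0)
  if (any(ok)) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    band <- c(afGrid[starts[best]], afGrid[ends[best]])
  }
  new("DegradationCurve", axis = "allele_fraction", levels = afGrid,
      metric = "het_call_accuracy", values = acc,
      perReplicate = matrix(acc, nrow = 1), replicates = 1L,
      seed = as.integer(seed), band = band)
}

#' Select a QC threshold from a degradation curve
#'
#' Scans levels from least to most degraded (for downsampling, from the
#' highest retention downward; for contamination and duplicates, from zero
#' upward), stops at the first level whose metric falls below
#' \code{minMetric}, and returns the most-degraded level passed before the
#' stop. Returns \code{NA} if no level qualifies.
#'
#' @param curve a \code{\link{DegradationCurve}}.
#' @param minMetric minimum acceptable metric value.
#' @return the selected threshold level, or \code{NA}.
#' @export
selectThreshold <- function(curve, minMetric) {
  stopifnot(is(curve, "DegradationCurve"))
  ord <- if (curve@axis == "downsample_fraction") {
    order(curve@levels, decreasing = TRUE)
  } else {
    order(curve@levels)
  }
  levels <- curve@levels[ord]
  values <- curve@values[ord]
  last <- NA_real_
  for (i in seq_along(levels)) {
    if (is.na(values[i]) || values[i] < minMetric) break
    last <- levels[i]
  }
  last
}
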