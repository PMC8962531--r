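#' Exclusion-rule configuration for reportable-range construction
#'
#' @param gcThreshold GC fraction above which (strictly) a window is
#'   excluded (default 0.75).
#' @param gcWindow sliding window width in bases (default 100, step 1).
#' @param homopolymerMinRun minimum homopolymer run length to exclude
#'   (default 10).
#' @param microrepeatUnits tandem-repeat unit lengths scanned (default 2:3).
#' @param microrepeatMinUnits minimum number of tandem units to exclude
#'   (default 6).
#' @param namedExclusions \code{GRanges} of regions excluded by name (e.g.
#'   pseudogene-homology regions); supplied as input, not detected.
#' @return a list of class \code{"ExclusionRuleConfig"}.
#' @export
exclusionConfig <- function(gcThreshold = 0.75, gcWindow = 100L,
                            homopolymerMinRun = 10L,
                            microrepeatUnits = c(2L, 3L),
                            microrepeatMinUnits = 6L,
                            namedExclusions = GenomicRanges::GRanges()) {
  if (gcWindow <= 0) stop("gcWindow must be positive")
  if (gcThreshold <= 0 || gcThreshold > 1) {
    stop("gcThreshold must lie in (0, 1]")
  }
  structure(list(gcThreshold = gcThreshold, gcWindow = as.integer(gcWindow),
                 homopolymerMinRun = as.integer(homopolymerMinRun),
                 microrepeatUnits = as.integer(microrepeatUnits),
                 microrepeatMinUnits = as.integer(microrepeatMinUnits),
                 namedExclusions = namedExclusions),
            class = "ExclusionRuleConfig")
}

#' Pad transcript exons, strand-aware
#'
#' Extends each exon by \code{upstreamPad} bases on its transcription-5'
#' side and \code{downstreamPad} on its 3' side (so on the minus strand the
#' genomic-left pad is the downstream pad), clamps at the first coordinate,
#' and merges overlapping padded exons.
#'
#' @param transcript a \code{\link{TranscriptModel}}.
#' @param upstreamPad bases of upstream-intronic padding (default 15).
#' @param downstreamPad bases of downstream-intronic padding (default 6).
#' @return \code{GRanges} of merged padded exons.
#' @export
padExons <- function(transcript, upstreamPad = 15L, downstreamPad = 6L) {
  validObject(transcript)
  e <- transcript@exons
  if (transcript@strand == "+") {
    left <- upstreamPad; right <- downstreamPad
  } else {
    left <- downstreamPad; right <- upstreamPad
  }
  starts <- pmax(1L, IRanges::start(e) - left)
  ends <- IRanges::end(e) + right
  gr <- GenomicRanges::GRanges(transcript@chrom,
                               IRanges::IRanges(starts, ends))
  GenomicRanges::reduce(gr)
}

#' Add single-base site intervals to an interval set
#'
#' Each 1-based site not already covered is appended as a width-1 interval;
#' covered sites are no-ops. Annotations distinguish the origin of each
#' interval.
#'
#' @param base annotated \code{GRanges} (an \code{annotation} metadata column
#'   is added as "exon_padded" if absent).
#' @param plpSites,pgxSites integer vectors of 1-based positions.
#' @param chrom sequence name for the added sites.
#' @return \code{GRanges} with an \code{annotation} column.
#' @export
addSites <- function(base, plpSites = integer(0), pgxSites = integer(0),
                     chrom = "region") {
  if (is.null(base$annotation)) base$annotation <- "exon_padded"
  addOne <- function(gr, sites, label) {
    if (length(sites) == 0) return(gr)
    s <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(sites, width = 1L))
    outside <- GenomicRanges::countOverlaps(s, gr) == 0
    if (any(outside)) {
      add <- s[outside]
      add$annotation <- label
      gr <- c(gr, add)
    }
    gr
  }
  out <- addOne(base, unique(plpSites), "plp_site")
  out <- addOne(out, unique(pgxSites), "pgx_site")
  GenomicRanges::sort(out)
}

# Maximal periodic stretches with period u covering >= minUnits units.
.tandemRepeats <- function(chars, u, minUnits) {
  n <- length(chars)
  if (n < u * minUnits) return(IRanges::IRanges())
  match <- chars[(u + 1):n] == chars[1:(n - u)]
  r <- rle(match)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + u) >= u * minUnits
  if (!any(keep)) return(IRanges::IRanges())
  IRanges::IRanges(start = starts[keep], end = ends[keep] + u)
}

#' Scan a reference fragment for excludable technically challenging regions
#'
#' Returns the union of (a) named exclusions from the configuration, (b)
#' positions covered by any sliding GC window whose GC fraction strictly
#' exceeds the threshold, (c) homopolymer runs at or above the minimum run
#' length, and (d) tandem di-/tri-nucleotide repeats with at least the
#' minimum unit count.
#'
#' @param reference \code{DNAString} or character.
#' @param config an \code{\link{exclusionConfig}}.
#' @param chrom sequence name for the returned intervals.
#' @return \code{GRanges} with a \code{rule} metadata column.
#' @export
scanExclusions <- function(reference, config = exclusionConfig(),
                           chrom = "region") {
  seq <- Biostrings::DNAString(as.character(reference))
  n <- length(seq)
  if (config$gcWindow > n) stop("gcWindow is longer than the reference")
  chars <- strsplit(as.character(seq), "")[[1]]
  pieces <- list()

  gc <- Biostrings::letterFrequencyInSlidingView(seq, config$gcWindow, "GC")
  hot <- which(gc[, 1] / config$gcWindow > config$gcThreshold)
  if (length(hot)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(hot, width = config$gcWindow)))
    gr$rule <- "high_gc"
    pieces <- c(pieces, list(gr))
  }

  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= config$homopolymerMinRun
  if (any(keep)) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
      start = ends[keep] - r$lengths[keep] + 1L, end = ends[keep]))
    gr$rule <- "homopolymer"
    pieces <- c(pieces, list(gr))
  }

  for (u in config$microrepeatUnits) {
    ir <- .tandemRepeats(chars, u, config$microrepeatMinUnits)
    if (length(ir)) {
      gr <- GenomicRanges::GRanges(chrom, ir)
      gr$rule <- paste0("microrepeat_", u)
      pieces <- c(pieces, list(gr))
    }
  }

  if (length(config$namedExclusions)) {
    gr <- config$namedExclusions
    if (is.null(gr$rule)) gr$rule <- "named"
    pieces <- c(pieces, list(gr))
  }
  if (length(pieces) == 0) {
    out <- GenomicRanges::GRanges()
    out$rule <- character(0)
    return(out)
  }
  GenomicRanges::sort(do.call(c, pieces))
}

#' Flag consistently low-coverage positions
#'
#' Flags maximal runs of positions where the fraction of samples with depth
#' strictly below \code{depthThreshold} is at least \code{sampleFraction}.
#'
#' @param matrix depth matrix, positions x samples.
#' @param depthThreshold minimum acceptable depth (default 20).
#' @param sampleFraction sample fraction at or above which a position is
#'   flagged (default 0.20; the rule is >=).
#' @param chrom sequence name.
#' @param offset 0-based offset of the first matrix row (default 0, i.e. the
#'   first row is position 1).
#' @return \code{GRanges} of merged flagged runs.
#' @export
coverageFlag <- function(matrix, depthThreshold = 20L,
                         sampleFraction = 0.20, chrom = "region",
                         offset = 0L) {
  if (!is.matrix(matrix) || ncol(matrix) < 1 || nrow(matrix) < 1) {
    stop("need a non-empty positions x samples depth matrix")
  }
  fracLow <- rowMeans(matrix < depthThreshold)
  flag <- fracLow >= sampleFraction - 1e-12
  if (!any(flag)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(which(flag) + offset, width = 1L)))
}

#' Build the reportable range
#'
#' Pipeline: pad exons (strand-aware), add P/LP and PGx single-base sites
#' outside the padded exons, subtract scanned exclusions, and annotate (not
#' subtract) low-coverage flags. Requested sites that fall inside an
#' exclusion are surfaced in the conflict report rather than silently
#' dropped or retained.
#'
#' @param transcripts list of \code{\link{TranscriptModel}}s.
#' @param plpSites,pgxSites 1-based positions of known P/LP variants and PGx
#'   star-allele sites.
#' @param reference reference fragment for exclusion scanning; \code{NULL}
#'   to skip sequence-based exclusions.
#' @param config an \code{\link{exclusionConfig}}.
#' @param coverageMatrix optional depth matrix for coverage flagging.
#' @param upstreamPad,downstreamPad exon padding in bases.
#' @param depthThreshold,sampleFraction coverage-rule parameters.
#' @param chrom sequence name.
#' @return a \code{\link{ReportableRange}}.
#' @export
buildReportableRange <- function(transcripts, plpSites = integer(0),
                                 pgxSites = integer(0), reference = NULL,
                                 config = exclusionConfig(),
                                 coverageMatrix = NULL,
                                 upstreamPad = 15L, downstreamPad = 6L,
                                 depthThreshold = 20L, sampleFraction = 0.20,
                                 chrom = "region") {
  padded <- lapply(transcripts, padExons, upstreamPad = upstreamPad,
                   downstreamPad = downstreamPad)
  base <- GenomicRanges::reduce(do.call(c, padded))
  base$annotation <- "exon_padded"
  augmented <- addSites(base, plpSites, pgxSites, chrom = chrom)

  exclusions <- if (is.null(reference)) {
    gr <- GenomicRanges::GRanges(); gr$rule <- character(0); gr
  } else {
    scanExclusions(reference, config, chrom = chrom)
  }

  conflicts <- data.frame(pos = integer(0), type = character(0),
                          rule = character(0), stringsAsFactors = FALSE)
  for (siteSet in list(list(plpSites, "plp_site"),
                       list(pgxSites, "pgx_site"))) {
    sites <- unique(siteSet[[1]])
    if (length(sites) == 0 || length(exclusions) == 0) next
    sgr <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(sites, width = 1L))
    hits <- GenomicRanges::findOverlaps(sgr, exclusions)
    if (length(hits)) {
      conflicts <- rbind(conflicts, data.frame(
        pos = sites[S4Vectors::queryHits(hits)],
        type = siteSet[[2]],
        rule = exclusions$rule[S4Vectors::subjectHits(hits)],
        stringsAsFactors = FALSE))
    }
  }

  # subtract exclusions per annotation label so labels survive the cut
  pieces <- list()
  for (lab in unique(augmented$annotation)) {
    part <- augmented[augmented$annotation == lab]
    kept <- GenomicRanges::setdiff(GenomicRanges::reduce(part),
                                   GenomicRanges::reduce(exclusions))
    if (length(kept)) {
      kept$annotation <- lab
      pieces <- c(pieces, list(kept))
    }
  }
  final <- if (length(pieces)) GenomicRanges::sort(do.call(c, pieces)) else {
    gr <- GenomicRanges::GRanges(); gr$annotation <- character(0); gr
  }

  flags <- if (is.null(coverageMatrix)) GenomicRanges::GRanges() else {
    coverageFlag(coverageMatrix, depthThreshold, sampleFraction,
                 chrom = chrom)
  }

  new("ReportableRange", intervals = final,
      exclusionsApplied = exclusions, coverageFlags = flags,
      conflicts = conflicts,
      totalBases = sum(GenomicRanges::width(final)))
}
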