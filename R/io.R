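#' Write a CallSet as minimal VCF 4.2
#'
#' One sample per file; GT-only FORMAT; unphased diploid genotypes
#' (0/1 for het, 1/1 for hom-alt). The generating seed, when supplied, is
#' recorded in a header line so every emitted file carries its provenance.
#'
#' @param callset a \code{CallSet}.
#' @param path output path.
#' @param seed optional integer seed recorded in the header.
#' @return invisibly, the path.
#' @export
writeCallSet <- function(callset, path, seed = NULL) {
  stopifnot(is(callset, "CallSet"))
  v <- variants(callset)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=VariantAgreement",
    if (!is.null(seed)) paste0("##seed=", as.integer(seed)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId(callset), sep = "\t")
  )
  body <- if (nrow(v)) {
    gt <- ifelse(v$genotype == "het", "0/1", "1/1")
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT", gt,
          sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a CallSet from a minimal VCF
#'
#' Single-sample VCF with GT in FORMAT. Multi-allelic records are split into
#' one record per alternate allele with the implied zygosity (a 1/2 genotype
#' becomes two heterozygous records). Missing genotypes (./.) are skipped
#' with a warning; half-calls are rejected. Unsorted records are sorted with
#' a warning.
#'
#' @param path VCF path.
#' @param lab,replicate optional provenance to attach.
#' @return a \code{CallSet}.
#' @export
readCallSet <- function(path, lab = NULL, replicate = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gtMat <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gtMat) || ncol(gtMat) != 1) {
    stop("expected a single-sample VCF with GT in FORMAT")
  }
  sample <- colnames(gtMat)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    gtStr <- gtMat[i, 1]
    if (is.na(gtStr) || gtStr %in% c("./.", ".|.", ".")) {
      warning("skipping record with missing genotype at ",
              fix[i, "CHROM"], ":", fix[i, "POS"])
      next
    }
    alleles <- strsplit(gsub("\\|", "/", gtStr), "/", fixed = FALSE)[[1]]
    if (length(alleles) != 2 || any(alleles == ".")) {
      stop("half-call or non-diploid genotype '", gtStr, "' at ",
           fix[i, "CHROM"], ":", fix[i, "POS"])
    }
    alleles <- as.integer(alleles)
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in unique(alleles[alleles > 0])) {
      nCopies <- sum(alleles == a)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[a],
        genotype = if (nCopies == 2) "hom_alt" else "het",
        stringsAsFactors = FALSE)
    }
  }
  v <- if (length(rows)) do.call(rbind, rows) else .emptyVariants()
  if (nrow(v) > 1 && is.unsorted(order(v$chrom, v$pos))) {
    warning("unsorted VCF records; sorting")
  }
  CallSet(sample, v, lab = lab, replicate = replicate)
}

#' BED interval I/O
#'
#' Thin wrappers over rtracklayer: BED files are 0-based half-open on disk
#' and 1-based closed \code{GRanges} in memory; the conversion happens only
#' here. A \code{name} column, when present, carries the annotation label.
#'
#' @param path BED path.
#' @param merge merge overlapping intervals on read (default FALSE).
#' @return \code{readBedFile}: a \code{GRanges}.
#' @name bed-io
NULL

#' @rdname bed-io
#' @export
readBedFile <- function(path, merge = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (merge) gr <- GenomicRanges::reduce(gr)
  gr
}

#' @rdname bed-io
#' @param gr a \code{GRanges}; an \code{annotation} metadata column is
#'   written as the BED name field.
#' @export
writeBedFile <- function(gr, path) {
  if (!is.null(gr$annotation)) gr$name <- gr$annotation
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Reference fragment I/O (FASTA)
#'
#' @param x a \code{DNAString}.
#' @param path FASTA path.
#' @param name sequence name.
#' @param seed optional seed recorded in the sequence description.
#' @return \code{readReferenceFasta}: a \code{DNAString}.
#' @name fasta-io
NULL

#' @rdname fasta-io
#' @export
writeReferenceFasta <- function(x, path, name = "region", seed = NULL) {
  set <- Biostrings::DNAStringSet(x)
  names(set) <- if (is.null(seed)) name else paste0(name, " seed=", seed)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname fasta-io
#' @export
readReferenceFasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  set[[1]]
}

#' Coverage matrix I/O (TSV)
#'
#' Rows are positions, columns samples; the seed travels in a leading
#' comment line.
#'
#' @param m integer depth matrix.
#' @param path TSV path.
#' @param seed optional seed recorded in the header comment.
#' @return \code{readCoverageMatrix}: integer matrix.
#' @name coverage-io
NULL

#' @rdname coverage-io
#' @export
writeCoverageMatrix <- function(m, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed=", as.integer(seed)), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coverage-io
#' @export
readCoverageMatrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  as.matrix(df)
}

#' Cohort configuration I/O (YAML)
#'
#' @param config a \code{\link{CohortConfig}}.
#' @param path YAML path.
#' @return \code{readCohortConfig}: a \code{CohortConfig}.
#' @name config-io
NULL

#' @rdname config-io
#' @export
writeCohortConfig <- function(config, path) {
  slots <- c("nSamples", "regionLength", "variantRate", "typeMix",
             "indelLengthProbs", "hetFraction", "fnRateByStratum",
             "fpRateByStratum", "gtErrorRate", "nLabs",
             "nReplicatesPerLab", "seed")
  x <- lapply(slots, function(s) {
    v <- slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(x) <- slots
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname config-io
#' @export
readCohortConfig <- function(path) {
  x <- yaml::read_yaml(path)
  toNamed <- function(v) if (is.list(v)) unlist(v) else v
  cohortConfig(
    nSamples = x$nSamples, regionLength = x$regionLength,
    variantRate = x$variantRate, typeMix = toNamed(x$typeMix),
    indelLengthProbs = as.numeric(unlist(x$indelLengthProbs)),
    hetFraction = x$hetFraction,
    fnRateByStratum = toNamed(x$fnRateByStratum),
    fpRateByStratum = toNamed(x$fpRateByStratum),
    gtErrorRate = x$gtErrorRate, nLabs = x$nLabs,
    nReplicatesPerLab = x$nReplicatesPerLab, seed = x$seed)
}

#' Serialize an agreement table as TSV
#'
#' @param tab data.frame from \code{\link{agreementTable}}.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeAgreementTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a Jaccard matrix as TSV
#'
#' Row/column labels are \code{lab:replicate:sample}.
#'
#' @param jm a \code{\link{JaccardMatrix}}.
#' @param path TSV path.
#' @return invisibly, the path.
#' @export
writeJaccardMatrix <- function(jm, path) {
  utils::write.table(jm@values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
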