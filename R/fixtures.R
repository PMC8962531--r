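#' Load a packaged printed-table fixture
#'
#' The package ships the published validation tables (variant-calling
#' accuracy counts by stratum; pharmacogenomic star-allele concordance) as
#' plain-text fixtures so reproduction checks run with no downloads. File
#' checksums are verified on every load.
#'
#' @param tableId \code{"table2"} (accuracy by genomic context and variant
#'   type) or \code{"table3"} (PGx star-allele concordance).
#' @return data.frame of typed fixture rows; the fixture description is
#'   attached as attribute \code{"description"}.
#' @export
loadPrintedTable <- function(tableId) {
  metaPath <- system.file("extdata", "fixtures.json",
                          package = "VariantAgreement", mustWork = TRUE)
  meta <- jsonlite::read_json(metaPath)
  if (!tableId %in% names(meta)) {
    stop("unknown table id '", tableId, "'; available: ",
         paste(names(meta), collapse = ", "))
  }
  entry <- meta[[tableId]]
  path <- system.file("extdata", entry$file, package = "VariantAgreement",
                      mustWork = TRUE)
  got <- unname(tools::md5sum(path))
  if (got != entry$md5) {
    stop("checksum mismatch for ", entry$file, ": expected ", entry$md5,
         ", got ", got)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  attr(df, "description") <- entry$description
  df
}
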