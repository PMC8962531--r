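# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package go through this so that identical
# seeds give bit-identical output regardless of ambient RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Zero-row variant table with the canonical column set.
.emptyVariants <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), genotype = character(0),
    stringsAsFactors = FALSE
  )
}

.GENOTYPES <- c("het", "hom_alt")

# Full matching key: site + alleles + zygosity.
.variantKey <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, v$genotype, sep = "\r")
}

# Site/allele key without zygosity.
.siteKey <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
}

.checkVariantFrame <- function(v, what = "variants") {
  need <- c("chrom", "pos", "ref", "alt", "genotype")
  if (!is.data.frame(v) || !all(need %in% names(v))) {
    stop(what, " must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (nrow(v) == 0) return(invisible(TRUE))
  if (any(v$pos < 1)) stop("variant positions must be >= 1")
  if (any(!nzchar(v$ref)) || any(!nzchar(v$alt))) {
    stop("ref and alt alleles must be non-empty")
  }
  if (any(v$ref == v$alt)) stop("ref and alt must differ")
  if (!all(v$genotype %in% .GENOTYPES)) {
    stop("genotype must be one of: ", paste(.GENOTYPES, collapse = ", "))
  }
  if (anyDuplicated(.siteKey(v))) {
    stop("duplicate (chrom, pos, ref, alt) entries in ", what)
  }
  invisible(TRUE)
}

# Variant type from normalized ref/alt strings.
.variantType <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "snv",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

# Indel event length (SNVs count as length 1).
.eventLength <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), 1L, abs(nchar(alt) - nchar(ref)))
}

# Probability/rate validation.
.checkProb <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]")
  }
  invisible(TRUE)
}

# Look up a per-stratum rate with a "default" fallback.
.rateFor <- function(rates, stratum) {
  if (is.null(names(rates))) return(unname(rates[1]))
  if (stratum %in% names(rates)) return(unname(rates[[stratum]]))
  if ("default" %in% names(rates)) return(unname(rates[["default"]]))
  0
}
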