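#' Read a star-allele definition table from TSV
#'
#' Expected columns: gene, allele, chrom, pos, ref, alt. One row per
#' defining variant; the reference allele carries no rows and is added
#' automatically.
#'
#' @param path TSV file path.
#' @param referenceAllele reference allele name (default "*1").
#' @return named list of \code{\link{StarAlleleTable}}s, one per gene.
#' @export
readStarAlleleTable <- function(path, referenceAllele = "*1") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("gene", "allele", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("definition table needs columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, , drop = FALSE]
    alleles <- split(sub[, c("chrom", "pos", "ref", "alt")], sub$allele)
    alleles <- lapply(alleles, function(x) {
      rownames(x) <- NULL
      x
    })
    out[[g]] <- StarAlleleTable(g, alleles, referenceAllele)
  }
  out
}

#' Call a star-allele diplotype from a variant call set
#'
#' Rule-based unphased diplotype assignment. For each non-reference allele
#' the defining variants present in the call set and their zygosity are
#' tallied; an allele is fully matched homozygous when every defining
#' variant is present hom-alt, and fully matched heterozygous when every
#' defining variant is present het. Nested definitions resolve to the most
#' specific (largest) fully matched set. Assignment:
#' \itemize{
#'   \item one fully hom allele: allele/allele;
#'   \item two fully het alleles at disjoint sites: allele/allele in trans
#'     (flagged ambiguous, since an unphased call set cannot exclude the
#'     cis compound haplotype);
#'   \item one fully het allele: allele/reference;
#'   \item none: reference/reference.
#' }
#' Partial matches (some defining variants present, or mixed zygosity) and
#' calls at definition sites matching no allele are recorded as conflicts
#' and flag the call ambiguous.
#'
#' @param calls a \code{CallSet} (normalized).
#' @param table a \code{\link{StarAlleleTable}}.
#' @param ploidy 2 (default) or 1 for haploid genes (e.g. X-linked genes in
#'   males; ploidy is an input, not inferred).
#' @return a \code{\link{DiplotypeCall}}.
#' @export
callStarAlleles <- function(calls, table, ploidy = 2L) {
  validObject(table)
  stopifnot(is(calls, "CallSet"), ploidy %in% 1:2)
  v <- variants(calls)
  defKeys <- lapply(table@alleles, function(a) {
    paste(a$chrom, a$pos, a$ref, a$alt, sep = "\r")
  })
  allDefKeys <- unique(unlist(defKeys))
  vKeys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
  defSites <- unique(vapply(strsplit(allDefKeys, "\r", fixed = TRUE),
                            function(p) paste(p[1], p[2]), ""))
  vSites <- paste(v$chrom, v$pos)

  conflicts <- character(0)
  stray <- vSites %in% defSites & !(vKeys %in% allDefKeys)
  if (any(stray)) {
    conflicts <- c(conflicts, paste0(
      "call at definition site matches no allele: ",
      v$chrom[stray], ":", v$pos[stray], " ", v$ref[stray], ">",
      v$alt[stray]))
  }

  status <- list()
  nonref <- setdiff(names(table@alleles), table@referenceAllele)
  for (a in nonref) {
    keys <- defKeys[[a]]
    present <- keys %in% vKeys
    gt <- v$genotype[match(keys[present], vKeys)]
    status[[a]] <- list(
      n = length(keys),
      nPresent = sum(present),
      fullHom = all(present) && all(gt == "hom_alt"),
      fullHet = all(present) && all(gt == "het"),
      partial = any(present) && !(all(present) &&
                                  (all(gt == "hom_alt") || all(gt == "het")))
    )
  }

  partials <- names(status)[vapply(status, `[[`, TRUE, "partial")]
  if (length(partials)) {
    conflicts <- c(conflicts, paste0(
      "partial or mixed-zygosity match for allele ", partials))
  }

  full <- names(status)[vapply(status, function(s) s$fullHom || s$fullHet,
                               TRUE)]
  # nested definitions: drop fully matched alleles whose defining set is a
  # proper subset of another fully matched allele's set
  if (length(full) > 1) {
    drop <- rep(FALSE, length(full))
    for (i in seq_along(full)) {
      for (j in seq_along(full)) {
        if (i == j) next
        si <- defKeys[[full[i]]]; sj <- defKeys[[full[j]]]
        if (length(si) < length(sj) && all(si %in% sj)) drop[i] <- TRUE
        if (length(si) == length(sj) && i < j && setequal(si, sj)) {
          conflicts <- c(conflicts, paste0(
            "alleles ", full[i], " and ", full[j],
            " have identical defining sets"))
        }
      }
    }
    full <- full[!drop]
  }
  fullHom <- full[vapply(full, function(a) status[[a]]$fullHom, TRUE)]
  fullHet <- full[vapply(full, function(a) status[[a]]$fullHet, TRUE)]

  ambiguous <- length(conflicts) > 0
  ref <- table@referenceAllele

  if (ploidy == 1L) {
    allele <- if (length(full) >= 1) {
      if (length(full) > 1) {
        ambiguous <- TRUE
        conflicts <- c(conflicts, "multiple fully matched haploid alleles")
      }
      full[order(-vapply(full, function(a) status[[a]]$n, 0), full)][1]
    } else ref
    return(new("DiplotypeCall", gene = table@gene, alleles = allele,
               ambiguous = ambiguous, conflicts = conflicts))
  }

  if (length(fullHom) >= 1) {
    if (length(fullHom) > 1 || length(fullHet) > 0) {
      ambiguous <- TRUE
      conflicts <- c(conflicts,
                     "additional fully matched alleles beyond the hom call")
    }
    best <- fullHom[order(-vapply(fullHom, function(a) status[[a]]$n, 0),
                          fullHom)][1]
    pair <- c(best, best)
  } else if (length(fullHet) >= 2) {
    picked <- fullHet[order(-vapply(fullHet, function(a) status[[a]]$n, 0),
                            fullHet)][1:2]
    if (length(fullHet) > 2) {
      conflicts <- c(conflicts, "more than two fully matched het alleles")
    }
    # trans interpretation preferred; cis compound cannot be excluded
    ambiguous <- TRUE
    pair <- sort(picked)
  } else if (length(fullHet) == 1) {
    pair <- sort(c(fullHet, ref))
  } else {
    pair <- c(ref, ref)
  }
  new("DiplotypeCall", gene = table@gene, alleles = pair,
      ambiguous = ambiguous, conflicts = conflicts)
}

.dipLabel <- function(d) paste(sort(dipAlleles(d)), collapse = "/")

#' Tabulate multi-method diplotype concordance
#'
#' Compares each method's diplotype calls against the per-sample truth
#' diplotypes and tabulates, per truth diplotype and method, the number of
#' correct (exact unordered allele-pair match) and incorrect calls, plus the
#' pooled overall concordance.
#'
#' @param truthDiplotypes named list (by sample) of \code{DiplotypeCall}s.
#' @param methodCalls named list (by method) of named lists (by sample) of
#'   \code{DiplotypeCall}s.
#' @return list with \code{rows} (data.frame: gene, diplotype, method, n,
#'   correct, incorrect), \code{overall} (data.frame per gene+diplotype with
#'   pooled numerator/denominator/fraction) and \code{grandTotal}
#'   (numerator, denominator, fraction over every call).
#' @export
tabulateConcordance <- function(truthDiplotypes, methodCalls) {
  rows <- list()
  for (m in names(methodCalls)) {
    calls <- methodCalls[[m]]
    if (length(calls) == 0) stop("method ", m, " has zero samples")
    for (s in names(calls)) {
      if (!s %in% names(truthDiplotypes)) {
        stop("sample ", s, " has no truth diplotype")
      }
      truth <- truthDiplotypes[[s]]
      ok <- .dipLabel(calls[[s]]) == .dipLabel(truth) &&
        calls[[s]]@gene == truth@gene
      rows[[length(rows) + 1]] <- data.frame(
        gene = truth@gene, diplotype = .dipLabel(truth), method = m,
        sample = s, correct = as.integer(ok), incorrect = as.integer(!ok),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  byRow <- stats::aggregate(cbind(correct, incorrect) ~
                              gene + diplotype + method, data = long, sum)
  byRow$n <- byRow$correct + byRow$incorrect
  byRow <- byRow[order(byRow$gene, byRow$diplotype, byRow$method), ,
                 drop = FALSE]
  rownames(byRow) <- NULL
  overall <- stats::aggregate(cbind(correct, incorrect) ~ gene + diplotype,
                              data = long, sum)
  overall$total <- overall$correct + overall$incorrect
  overall$fraction <- overall$correct / overall$total
  overall <- overall[order(overall$gene, overall$diplotype), , drop = FALSE]
  rownames(overall) <- NULL
  grand <- c(numerator = sum(long$correct),
             denominator = nrow(long))
  list(rows = byRow, overall = overall,
       grandTotal = c(grand,
                      fraction = unname(grand[1] / grand[2])))
}
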