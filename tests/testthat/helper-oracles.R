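# Independent brute-force oracles and small generators used across tests.
# These deliberately avoid the package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

wholeRegion <- function(len, chrom = "region") {
  GRanges(chrom, IRanges(1, len))
}

# Exhaustive-enumeration classifier: for every truth record scan every eval
# record for an exact key match; leftovers are FN/FP. TN by per-position
# footprint marking.
oracleClassify <- function(tv, ev, regionLen) {
  inReg <- function(v) v[v$pos >= 1 & v$pos <= regionLen, , drop = FALSE]
  tv <- inReg(tv); ev <- inReg(ev)
  key <- function(v, i) paste(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                              v$genotype[i])
  tp <- 0L; fn <- 0L
  matchedEval <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(tv))) {
    hit <- FALSE
    for (j in seq_len(nrow(ev))) {
      if (!matchedEval[j] && key(tv, i) == key(ev, j)) {
        hit <- TRUE; matchedEval[j] <- TRUE; break
      }
    }
    if (hit) tp <- tp + 1L else fn <- fn + 1L
  }
  fp <- sum(!matchedEval)
  touched <- rep(FALSE, regionLen)
  for (v in list(tv, ev)) {
    for (i in seq_len(nrow(v))) {
      span <- v$pos[i]:(v$pos[i] + nchar(v$ref[i]) - 1L)
      span <- span[span <= regionLen]
      touched[span] <- TRUE
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = regionLen - sum(touched))
}

# Random small variant tables on a shared reference for matcher tests.
randomVariantTable <- function(n, regionLen, refChars) {
  pos <- sort(sample(seq(5, regionLen - 10, by = 8), n))
  type <- sample(c("snv", "ins", "del"), n, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    p <- pos[i]
    if (type[i] == "snv") {
      ref[i] <- refChars[p]
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    } else if (type[i] == "ins") {
      ref[i] <- refChars[p]
      alt[i] <- paste0(refChars[p],
                       paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                                    replace = TRUE), collapse = ""))
    } else {
      len <- sample(1:3, 1)
      ref[i] <- paste(refChars[p:(p + len)], collapse = "")
      alt[i] <- refChars[p]
    }
  }
  data.frame(chrom = "region", pos = pos, ref = ref, alt = alt,
             genotype = sample(c("het", "hom_alt"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Derive an eval table from truth by dropping/flipping/adding records.
perturbVariantTable <- function(tv, regionLen, refChars,
                                dropP = 0.1, flipP = 0.1, nAdd = 3) {
  keep <- runif(nrow(tv)) >= dropP
  ev <- tv[keep, , drop = FALSE]
  if (nrow(ev)) {
    flip <- runif(nrow(ev)) < flipP
    ev$genotype[flip] <- ifelse(ev$genotype[flip] == "het", "hom_alt", "het")
  }
  if (nAdd > 0) {
    free <- setdiff(seq(6, regionLen - 10, by = 8) + 1L, tv$pos)
    add <- randomVariantTable(nAdd, regionLen, refChars)
    add$pos <- sort(sample(free, nAdd))
    for (i in seq_len(nAdd)) {
      p <- add$pos[i]
      if (nchar(add$ref[i]) == 1) {
        add$ref[i] <- refChars[p]
        if (nchar(add$alt[i]) == 1) {
          add$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), add$ref[i]), 1)
        } else {
          add$alt[i] <- paste0(refChars[p], substr(add$alt[i], 2,
                                                   nchar(add$alt[i])))
        }
      } else {
        len <- nchar(add$ref[i]) - 1L
        add$ref[i] <- paste(refChars[p:(p + len)], collapse = "")
        add$alt[i] <- refChars[p]
      }
    }
    ev <- rbind(ev, add)
  }
  ev <- ev[!duplicated(paste(ev$chrom, ev$pos, ev$ref, ev$alt)), ,
           drop = FALSE]
  ev[order(ev$pos), , drop = FALSE]
}

randomRefChars <- function(n) sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE)

# Leftmost equivalent indel representation by direct sequence editing: try
# every anchor position left of the variant and keep the leftmost whose
# edited sequence equals the original edit.
oracleLeftAlign <- function(pos, ref, alt, refChars) {
  apply_edit <- function(p, r, a) {
    n <- length(refChars)
    before <- if (p > 1) paste(refChars[1:(p - 1)], collapse = "") else ""
    after_start <- p + nchar(r)
    after <- if (after_start <= n) {
      paste(refChars[after_start:n], collapse = "")
    } else ""
    paste0(before, a, after)
  }
  target <- apply_edit(pos, ref, alt)
  isDel <- nchar(ref) > nchar(alt)
  L <- abs(nchar(ref) - nchar(alt))
  best <- NULL
  for (p in 1:pos) {
    if (isDel) {
      if (p + L > length(refChars)) next
      r <- paste(refChars[p:(p + L)], collapse = "")
      a <- refChars[p]
      if (apply_edit(p, r, a) == target) { best <- list(p, r, a); break }
    } else {
      # insertions: enumerate inserted strings that reproduce the edit
      r <- refChars[p]
      # the inserted sequence must make the edited string match
      n <- length(refChars)
      before <- if (p > 1) paste(refChars[1:(p - 1)], collapse = "") else ""
      after <- if (p + 1 <= n) paste(refChars[(p + 1):n], collapse = "") else ""
      need <- target
      if (startsWith(need, paste0(before, r)) &&
          endsWith(need, after) &&
          nchar(need) == nchar(before) + 1 + L + nchar(after)) {
        ins <- substr(need, nchar(before) + 2, nchar(before) + 1 + L)
        best <- list(p, r, paste0(r, ins))
        break
      }
    }
  }
  best
}

# Per-position O(n*w) GC window exclusion scan.
oracleGCScan <- function(chars, window, threshold) {
  n <- length(chars)
  excluded <- rep(FALSE, n)
  isGC <- chars %in% c("G", "C")
  for (s in 1:(n - window + 1)) {
    if (sum(isGC[s:(s + window - 1)]) / window > threshold) {
      excluded[s:(s + window - 1)] <- TRUE
    }
  }
  excluded
}

# Per-position homopolymer / microrepeat membership scan.
oracleRepeatScan <- function(chars, minRun, units, minUnits) {
  n <- length(chars)
  excluded <- rep(FALSE, n)
  for (s in 1:n) {
    r <- 1L
    while (s + r <= n && chars[s + r] == chars[s]) r <- r + 1L
    if (r >= minRun) excluded[s:(s + r - 1)] <- TRUE
  }
  for (u in units) {
    for (s in 1:(n - u)) {
      len <- 0L
      while (s + u + len <= n && chars[s + u + len] == chars[s + len]) {
        len <- len + 1L
      }
      if (len > 0 && (len + u) >= u * minUnits) {
        excluded[s:(s + len + u - 1)] <- TRUE
      }
    }
  }
  excluded
}

grToMask <- function(gr, n) {
  mask <- rep(FALSE, n)
  for (i in seq_along(gr)) {
    mask[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  }
  mask
}

# 5-allele toy star-allele definition table with disjoint defining sets.
toyStarTable <- function() {
  v <- function(pos, ref, alt) data.frame(chrom = "geneA", pos = pos,
                                          ref = ref, alt = alt,
                                          stringsAsFactors = FALSE)
  StarAlleleTable("GENEA", list(
    "*2" = rbind(v(100, "A", "G"), v(150, "C", "T")),
    "*3" = v(200, "G", "A"),
    "*17" = rbind(v(300, "T", "C"), v(350, "G", "C")),
    "*22" = v(400, "A", "T")
  ))
}
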