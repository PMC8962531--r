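#' Positive percent agreement
#'
#' PPA = TP / (TP + FN), the sensitivity analogue used when the comparator is
#' a validated assay rather than ground truth. Returns \code{NA} (undefined)
#' when TP + FN = 0.
#'
#' @param x a \code{\link{ContingencyCounts}} or \code{ClassifiedCalls}.
#' @return proportion in [0, 1], or \code{NA} when undefined.
#' @export
ppa <- function(x) {
  cv <- countVector(x)
  d <- cv[["tp"]] + cv[["fn"]]
  if (d == 0) return(NA_real_)
  cv[["tp"]] / d
}

#' Negative percent agreement
#'
#' NPA = TN / (TN + FP). Returns \code{NA} when TN + FP = 0.
#'
#' @inheritParams ppa
#' @return proportion in [0, 1], or \code{NA} when undefined.
#' @export
npa <- function(x) {
  cv <- countVector(x)
  d <- cv[["tn"]] + cv[["fp"]]
  if (d == 0) return(NA_real_)
  cv[["tn"]] / d
}

#' Format a proportion as a percentage at table precision
#'
#' Presentation-layer rounding to 2 decimal places, half-up. Stored values
#' are never rounded; use this only for display.
#'
#' @param p proportion in [0, 1].
#' @param digits decimal places (default 2).
#' @return numeric percentage (e.g. 99.74).
#' @export
asPercent <- function(p, digits = 2) {
  # round half-up at the requested precision
  m <- 10^digits
  floor(p * 100 * m + 0.5) / m
}

#' Normal-approximation confidence interval over per-sample proportions
#'
#' mean +/- z * sd / sqrt(n) over the per-sample values, the interval form
#' used in clinical validation reporting; clamped to [0, 1] by default since
#' the normal interval can exceed the parameter space.
#'
#' @param values per-sample proportions (length >= 2).
#' @param z critical value (default 1.96).
#' @param clamp clamp the interval to [0, 1] (default TRUE).
#' @return numeric (low, high).
#' @export
ciNormalPerSample <- function(values, z = 1.96, clamp = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("need at least 2 per-sample values for a normal interval")
  }
  if (z <= 0) stop("z must be positive")
  m <- mean(values)
  half <- z * stats::sd(values) / sqrt(length(values))
  ci <- c(m - half, m + half)
  if (clamp) ci <- pmin(pmax(ci, 0), 1)
  ci
}

#' Pooled binomial confidence interval for PPA or NPA
#'
#' Wald or Wilson interval on the pooled (micro-averaged) proportion.
#'
#' @param x a \code{\link{ContingencyCounts}} or \code{ClassifiedCalls}.
#' @param which \code{"ppa"} or \code{"npa"}.
#' @param method \code{"wald"} or \code{"wilson"}.
#' @param z critical value for the Wald interval (default 1.96); the Wilson
#'   interval uses the matching two-sided confidence level.
#' @param clamp clamp to [0, 1].
#' @return numeric (low, high).
#' @export
ciPooled <- function(x, which = c("ppa", "npa"), method = c("wald", "wilson"),
                     z = 1.96, clamp = TRUE) {
  which <- match.arg(which)
  method <- match.arg(method)
  cv <- countVector(x)
  if (which == "ppa") {
    k <- cv[["tp"]]; n <- cv[["tp"]] + cv[["fn"]]
  } else {
    k <- cv[["tn"]]; n <- cv[["tn"]] + cv[["fp"]]
  }
  if (n == 0) stop("zero denominator: ", which, " is undefined")
  p <- k / n
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - half, p + half)
  } else {
    conf <- 2 * stats::pnorm(z) - 1
    ci <- stats::prop.test(k, n, conf.level = conf,
                           correct = FALSE)$conf.int
    ci <- as.numeric(ci)
  }
  if (clamp) ci <- pmin(pmax(ci, 0), 1)
  ci
}

#' Agreement results across strata, in validation-table shape
#'
#' Computes pooled PPA/NPA with pooled binomial intervals per stratum and,
#' when per-sample classifications are supplied, the per-sample-mean
#' (macro-averaged) PPA with the normal-approximation interval.
#'
#' @param strataCounts named list of \code{\link{ContingencyCounts}} (e.g.
#'   summed across samples), one per stratum.
#' @param perSampleStrata optional list (one element per sample) of named
#'   lists of \code{ContingencyCounts} as returned by
#'   \code{\link{stratifyCalls}}; enables the macro-averaged columns.
#' @param ciMethod \code{"wald"} or \code{"wilson"} for the pooled interval.
#' @return data.frame with columns stratum, tp, fp, fn, tn, ppa, ppa_ci_low,
#'   ppa_ci_high, npa, npa_ci_low, npa_ci_high, ppa_macro, ppa_macro_ci_low,
#'   ppa_macro_ci_high, method, ci_method.
#' @export
agreementTable <- function(strataCounts, perSampleStrata = NULL,
                           ciMethod = c("wald", "wilson")) {
  ciMethod <- match.arg(ciMethod)
  rows <- lapply(names(strataCounts), function(nm) {
    cc <- strataCounts[[nm]]
    cv <- countVector(cc)
    p <- ppa(cc); q <- npa(cc)
    pci <- if (!is.na(p) && (cv[["tp"]] + cv[["fn"]]) > 0) {
      ciPooled(cc, "ppa", ciMethod)
    } else c(NA_real_, NA_real_)
    qci <- if (!is.na(q)) ciPooled(cc, "npa", ciMethod) else
      c(NA_real_, NA_real_)
    macro <- c(NA_real_, NA_real_, NA_real_)
    if (!is.null(perSampleStrata)) {
      vals <- vapply(perSampleStrata, function(s) {
        if (!nm %in% names(s)) return(NA_real_)
        ppa(s[[nm]])
      }, numeric(1))
      vals <- vals[!is.na(vals)]
      if (length(vals) >= 2) {
        macro <- c(mean(vals), ciNormalPerSample(vals))
      } else if (length(vals) == 1) {
        macro <- c(vals, NA_real_, NA_real_)
      }
    }
    data.frame(
      stratum = nm, tp = cv[["tp"]], fp = cv[["fp"]], fn = cv[["fn"]],
      tn = cv[["tn"]], ppa = p, ppa_ci_low = pci[1], ppa_ci_high = pci[2],
      npa = q, npa_ci_low = qci[1], npa_ci_high = qci[2],
      ppa_macro = macro[1], ppa_macro_ci_low = macro[2],
      ppa_macro_ci_high = macro[3],
      method = "pooled", ci_method = ciMethod,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sum contingency counts across samples
#'
#' @param countsList list of \code{\link{ContingencyCounts}} for the same
#'   stratum.
#' @return a pooled \code{ContingencyCounts}.
#' @export
sumCounts <- function(countsList) {
  m <- vapply(countsList, countVector, numeric(4))
  ContingencyCounts(sum(m["tp", ]), sum(m["fp", ]), sum(m["fn", ]),
                    sum(m["tn", ]),
                    stratum = countsList[[1]]@stratum)
}

#' PPA as a function of indel event length
#'
#' Bins TP and FN records by event length (SNVs form the length-1 bin of
#' their own category; an indel's length is the inserted/deleted base count)
#' and reports per-bin PPA. Empty bins are \code{NA}, not zero.
#'
#' @param classified a \code{\link{ClassifiedCalls}} or a list of them
#'   (pooled).
#' @param maxLength largest event length to report.
#' @return data.frame with columns type, length, tp, fn, ppa.
#' @export
accuracyByEventLength <- function(classified, maxLength = 20) {
  if (is(classified, "ClassifiedCalls")) classified <- list(classified)
  tp <- do.call(rbind, lapply(classified, truePositives))
  fn <- do.call(rbind, lapply(classified, falseNegatives))
  grid <- expand.grid(type = c("snv", "insertion", "deletion"),
                      length = seq_len(maxLength),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$type != "snv" | grid$length == 1, , drop = FALSE]
  tally <- function(v, type, len) {
    if (is.null(v) || nrow(v) == 0) return(0L)
    sum(.variantType(v$ref, v$alt) == type &
        .eventLength(v$ref, v$alt) == len)
  }
  grid$tp <- mapply(function(t, l) tally(tp, t, l), grid$type, grid$length)
  grid$fn <- mapply(function(t, l) tally(fn, t, l), grid$type, grid$length)
  grid$ppa <- ifelse(grid$tp + grid$fn == 0, NA_real_,
                     grid$tp / (grid$tp + grid$fn))
  rownames(grid) <- NULL
  grid
}
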