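#' @include ContentMatrix.R
NULL

#' Relative standard deviation
#'
#' Sample standard deviation (n-1 denominator) over the mean, times 100.
#' Scale-invariant: \code{rsd(c * x) == rsd(x)} for any \code{c > 0}.
#'
#' @param values Numeric vector with at least 2 values and non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(1, 2, 3))   # 50
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("rsd() needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("rsd() undefined for zero mean")
  sd(values) / m * 100
}

#' Spike-recovery rate
#'
#' \code{(detected - original) * 100 / added}, the standard accuracy metric
#' for a spiked-known design.
#'
#' @param detected,original,added Amounts (same units); \code{added > 0}.
#' @return Recovery in percent (vectorized).
#' @examples
#' recovery(1.981, 1.0, 1.0)   # 98.1
#' @export
recovery <- function(detected, original, added) {
  if (any(added <= 0)) stop("'added' must be strictly positive")
  (detected - original) * 100 / added
}

#' Method-validation report
#'
#' Summarises the standard validation arms per analyte: intra-day precision
#' (n = 6 injections within one day), inter-day precision (duplicates on 3
#' consecutive days), repeatability (6 independently prepared samples, with
#' the mean content), stability (7 timepoints over 24 h) and spike recovery
#' (mean +/- sd and RSD). All dispersions are RSDs.
#'
#' @param arms A named list with elements \code{intra_day},
#'   \code{inter_day}, \code{repeatability}, \code{stability} (each a named
#'   list of numeric vectors, one per analyte) and \code{recovery} (a named
#'   list of data.frames with columns \code{detected}, \code{original},
#'   \code{added}), e.g. from \code{\link{simulateValidationArms}}.
#' @return A data.frame, one row per analyte: \code{analyte},
#'   \code{intra_day_rsd}, \code{inter_day_rsd}, \code{repeatability_rsd},
#'   \code{repeatability_mean}, \code{stability_rsd}, \code{recovery_mean},
#'   \code{recovery_sd}, \code{recovery_rsd}.
#' @export
validationReport <- function(arms) {
  need <- c("intra_day", "inter_day", "repeatability", "stability",
            "recovery")
  if (!all(need %in% names(arms)))
    stop("'arms' must contain: ", paste(need, collapse = ", "))
  analytes <- names(arms$intra_day)
  rows <- lapply(analytes, function(an) {
    for (arm in need) {
      v <- arms[[arm]][[an]]
      n <- if (is.data.frame(v)) nrow(v) else length(v)
      if (is.null(v) || n < 2L)
        stop("arm '", arm, "' has fewer than 2 values for analyte '", an,
             "'")
    }
    rec <- arms$recovery[[an]]
    recPct <- recovery(rec$detected, rec$original, rec$added)
    data.frame(
      analyte = an,
      intra_day_rsd = rsd(arms$intra_day[[an]]),
      inter_day_rsd = rsd(arms$inter_day[[an]]),
      repeatability_rsd = rsd(arms$repeatability[[an]]),
      repeatability_mean = mean(arms$repeatability[[an]]),
      stability_rsd = rsd(arms$stability[[an]]),
      recovery_mean = mean(recPct),
      recovery_sd = sd(recPct),
      recovery_rsd = if (mean(recPct) == 0) NA_real_ else rsd(recPct),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-analyte batch summary
#'
#' ND-excluded minimum, maximum and mean content per analyte, with the
#' count of ND cells.
#'
#' @param x A \linkS4class{ContentMatrix}.
#' @return A data.frame with columns \code{analyte}, \code{min}, \code{max},
#'   \code{mean}, \code{n_nd}.
#' @seealso \code{\link{dominantAnalyte}}
#' @export
batchSummary <- function(x) {
  stopifnot(is(x, "ContentMatrix"))
  m <- contentValues(x)
  if (!nrow(m) || !ncol(m)) stop("empty content matrix")
  data.frame(
    analyte = rownames(m),
    min = apply(m, 1, min, na.rm = TRUE),
    max = apply(m, 1, max, na.rm = TRUE),
    mean = rowMeans(m, na.rm = TRUE),
    n_nd = as.integer(rowSums(is.na(m))),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Dominant analyte per sample
#'
#' @param x A \linkS4class{ContentMatrix}.
#' @return Named character vector: per sample, the analyte with the highest
#'   (non-ND) content.
#' @export
dominantAnalyte <- function(x) {
  m <- contentValues(x)
  apply(m, 2, function(col) rownames(m)[which.max(col)])
}

#' Compare analyte contents between two origin groups
#'
#' Two-sided two-sample t-test per analyte, pooled-variance Student's t by
#' default (Welch via \code{varEqual = FALSE}). ND cells are excluded
#' pairwise, never by deleting whole samples. No multiple-testing
#' adjustment is applied by default; Benjamini-Hochberg is available via
#' \code{adjust = "BH"}.
#'
#' @param x A \linkS4class{ContentMatrix} with origin labels.
#' @param groupA,groupB Origin labels to compare.
#' @param varEqual Pooled-variance Student's t (TRUE, default) or Welch.
#' @param alpha Significance level for the flag (default 0.05).
#' @param adjust P-value adjustment method (default \code{"none"}).
#' @return A data.frame per analyte: \code{analyte}, \code{mean_a},
#'   \code{mean_b}, \code{t}, \code{p}, \code{flag} (p < alpha) and
#'   \code{direction} (\code{"higher-in-b"} / \code{"lower-in-b"} for
#'   flagged analytes, \code{""} otherwise). Analytes with fewer than 2
#'   non-ND values in either group are skipped and listed in the
#'   \code{"skipped"} attribute.
#' @export
compareOrigins <- function(x, groupA, groupB, varEqual = TRUE,
                           alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(is(x, "ContentMatrix"))
  adjust <- match.arg(adjust)
  org <- origins(x)
  if (!groupA %in% org || !groupB %in% org)
    stop("both origin labels must occur in origins(x)")
  m <- contentValues(x)
  rows <- list(); skipped <- character(0)
  for (an in rownames(m)) {
    a <- m[an, org == groupA]; a <- a[!is.na(a)]
    b <- m[an, org == groupB]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <- c(skipped, an)
      next
    }
    tt <- t.test(a, b, var.equal = varEqual)
    rows[[an]] <- data.frame(analyte = an, mean_a = mean(a),
                             mean_b = mean(b),
                             t = unname(tt$statistic), p = tt$p.value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$flag <- out$p < alpha
  out$direction <- ifelse(!out$flag, "",
                          ifelse(out$mean_b > out$mean_a, "higher-in-b",
                                 "lower-in-b"))
  attr(out, "skipped") <- skipped
  out
}
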