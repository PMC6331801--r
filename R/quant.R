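#' @include ContentMatrix.R
NULL

#' CalibrationCurve: linear internal-standard response
#'
#' One analyte's area-ratio response: \eqn{Y = aX + b} where \eqn{X} is the
#' analyte concentration in the injected (post internal-standard mix)
#' solution in ug/mL and \eqn{Y} is the analyte/IS peak-area ratio.
#'
#' @slot analyte Analyte name.
#' @slot slope,intercept Regression coefficients a (> 0) and b.
#' @slot r Pearson correlation of the calibration points, in (0, 1].
#' @slot rangeLow,rangeHigh Linear range in ug/mL (low < high).
#'
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", representation(
  analyte = "character", slope = "numeric", intercept = "numeric",
  r = "numeric", rangeLow = "numeric", rangeHigh = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (object@slope <= 0) return("slope must be positive")
  if (!is.na(object@r) && (object@r <= 0 || object@r > 1))
    return("r must lie in (0, 1]")
  if (object@rangeLow >= object@rangeHigh)
    return("rangeLow must be below rangeHigh")
  TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf("CalibrationCurve [%s]: Y = %.4g X %+.4g, r = %.4f, range %.3g-%.3g ug/mL\n",
              object@analyte, object@slope, object@intercept, object@r,
              object@rangeLow, object@rangeHigh))
})

#' Construct a calibration curve from known coefficients
#'
#' @param analyte Analyte name.
#' @param slope,intercept Coefficients of \eqn{Y = aX + b}.
#' @param r Pearson correlation (NA allowed for externally tabulated curves).
#' @param rangeLow,rangeHigh Linear range in ug/mL.
#' @return A \linkS4class{CalibrationCurve}.
#' @export
calibrationCurve <- function(analyte, slope, intercept, r = NA_real_,
                             rangeLow, rangeHigh) {
  new("CalibrationCurve", analyte = as.character(analyte),
      slope = as.numeric(slope), intercept = as.numeric(intercept),
      r = as.numeric(r), rangeLow = as.numeric(rangeLow),
      rangeHigh = as.numeric(rangeHigh))
}

#' Fit a calibration curve by ordinary least squares
#'
#' Unweighted OLS of the area ratio on the concentration, with \code{r} the
#' Pearson correlation of the points. Weighted variants (1/x, 1/x^2) are
#' available for heteroscedastic data but are off by default.
#'
#' @param concentration Concentrations X in ug/mL (>= 3 distinct values).
#' @param ratio Peak-area ratios Y (analyte area / IS area).
#' @param analyte Analyte name to record on the curve.
#' @param weighting \code{"none"} (default), \code{"1/x"} or \code{"1/x2"}.
#' @return A \linkS4class{CalibrationCurve} with the linear range set to
#'   the span of \code{concentration}.
#' @examples
#' x <- c(0.01, 0.02, 0.05, 0.08, 0.1, 0.103)
#' fitCalibration(x, 15.87 * x - 0.014)
#' @export
fitCalibration <- function(concentration, ratio, analyte = "",
                           weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  stopifnot(length(concentration) == length(ratio))
  if (length(unique(concentration)) < 3L)
    stop("need at least 3 distinct concentrations to fit a calibration curve")
  if (sd(concentration) == 0)
    stop("degenerate design: all concentrations identical")
  w <- switch(weighting, none = NULL, `1/x` = 1 / concentration,
              `1/x2` = 1 / concentration^2)
  fit <- if (is.null(w)) lm(ratio ~ concentration)
         else lm(ratio ~ concentration, weights = w)
  if (sd(ratio) == 0)
    stop("degenerate response: zero slope, correlation undefined")
  r <- cor(concentration, ratio)
  calibrationCurve(analyte, slope = unname(coef(fit)[2L]),
                   intercept = unname(coef(fit)[1L]), r = r,
                   rangeLow = min(concentration),
                   rangeHigh = max(concentration))
}

#' Back-calculate concentration from an area ratio
#'
#' Inverts \eqn{Y = aX + b} and flags the result against the curve's linear
#' range.
#'
#' @param curve A \linkS4class{CalibrationCurve}.
#' @param y Area ratio(s).
#' @return A data.frame with columns \code{concentration} (ug/mL) and
#'   \code{flag} (\code{"below-range"}, \code{"in-range"} or
#'   \code{"above-range"}).
#' @examples
#' cur <- calibrationCurve("x", 15.87, -0.014, 0.9999, 0.008, 0.103)
#' invertCalibration(cur, 1.573)   # 0.100 ug/mL
#' @export
invertCalibration <- function(curve, y) {
  stopifnot(is(curve, "CalibrationCurve"))
  x <- (y - curve@intercept) / curve@slope
  flag <- ifelse(x < curve@rangeLow, "below-range",
                 ifelse(x > curve@rangeHigh, "above-range", "in-range"))
  data.frame(concentration = x, flag = flag, stringsAsFactors = FALSE)
}

#' Sample-preparation constants
#'
#' The constants that tie an injected-solution concentration back to the
#' dried-rhizome content: 0.20 g of powder extracted in 25 mL of
#' acetonitrile, and a 1:1 mix of sample solution with the internal-standard
#' working solution before injection (a 2-fold dilution).
#'
#' @param sample_mass Powder mass in g (default 0.20).
#' @param extraction_volume Extraction volume in mL (default 25).
#' @param is_mix_dilution Dilution factor of the IS mixing step (default 2).
#' @return A named list of class \code{"PrepConstants"}.
#' @export
prepConstants <- function(sample_mass = 0.20, extraction_volume = 25,
                          is_mix_dilution = 2) {
  if (any(c(sample_mass, extraction_volume, is_mix_dilution) <= 0))
    stop("all preparation constants must be strictly positive")
  structure(list(sample_mass = sample_mass,
                 extraction_volume = extraction_volume,
                 is_mix_dilution = is_mix_dilution),
            class = "PrepConstants")
}

#' Convert an injected-solution concentration to mg/g content
#'
#' \code{x * is_mix_dilution * extraction_volume / (sample_mass * 1000)}.
#' Linear and homogeneous in \code{x}; with the default constants the
#' factor is 0.25 (mg/g per ug/mL).
#'
#' @param x Concentration(s) in the injected solution, ug/mL (>= 0).
#' @param prep \code{\link{prepConstants}}.
#' @return Content(s) in mg/g.
#' @examples
#' contentMgPerG(4.0)   # 1.0 mg/g
#' @export
contentMgPerG <- function(x, prep = prepConstants()) {
  if (any(x < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  x * prep$is_mix_dilution * prep$extraction_volume /
    (prep$sample_mass * 1000)
}

#' Estimate LOD and LOQ from a dilution series
#'
#' Finds the concentrations at which the signal-to-noise ratio crosses 3
#' (LOD) and 10 (LOQ) by log-linear interpolation between the bracketing
#' points of the series: log-concentration is interpolated linearly in
#' log(S/N).
#'
#' @param series A data.frame with columns \code{concentration} (strictly
#'   decreasing, ug/mL), \code{signal} and \code{noise} (> 0), e.g. from
#'   \code{\link{simulateDilutionSeries}}.
#' @return A named numeric vector \code{c(lod = ..., loq = ...)} in the
#'   concentration units of the series; always \code{loq > lod}.
#' @export
estimateLodLoq <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("concentration", "signal", "noise") %in% names(series)))
  if (any(series$noise <= 0)) stop("noise values must be positive")
  if (is.unsorted(rev(series$concentration), strictly = TRUE))
    stop("concentrations must be strictly decreasing")
  sn <- series$signal / series$noise
  crossing <- function(target) {
    if (max(sn) < target || min(sn) > target)
      stop("S/N series does not bracket ", target,
           "; extend the dilution series")
    exact <- which(sn == target)
    if (length(exact)) return(series$concentration[exact[1L]])
    i <- which(sn[-length(sn)] > target & sn[-1L] < target)[1L]
    if (is.na(i))
      stop("S/N series does not bracket ", target,
           "; extend the dilution series (non-monotone crossing)")
    f <- (log(target) - log(sn[i])) / (log(sn[i + 1L]) - log(sn[i]))
    exp(log(series$concentration[i]) +
          f * (log(series$concentration[i + 1L]) -
                 log(series$concentration[i])))
  }
  c(lod = crossing(3), loq = crossing(10))
}

#' Quantify an MRM batch
#'
#' Turns long-format replicate peak areas into a \linkS4class{ContentMatrix}
#' of mg/g contents: per injection the analyte/IS area ratio is inverted
#' through the analyte's calibration curve, replicate injections are
#' averaged, contents below the analyte's LOD are recorded as ND
#' (\code{NA}), and the mg/g conversion applies the preparation constants.
#'
#' Measurements with a missing or non-positive IS area are skipped and
#' reported in \code{metadata(result)$skipped}; replicate RSDs and linear
#' range flags are kept in \code{metadata(result)} as well.
#'
#' @param areas data.frame with columns \code{sample_id}, \code{analyte},
#'   \code{area}, \code{is_area} and optionally \code{replicate}.
#' @param curves Named list of \linkS4class{CalibrationCurve} objects (or
#'   the curve table from \code{\link{loadFixtures}("curves")}); every
#'   analyte in \code{areas} must have a curve.
#' @param prep \code{\link{prepConstants}}.
#' @param lods Optional named numeric vector of LODs in ng/mL per analyte;
#'   when given, back-calculated concentrations below LOD become ND.
#' @param origin Optional named character vector mapping sample_id to an
#'   origin label.
#' @return A \linkS4class{ContentMatrix} (analytes in curve-registry order,
#'   samples sorted by id).
#' @export
quantifyBatch <- function(areas, curves, prep = prepConstants(),
                          lods = NULL, origin = NULL) {
  stopifnot(is.data.frame(areas),
            all(c("sample_id", "analyte", "area", "is_area") %in%
                  names(areas)))
  curves <- .asCurveList(curves)
  missing <- setdiff(unique(areas$analyte), names(curves))
  if (length(missing))
    stop("no calibration curve for analyte(s): ",
         paste(missing, collapse = ", "))
  bad <- !is.finite(areas$is_area) | areas$is_area <= 0
  skipped <- areas[bad, c("sample_id", "analyte"), drop = FALSE]
  if (nrow(skipped))
    warning(nrow(skipped), " measurement(s) skipped: missing or invalid ",
            "internal-standard area")
  areas <- areas[!bad, , drop = FALSE]

  analytes <- names(curves)
  samples <- sort(unique(as.character(areas$sample_id)))
  content <- matrix(NA_real_, length(analytes), length(samples),
                    dimnames = list(analytes, samples))
  repRsd <- content
  rangeFlag <- matrix(NA_character_, length(analytes), length(samples),
                      dimnames = dimnames(content))
  ratio <- areas$area / areas$is_area
  for (an in analytes) {
    sel <- areas$analyte == an
    if (!any(sel)) next
    inv <- invertCalibration(curves[[an]], ratio[sel])
    sid <- as.character(areas$sample_id[sel])
    for (s in unique(sid)) {
      xs <- inv$concentration[sid == s]
      x <- mean(xs)
      rangeFlag[an, s] <- if (x < curves[[an]]@rangeLow) "below-range"
                          else if (x > curves[[an]]@rangeHigh) "above-range"
                          else "in-range"
      if (length(xs) >= 2L && mean(xs) != 0)
        repRsd[an, s] <- sd(xs) / mean(xs) * 100
      nd <- !is.null(lods) && an %in% names(lods) &&
        x < lods[[an]] / 1000  # ng/mL -> ug/mL
      content[an, s] <- if (nd) NA_real_ else contentMgPerG(max(x, 0), prep)
    }
  }
  orig <- if (is.null(origin)) rep(NA_character_, length(samples))
          else unname(origin[samples])
  cm <- ContentMatrix(content, origin = orig)
  S4Vectors::metadata(cm)$replicate_rsd <- repRsd
  S4Vectors::metadata(cm)$range_flags <- rangeFlag
  S4Vectors::metadata(cm)$skipped <- skipped
  cm
}

## accept either a named list of CalibrationCurve or the fixture table
.asCurveList <- function(curves) {
  if (is.data.frame(curves)) return(curvesFromTable(curves))
  if (!is.list(curves) || !length(curves) ||
      !all(vapply(curves, is, logical(1), "CalibrationCurve")))
    stop("'curves' must be a curve table or a named list of CalibrationCurve")
  if (is.null(names(curves)))
    names(curves) <- vapply(curves, function(c) c@analyte, character(1))
  curves
}

#' Turn the packaged calibration table into CalibrationCurve objects
#'
#' @param tab Curve table with columns \code{analyte}, \code{slope},
#'   \code{intercept}, \code{r}, \code{range_low}, \code{range_high} (as
#'   returned by \code{\link{loadFixtures}("curves")}).
#' @return A named list of \linkS4class{CalibrationCurve}.
#' @export
curvesFromTable <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("analyte", "slope", "intercept", "range_low",
                  "range_high") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    calibrationCurve(tab$analyte[i], tab$slope[i], tab$intercept[i],
                     if ("r" %in% names(tab)) tab$r[i] else NA_real_,
                     tab$range_low[i], tab$range_high[i])
  })
  names(out) <- tab$analyte
  out
}
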