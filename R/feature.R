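#' @include chem-formula.R
NULL

#' FeatureRecord: one chromatographic feature
#'
#' A single LC-MS feature: retention time, observed precursor m/z, a table
#' of fragment peaks, and (optionally) the UV absorbance maximum from the
#' diode-array detector. Fragments are stored sorted by decreasing m/z, the
#' order used in reports.
#'
#' @slot featureId Character identifier.
#' @slot retentionTime Retention time in minutes (>= 0).
#' @slot precursorMz Observed precursor m/z (> 0).
#' @slot fragments data.frame with columns \code{mz} (> 0) and
#'   \code{intensity} (>= 0); may have zero rows.
#' @slot uvLambdaMax UV lambda-max in nm, or \code{NA} when absorption is
#'   absent or below 200 nm.
#'
#' @exportClass FeatureRecord
setClass("FeatureRecord", representation(
  featureId = "character",
  retentionTime = "numeric",
  precursorMz = "numeric",
  fragments = "data.frame",
  uvLambdaMax = "numeric"
))

setValidity("FeatureRecord", function(object) {
  if (length(object@retentionTime) != 1L || object@retentionTime < 0)
    return("retentionTime must be a single non-negative number")
  if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz) ||
      object@precursorMz <= 0)
    return("precursorMz must be a single positive number")
  fr <- object@fragments
  if (!all(c("mz", "intensity") %in% names(fr)))
    return("fragments must have 'mz' and 'intensity' columns")
  if (nrow(fr)) {
    if (any(!is.finite(fr$mz)) || any(fr$mz <= 0))
      return("fragment m/z values must be positive")
    if (any(fr$intensity < 0))
      return("fragment intensities must be non-negative")
    if (is.unsorted(rev(fr$mz)))
      return("fragments must be sorted by decreasing m/z")
  }
  TRUE
})

#' Construct a FeatureRecord
#'
#' @param precursorMz Observed precursor m/z.
#' @param retentionTime Retention time in minutes.
#' @param fragmentMz,fragmentIntensity Fragment peak list (intensities
#'   default to 1 when omitted). Peaks are sorted by decreasing m/z.
#' @param uvLambdaMax UV lambda-max (nm) or \code{NA}.
#' @param featureId Optional identifier.
#' @return A \linkS4class{FeatureRecord}.
#' @examples
#' featureRecord(469.3315, 25.91, c(451.3216, 397.2745), uvLambdaMax = 287)
#' @export
featureRecord <- function(precursorMz, retentionTime,
                          fragmentMz = numeric(0),
                          fragmentIntensity = rep(1, length(fragmentMz)),
                          uvLambdaMax = NA_real_,
                          featureId = NA_character_) {
  ord <- order(fragmentMz, decreasing = TRUE)
  fr <- data.frame(mz = as.numeric(fragmentMz)[ord],
                   intensity = as.numeric(fragmentIntensity)[ord])
  new("FeatureRecord", featureId = as.character(featureId),
      retentionTime = as.numeric(retentionTime),
      precursorMz = as.numeric(precursorMz),
      fragments = fr, uvLambdaMax = as.numeric(uvLambdaMax))
}

setMethod("show", "FeatureRecord", function(object) {
  cat(sprintf("FeatureRecord %s: m/z %.4f at %.2f min, %d fragment(s), UV %s\n",
              object@featureId, object@precursorMz, object@retentionTime,
              nrow(object@fragments),
              ifelse(is.na(object@uvLambdaMax), "<200 nm/absent",
                     paste0(object@uvLambdaMax, " nm"))))
})

#' @rdname featureRecord
#' @param x A \linkS4class{FeatureRecord}.
#' @export
fragmentPeaks <- function(x) {
  stopifnot(is(x, "FeatureRecord"))
  x@fragments
}

#' @rdname featureRecord
#' @export
precursorMz <- function(x) x@precursorMz

#' @rdname featureRecord
#' @export
retentionTime <- function(x) x@retentionTime

#' @rdname featureRecord
#' @export
uvLambdaMax <- function(x) x@uvLambdaMax

#' @rdname featureRecord
#' @export
featureId <- function(x) x@featureId
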