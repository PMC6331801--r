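#' @include ProtostaneMS-package.R
NULL

#' ContentMatrix: analyte-by-sample contents in mg/g
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one assay
#' \code{"content"}: analytes (rows) by samples (columns), in mg of analyte
#' per g of dried rhizome. \code{NA} cells mean "ND" -- below the analyte's
#' limit of detection -- and are excluded from all summaries and tests.
#' Sample origin labels (e.g. \code{"Fujian"} / \code{"Sichuan"}) live in
#' \code{colData(x)$origin}.
#'
#' @exportClass ContentMatrix
setClass("ContentMatrix", contains = "SummarizedExperiment")

setValidity("ContentMatrix", function(object) {
  if (!"content" %in% SummarizedExperiment::assayNames(object))
    return("a ContentMatrix needs a 'content' assay")
  m <- SummarizedExperiment::assay(object, "content")
  if (!is.numeric(m)) return("the content assay must be numeric")
  if (any(m < 0, na.rm = TRUE)) return("contents must be non-negative")
  if (!"origin" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData must contain an 'origin' column")
  TRUE
})

#' Construct a ContentMatrix
#'
#' @param content Numeric matrix, analytes (rows, named) by samples
#'   (columns, named); \code{NA} encodes ND (below the LOD).
#' @param origin Character vector of per-sample origin labels, recycled to
#'   the number of columns.
#' @return A \linkS4class{ContentMatrix}.
#' @examples
#' m <- matrix(c(1.4, 0.3, 1.5, 0.2), nrow = 2,
#'             dimnames = list(c("alisol B 23-acetate", "alisol B"),
#'                             c("S1", "S2")))
#' ContentMatrix(m, origin = c("Fujian", "Sichuan"))
#' @export
ContentMatrix <- function(content, origin = NA_character_) {
  content <- as.matrix(content)
  storage.mode(content) <- "double"
  if (is.null(rownames(content)) || is.null(colnames(content)))
    stop("'content' must have analyte row names and sample column names")
  cd <- S4Vectors::DataFrame(origin = rep_len(as.character(origin),
                                              ncol(content)),
                             row.names = colnames(content))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(content = content), colData = cd)
  new("ContentMatrix", se)
}

#' @rdname ContentMatrix
#' @param x A \linkS4class{ContentMatrix}.
#' @export
contentValues <- function(x) {
  stopifnot(is(x, "ContentMatrix"))
  SummarizedExperiment::assay(x, "content")
}

#' @rdname ContentMatrix
#' @export
origins <- function(x) {
  stopifnot(is(x, "ContentMatrix"))
  as.character(SummarizedExperiment::colData(x)$origin)
}

#' @rdname ContentMatrix
#' @export
analyteNames <- function(x) rownames(contentValues(x))

#' @rdname ContentMatrix
#' @export
ndMask <- function(x) is.na(contentValues(x))

setMethod("show", "ContentMatrix", function(object) {
  m <- contentValues(object)
  cat(sprintf("ContentMatrix: %d analyte(s) x %d sample(s), %d ND cell(s)\n",
              nrow(m), ncol(m), sum(is.na(m))))
  tb <- table(origins(object))
  cat("origins:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
})
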