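#' @include chem-formula.R
NULL

#' Default neutral-loss vocabulary
#'
#' The neutral losses observed in protostane triterpenoid positive-mode
#' fragmentation: water, acetic acid ("HAc", C2H4O2), ketene (C2H2O) and the
#' C-23--C-24 side-chain fragments C4H8O, C4H10O2, C6H10O2 and C6H12O3.
#'
#' Note the exact mass degeneracies within this vocabulary
#' (C4H10O2 = H2O + C4H8O; C6H10O2 = C2H2O + C4H8O; C6H12O3 = HAc + C4H8O):
#' the chain search resolves them by always preferring the shortest chain.
#'
#' @param labels Character vector of loss labels.
#' @param formulas Character vector of formula strings, parallel to
#'   \code{labels}.
#' @return A data.frame with columns \code{label}, \code{formula},
#'   \code{mass}; every mass is strictly positive.
#' @export
lossVocabulary <- function(labels = c("H2O", "HAc", "C2H2O", "C4H8O",
                                      "C4H10O2", "C6H10O2", "C6H12O3"),
                           formulas = c("H2O", "C2H4O2", "C2H2O", "C4H8O",
                                        "C4H10O2", "C6H10O2", "C6H12O3")) {
  if (length(labels) == 0L) stop("loss vocabulary must not be empty")
  if (length(labels) != length(formulas))
    stop("'labels' and 'formulas' must have the same length")
  mass <- vapply(formulas, monoisotopicMass, numeric(1))
  if (any(mass <= 0)) stop("every neutral loss must have positive mass")
  data.frame(label = labels, formula = formulas, mass = unname(mass),
             stringsAsFactors = FALSE)
}

## All multisets of loss indices up to maxDepth, as a list ordered by depth.
## Each element: list(idx = integer indices into vocab, mass = total mass).
.lossMultisets <- function(vocab, maxDepth) {
  out <- list(list(idx = integer(0), mass = 0))
  frontier <- list(list(idx = integer(0), mass = 0))
  for (d in seq_len(maxDepth)) {
    nxt <- list()
    for (node in frontier) {
      start <- if (length(node$idx)) node$idx[length(node$idx)] else 1L
      for (i in start:nrow(vocab)) {
        child <- list(idx = c(node$idx, i), mass = node$mass + vocab$mass[i])
        nxt[[length(nxt) + 1L]] <- child
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Annotate fragment ions with neutral-loss chains
#'
#' For each fragment, finds the shortest multiset of vocabulary losses
#' (chain depth at most \code{maxDepth}) whose cumulative mass matches
#' \code{precursorMz - fragmentMz} within tolerance. Ties are broken by
#' smallest absolute ppm error, then by lexicographic chain label, so the
#' output is deterministic. Fragments with no matching chain are returned
#' unannotated (empty chain, \code{annotated = FALSE}).
#'
#' The tolerance applied to a fragment at m/z \eqn{m} is
#' \code{max(tolPpm * 1e-6 * m, tolMdaFloor / 1000)} Da: QTOF fragment
#' accuracy is looser than MS1 accuracy and the absolute floor protects
#' low-mass fragments.
#'
#' @param precursorMz Precursor ([M+H]+) m/z; must exceed every fragment.
#' @param fragments Numeric vector of fragment m/z values, or a data.frame
#'   with an \code{mz} column.
#' @param losses Loss vocabulary from \code{\link{lossVocabulary}}.
#' @param tolPpm Relative fragment tolerance in ppm (default 15).
#' @param tolMdaFloor Absolute tolerance floor in mDa (default 3).
#' @param maxDepth Maximum chain length (default 4).
#' @return A data.frame with one row per fragment: \code{fragment_mz},
#'   \code{chain} (loss labels joined with \code{"+"}, \code{""} if none),
#'   \code{depth}, \code{ppm} (error of the fragment against the expected
#'   chain product; \code{NA} when unannotated) and \code{annotated}.
#' @examples
#' annotateLosses(529.3522, c(511.3424, 469.3313))
#' @export
annotateLosses <- function(precursorMz, fragments,
                           losses = lossVocabulary(),
                           tolPpm = 15, tolMdaFloor = 3, maxDepth = 4L) {
  if (is.data.frame(fragments)) fragments <- fragments$mz
  stopifnot(is.numeric(precursorMz), length(precursorMz) == 1L,
            precursorMz > 0, maxDepth >= 1L)
  if (!is.data.frame(losses) || nrow(losses) == 0L)
    stop("empty loss vocabulary")
  if (any(fragments > precursorMz + tolMdaFloor / 1000))
    stop("every fragment m/z must not exceed the precursor m/z")
  sets <- .lossMultisets(losses, maxDepth)
  setMass <- vapply(sets, function(s) sum(losses$mass[s$idx]), numeric(1))
  setDepth <- vapply(sets, function(s) length(s$idx), integer(1))
  rows <- lapply(fragments, function(mz) {
    target <- precursorMz - mz
    tol <- max(tolPpm * 1e-6 * mz, tolMdaFloor / 1000)
    hit <- which(abs(setMass - target) <= tol)
    if (!length(hit))
      return(data.frame(fragment_mz = mz, chain = "", depth = NA_integer_,
                        ppm = NA_real_, annotated = FALSE,
                        stringsAsFactors = FALSE))
    ## shortest chain first, then smallest |ppm|, then lexicographic label
    expMz <- precursorMz - setMass[hit]
    ppm <- (mz - expMz) / expMz * 1e6
    lab <- vapply(hit, function(i) {
      paste(losses$label[sets[[i]]$idx], collapse = "+")
    }, character(1))
    ord <- order(setDepth[hit], abs(ppm), lab)
    best <- ord[1L]
    data.frame(fragment_mz = mz, chain = lab[best],
               depth = setDepth[hit][best], ppm = ppm[best],
               annotated = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
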