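#' @include ProtostaneMS-package.R
NULL

## Monoisotopic atomic masses (Da). Fixed constants so that every mass in the
## package -- and in the test suite -- is bit-stable across platforms.
.ATOMIC_MASSES <- c(
  C = 12.000000,
  H = 1.00782503,
  O = 15.99491462,
  N = 14.00307401,
  S = 31.97207117,
  Na = 22.98976928
)

## Adduct conventions for singly protonated ions. "hydrogen-atom" adds the
## mass of a neutral H atom; "proton" additionally subtracts the electron
## mass. The package default is "hydrogen-atom" (see typeRules()/identify
## documentation and the methods vignette for why).
.ADDUCT_MASSES <- c(
  "hydrogen-atom" = 1.007825,
  "proton"        = 1.007276
)

#' ElementalFormula: an element-to-count map
#'
#' The unit of all mass arithmetic in the package. Counts are non-negative
#' integers over element symbols; C, H and O are always present (possibly
#' zero). The all-zero formula is legal and has mass 0.
#'
#' @slot counts Named integer vector, element symbol -> count.
#'
#' @exportClass ElementalFormula
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
    return("counts must be a named integer vector")
  if (anyNA(cnt) || any(cnt < 0))
    return("element counts must be non-negative integers")
  if (!all(c("C", "H", "O") %in% names(cnt)))
    return("counts must include C, H and O (zero is allowed)")
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbol in counts")
  TRUE
})

#' Construct an elemental formula from counts
#'
#' @param ... Element counts, e.g. \code{elementalFormula(C = 30, H = 48, O = 6)}.
#'   Unnamed arguments are not allowed; missing C/H/O default to zero.
#' @return An \linkS4class{ElementalFormula}.
#' @examples
#' elementalFormula(C = 30, H = 48, O = 6)
#' elementalFormula()            # the empty formula, mass 0
#' @export
elementalFormula <- function(...) {
  cnt <- c(...)
  if (length(cnt) && (is.null(names(cnt)) || any(!nzchar(names(cnt)))))
    stop("all element counts must be named")
  cnt <- vapply(cnt, function(x) as.integer(x), integer(1))
  for (el in c("C", "H", "O"))
    if (!el %in% names(cnt)) cnt[el] <- 0L
  new("ElementalFormula", counts = cnt)
}

#' Parse a molecular formula string
#'
#' Accepts Hill-style strings such as \code{"C30H48O6"}: a sequence of
#' element symbols, each followed by an optional positive integer (an
#' omitted count means 1). The empty string parses to the empty formula.
#'
#' @param text A single formula string.
#' @return An \linkS4class{ElementalFormula}.
#' @examples
#' parseFormula("C30H48O6")
#' parseFormula("H2O")
#' formulaString(parseFormula("C32H50O7"))
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single character string")
  text <- trimws(text)
  if (!nzchar(text)) return(elementalFormula())
  ## tokenize; anything not consumed by element+count tokens is malformed
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste0(toks, collapse = "") != text) {
    residue <- text
    for (t in toks) residue <- sub(t, "", residue, fixed = TRUE)
    stop("malformed formula string near '", substr(residue, 1, 8), "' in '",
         text, "'")
  }
  cnt <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    if (!el %in% names(.ATOMIC_MASSES))
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    n <- gsub("[A-Za-z]", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    cnt[el] <- (if (el %in% names(cnt)) cnt[el] else 0L) + n
  }
  do.call(elementalFormula, as.list(cnt))
}

#' Render a formula in Hill order
#'
#' C first, then H, then the remaining elements alphabetically; elements
#' with zero count are omitted. \code{parseFormula(formulaString(f))}
#' round-trips for every formula.
#'
#' @param f An \linkS4class{ElementalFormula}.
#' @return A single string.
#' @export
formulaString <- function(f) {
  stopifnot(is(f, "ElementalFormula"))
  cnt <- f@counts[f@counts > 0L]
  if (!length(cnt)) return("")
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  paste0(vapply(ord, function(el) {
    if (cnt[el] == 1L) el else paste0(el, cnt[el])
  }, character(1)), collapse = "")
}

setMethod("show", "ElementalFormula", function(object) {
  cat("ElementalFormula:", formulaString(object),
      sprintf("(monoisotopic mass %.6f Da)\n", monoisotopicMass(object)))
})

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the tabulated monoisotopic atomic mass
#' (C 12.000000, H 1.00782503, O 15.99491462, ...).
#'
#' @param f An \linkS4class{ElementalFormula} or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("H2O")        # 18.010565
#' monoisotopicMass("C30H48O6")   # 504.345089
#' @export
monoisotopicMass <- function(f) {
  f <- .asFormula(f)
  cnt <- f@counts
  miss <- setdiff(names(cnt)[cnt > 0L], names(.ATOMIC_MASSES))
  if (length(miss))
    stop("no tabulated monoisotopic mass for element(s): ",
         paste(miss, collapse = ", "))
  sum(cnt * .ATOMIC_MASSES[names(cnt)])
}

.asFormula <- function(f) {
  if (is(f, "ElementalFormula")) f else parseFormula(f)
}

#' Mass added by an adduct convention
#'
#' @param convention \code{"hydrogen-atom"} (+1.007825 Da, the default used
#'   throughout the package) or \code{"proton"} (+1.007276 Da, i.e. corrected
#'   for the electron mass).
#' @return Added mass in Da.
#' @export
adductMass <- function(convention = c("hydrogen-atom", "proton")) {
  convention <- match.arg(convention)
  unname(.ADDUCT_MASSES[convention])
}

#' m/z of the protonated molecular ion [M+H]+
#'
#' @inheritParams monoisotopicMass
#' @inheritParams adductMass
#' @return m/z at charge +1.
#' @examples
#' mzProtonated("C30H48O6")              # 505.352914
#' mzProtonated("C30H48O6", "proton")    # 505.352365
#' @export
mzProtonated <- function(f, convention = c("hydrogen-atom", "proton")) {
  monoisotopicMass(f) + adductMass(convention)
}

#' Signed ppm mass error of an observed [M+H]+ ion
#'
#' \code{(observed - theoretical) / theoretical * 1e6} where the theoretical
#' value is \code{\link{mzProtonated}(f, convention)}.
#'
#' @param observed Observed m/z (> 0); may be a vector.
#' @inheritParams mzProtonated
#' @return Signed ppm error(s).
#' @seealso \code{\link{roundPpm}} for the 1-decimal reporting convention.
#' @examples
#' roundPpm(ppmError(505.3534, "C30H48O6"))   # 1.0
#' @export
ppmError <- function(observed, f, convention = c("hydrogen-atom", "proton")) {
  if (any(!is.finite(observed)) || any(observed <= 0))
    stop("'observed' m/z must be positive and finite")
  th <- mzProtonated(f, convention)
  (observed - th) / th * 1e6
}

#' Round a ppm error for reporting
#'
#' One decimal place, rounding halves away from zero (the convention used
#' when tabulating mass errors).
#'
#' @param ppm Numeric vector of ppm errors.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
roundPpm <- function(ppm, digits = 1L) {
  p <- 10^digits
  sign(ppm) * floor(abs(ppm) * p + 0.5) / p
}

#' Rings-plus-double-bonds equivalent of a CHO formula
#'
#' \code{C - H/2 + 1}; may be half-integer for odd hydrogen counts. The
#' empty formula returns 1 by convention.
#'
#' @inheritParams monoisotopicMass
#' @return RDBE value.
#' @examples
#' rdbe("C30H48O6")   # 7
#' @export
rdbe <- function(f) {
  f <- .asFormula(f)
  cnt <- f@counts
  bad <- setdiff(names(cnt)[cnt > 0L], c("C", "H", "O"))
  if (length(bad))
    stop("rdbe() is defined here for CHO formulas only; found: ",
         paste(bad, collapse = ", "))
  unname(cnt["C"] - cnt["H"] / 2 + 1)
}

#' Search bounds for CHO formula enumeration
#'
#' Defaults are wide enough to contain every protostane triterpenoid in the
#' packaged library while keeping exhaustive search cheap: C 5--40,
#' H 10--64, O 0--10, RDBE 0--15, even-electron species only (even H, so the
#' neutral-molecule RDBE is an integer).
#'
#' @param cMin,cMax,hMin,hMax,oMin,oMax Per-element count bounds.
#' @param rdbeMin,rdbeMax RDBE range for the neutral molecule.
#' @param evenElectron If TRUE, restrict to even hydrogen counts.
#' @return A list of class \code{"EnumerationBounds"}.
#' @export
enumerationBounds <- function(cMin = 5L, cMax = 40L, hMin = 10L, hMax = 64L,
                              oMin = 0L, oMax = 10L,
                              rdbeMin = 0, rdbeMax = 15,
                              evenElectron = TRUE) {
  b <- list(cMin = as.integer(cMin), cMax = as.integer(cMax),
            hMin = as.integer(hMin), hMax = as.integer(hMax),
            oMin = as.integer(oMin), oMax = as.integer(oMax),
            rdbeMin = rdbeMin, rdbeMax = rdbeMax,
            evenElectron = isTRUE(evenElectron))
  if (b$cMin > b$cMax || b$hMin > b$hMax || b$oMin > b$oMax)
    stop("enumeration bounds must satisfy min <= max for every element")
  if (b$rdbeMin > b$rdbeMax) stop("rdbeMin must not exceed rdbeMax")
  class(b) <- "EnumerationBounds"
  b
}

#' Enumerate CHO formulas matching an observed [M+H]+ m/z
#'
#' Returns exactly the CHO formulas inside the bounds whose protonated m/z
#' lies within \code{tolPpm} of \code{observed}, sorted by absolute ppm
#' error and then lexicographically by formula string. An empty result is
#' valid (e.g. at zero tolerance).
#'
#' @param observed Observed m/z of the presumed [M+H]+ ion.
#' @param tolPpm Tolerance in ppm (>= 0).
#' @param bounds An \code{\link{enumerationBounds}} object.
#' @inheritParams adductMass
#' @return A data.frame with columns \code{formula} (string), \code{ppm}
#'   (signed error) and \code{rdbe}.
#' @examples
#' enumerateFormulas(505.3534, tolPpm = 5)   # C30H48O6
#' @export
enumerateFormulas <- function(observed, tolPpm = 5,
                              bounds = enumerationBounds(),
                              convention = c("hydrogen-atom", "proton")) {
  stopifnot(is.numeric(observed), length(observed) == 1L, observed > 0,
            is.numeric(tolPpm), tolPpm >= 0)
  convention <- match.arg(convention)
  if (!inherits(bounds, "EnumerationBounds"))
    stop("'bounds' must come from enumerationBounds()")
  add <- adductMass(convention)
  target <- observed - add
  tolAbs <- tolPpm * 1e-6 * observed
  mH <- .ATOMIC_MASSES[["H"]]
  mO <- .ATOMIC_MASSES[["O"]]
  out <- list()
  for (C in bounds$cMin:bounds$cMax) {
    for (O in bounds$oMin:bounds$oMax) {
      rem <- target - C * 12 - O * mO
      hLo <- max(bounds$hMin, ceiling((rem - tolAbs) / mH))
      hHi <- min(bounds$hMax, floor((rem + tolAbs) / mH))
      if (hLo > hHi) next
      for (H in hLo:hHi) {
        if (bounds$evenElectron && H %% 2L != 0L) next
        r <- C - H / 2 + 1
        if (r < bounds$rdbeMin || r > bounds$rdbeMax) next
        th <- C * 12 + H * mH + O * mO + add
        ppm <- (observed - th) / th * 1e6
        if (abs(ppm) > tolPpm) next
        out[[length(out) + 1L]] <- data.frame(
          formula = formulaString(elementalFormula(C = C, H = H, O = O)),
          ppm = ppm, rdbe = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(formula = character(0), ppm = numeric(0),
                      rdbe = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}
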