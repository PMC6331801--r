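#' @include feature.R neutral-losses.R
NULL

#' Classification rules for the seven protostane structural types
#'
#' Each structural type is recognised by a characteristic skeleton ion --
#' the product of C-23--C-24 bond dissociation -- together with the UV
#' absorbance class of the feature. The skeleton ion m/z values are the
#' empirical values observed on the instrument (397.2745 for types I/II,
#' 383.2983 for III, 339.2684 for IV, 385.3102 for V, 399.2896 for VI/VII),
#' matched at +/-15 ppm; they are deliberately not recomputed from candidate
#' fragment formulas, since the skeleton-ion compositions are not assigned
#' and the empirical values are the operative fingerprint.
#'
#' UV classes: "287" (pi-pi-pi conjugation across C11--C17, lambda-max
#' 287 +/- 5 nm), "245" (lambda-max 245 +/- 5 nm), "none" (absorption absent
#' or below 200 nm). Types that share a skeleton ion (I/II at 397.27, VI/VII
#' at 399.29) are separated by UV class alone.
#'
#' Rules are evaluated in precedence order IV, V, III, VI, VII, I, II --
#' rarer, more specific ions first -- stopping at the first rule whose ion
#' and UV class both match.
#'
#' @return A data.frame with columns \code{type}, \code{ion_mz},
#'   \code{uv_class}, in precedence order.
#' @export
typeRules <- function() {
  data.frame(
    type = c("IV", "V", "III", "VI", "VII", "I", "II"),
    ion_mz = c(339.2684, 385.3102, 383.2983, 399.2896, 399.2896,
               397.2745, 397.2745),
    uv_class = c("none", "none", "none", "none", "245", "287", "245"),
    stringsAsFactors = FALSE
  )
}

#' UV absorbance class of a lambda-max value
#'
#' @param lambdaMax Wavelength in nm, or \code{NA}.
#' @param window Half-width of the acceptance windows (default 5 nm).
#' @return \code{"287"}, \code{"245"} or \code{"none"}.
#' @export
uvClass <- function(lambdaMax, window = 5) {
  if (is.na(lambdaMax) || lambdaMax < 200) return("none")
  if (abs(lambdaMax - 287) <= window) return("287")
  if (abs(lambdaMax - 245) <= window) return("245")
  "none"
}

#' Assign a protostane structural type to a feature
#'
#' A type is assigned iff some fragment matches a rule's characteristic
#' skeleton ion within \code{tolPpm} and the feature's UV class equals the
#' rule's. The result depends only on which fragment m/z are present, so it
#' is invariant to fragment order and intensity scaling.
#'
#' @param feature A \linkS4class{FeatureRecord}.
#' @param rules Rule table from \code{\link{typeRules}}.
#' @param tolPpm Matching tolerance for the characteristic ion (default 15).
#' @return The assigned type as a character scalar (\code{"I"} ...
#'   \code{"VII"}), or \code{NA_character_} when unclassified; the latter
#'   carries a \code{"reason"} attribute for diagnostics.
#' @examples
#' f <- featureRecord(469.3315, 25.91, c(451.3216, 397.2745), uvLambdaMax = 287)
#' classifyType(f)   # "I"
#' @export
classifyType <- function(feature, rules = typeRules(), tolPpm = 15) {
  stopifnot(is(feature, "FeatureRecord"))
  if (!is.data.frame(rules) || nrow(rules) == 0L)
    stop("'rules' must be a non-empty rule table")
  mz <- fragmentPeaks(feature)$mz
  if (!length(mz)) {
    out <- NA_character_
    attr(out, "reason") <- "no fragments"
    return(out)
  }
  uv <- uvClass(uvLambdaMax(feature))
  ionSeen <- FALSE
  for (i in seq_len(nrow(rules))) {
    hit <- any(abs(mz - rules$ion_mz[i]) <= tolPpm * 1e-6 * rules$ion_mz[i])
    if (!hit) next
    ionSeen <- TRUE
    if (uv == rules$uv_class[i]) return(rules$type[i])
  }
  out <- NA_character_
  attr(out, "reason") <- if (ionSeen)
    sprintf("characteristic ion present but UV class '%s' matches no rule", uv)
  else "no characteristic skeleton ion found"
  out
}

## number of library expected fragments matched by the feature's peaks
.fragmentHits <- function(featMz, expectedMz, tolPpm, tolMdaFloor) {
  if (!length(expectedMz) || !length(featMz)) return(0L)
  sum(vapply(expectedMz, function(e) {
    tol <- max(tolPpm * 1e-6 * e, tolMdaFloor / 1000)
    any(abs(featMz - e) <= tol)
  }, logical(1)))
}

#' Identify a feature against the reference library
#'
#' Implements the two-tier identification workflow. A \emph{standard-match}
#' requires a standard-confirmed library entry agreeing on retention time
#' (\code{|dt| <= rtWindow}), on precursor formula (observed [M+H]+ within
#' \code{ms1TolPpm} of the entry's theoretical value) and on at least
#' \code{minFragmentHits} expected fragment ions. Failing that, the feature
#' is \emph{tentatively} identified from its accurate mass
#' (\code{\link{enumerateFormulas}}) and fragmentation type
#' (\code{\link{classifyType}}); if neither yields anything the feature is
#' \emph{unidentified}.
#'
#' @param feature A \linkS4class{FeatureRecord}.
#' @param library Library data.frame as returned by
#'   \code{\link{loadFixtures}("library")}.
#' @param rtWindow Retention-time window in minutes (default 0.5).
#' @param ms1TolPpm Precursor mass tolerance in ppm (default 5).
#' @param minFragmentHits Minimum matched expected fragments (default 2).
#' @param fragTolPpm,fragTolMdaFloor Fragment matching tolerance.
#' @param convention Adduct convention for [M+H]+ (see
#'   \code{\link{adductMass}}).
#' @param rules,bounds Passed to \code{\link{classifyType}} and
#'   \code{\link{enumerateFormulas}}.
#' @return A one-row data.frame: \code{feature_id}, \code{rt_min},
#'   \code{precursor_mz}, \code{mode} (\code{"standard-match"},
#'   \code{"tentative"} or \code{"unidentified"}), \code{matched_name},
#'   \code{assigned_formula}, \code{assigned_type}, \code{ms1_ppm},
#'   \code{n_fragment_hits}.
#' @export
identifyFeature <- function(feature, library,
                            rtWindow = 0.5, ms1TolPpm = 5,
                            minFragmentHits = 2L,
                            fragTolPpm = 15, fragTolMdaFloor = 3,
                            convention = c("hydrogen-atom", "proton"),
                            rules = typeRules(),
                            bounds = enumerationBounds()) {
  stopifnot(is(feature, "FeatureRecord"))
  if (!is.data.frame(library) || nrow(library) == 0L)
    stop("'library' must be a non-empty library table")
  convention <- match.arg(convention)
  featMz <- fragmentPeaks(feature)$mz
  obs <- precursorMz(feature)

  res <- data.frame(feature_id = featureId(feature),
                    rt_min = retentionTime(feature),
                    precursor_mz = obs,
                    mode = "unidentified",
                    matched_name = NA_character_,
                    assigned_formula = NA_character_,
                    assigned_type = NA_character_,
                    ms1_ppm = NA_real_,
                    n_fragment_hits = NA_integer_,
                    stringsAsFactors = FALSE)

  ## tier 1: match against standard-confirmed entries
  cand <- which(library$standard_confirmed &
                  abs(library$rt_min - retentionTime(feature)) <= rtWindow)
  if (length(cand)) {
    ppm <- vapply(cand, function(i)
      ppmError(obs, library$formula[i], convention), numeric(1))
    hits <- vapply(cand, function(i)
      .fragmentHits(featMz, library$fragment_mz[[i]],
                    fragTolPpm, fragTolMdaFloor), integer(1))
    ok <- abs(ppm) <= ms1TolPpm & hits >= minFragmentHits
    if (any(ok)) {
      ## deterministic choice: smallest |ppm|, then smallest |dt|
      dts <- abs(library$rt_min[cand] - retentionTime(feature))
      pick <- which(ok)[order(abs(ppm[ok]), dts[ok])][1L]
      i <- cand[pick]
      res$mode <- "standard-match"
      res$matched_name <- library$name[i]
      res$assigned_formula <- library$formula[i]
      res$assigned_type <- library$type[i]
      res$ms1_ppm <- ppm[pick]
      res$n_fragment_hits <- hits[pick]
      return(res)
    }
  }

  ## tier 2: tentative from accurate mass and fragmentation type
  forms <- enumerateFormulas(obs, tolPpm = ms1TolPpm, bounds = bounds,
                             convention = convention)
  type <- classifyType(feature, rules = rules)
  if (nrow(forms) || !is.na(type)) {
    res$mode <- "tentative"
    if (nrow(forms)) {
      res$assigned_formula <- forms$formula[1L]
      res$ms1_ppm <- forms$ppm[1L]
    }
    res$assigned_type <- as.character(type)
  }
  res
}

#' Annotate a batch of features
#'
#' Runs loss annotation, type classification and library identification on
#' every feature, and tallies the outcome. This is the batch driver that
#' produces a report shaped like the reference characterisation table.
#'
#' @param features A list of \linkS4class{FeatureRecord} objects.
#' @param library Library table (default: the packaged 25-compound library).
#' @param losses Loss vocabulary for \code{\link{annotateLosses}}.
#' @param maxDepth Maximum loss-chain depth (default 4).
#' @param ... Further arguments passed to \code{\link{identifyFeature}}.
#' @return A list with elements \code{results} (one data.frame row per
#'   feature, as in \code{\link{identifyFeature}}), \code{losses} (named
#'   list of per-feature loss-annotation tables) and \code{summary} (counts:
#'   \code{n_features}, \code{n_identified}, \code{n_standard_match},
#'   \code{n_tentative}, \code{type_tally}).
#' @examples
#' lib <- loadFixtures("library")
#' rep <- annotateRun(referenceFeatures(lib), lib)
#' rep$summary$n_identified
#' @export
annotateRun <- function(features, library = loadFixtures("library"),
                        losses = lossVocabulary(), maxDepth = 4L, ...) {
  if (!length(features))
    return(list(results = data.frame(), losses = list(),
                summary = list(n_features = 0L, n_identified = 0L,
                               n_standard_match = 0L, n_tentative = 0L,
                               type_tally = table(character(0)))))
  rows <- lapply(features, identifyFeature, library = library, ...)
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  lossTabs <- lapply(features, function(f) {
    annotateLosses(precursorMz(f), fragmentPeaks(f)$mz, losses = losses,
                   maxDepth = maxDepth)
  })
  names(lossTabs) <- results$feature_id
  tally <- table(factor(results$assigned_type,
                        levels = c("I", "II", "III", "IV", "V", "VI", "VII")))
  list(results = results, losses = lossTabs,
       summary = list(
         n_features = nrow(results),
         n_identified = sum(results$mode != "unidentified"),
         n_standard_match = sum(results$mode == "standard-match"),
         n_tentative = sum(results$mode == "tentative"),
         type_tally = tally))
}

#' Build FeatureRecords from the packaged reference library
#'
#' Reconstructs one feature per library entry from its recorded retention
#' time, observed precursor m/z, fragment list and UV lambda-max -- i.e. the
#' feature set the identification workflow was characterised on.
#'
#' @param library Library table from \code{\link{loadFixtures}("library")}.
#' @return A list of \linkS4class{FeatureRecord} objects, one per entry.
#' @export
referenceFeatures <- function(library = loadFixtures("library")) {
  lapply(seq_len(nrow(library)), function(i) {
    featureRecord(precursorMz = library$ms1_mz[i],
                  retentionTime = library$rt_min[i],
                  fragmentMz = library$fragment_mz[[i]],
                  uvLambdaMax = library$lambda_max[i],
                  featureId = sprintf("peak%02d", library$peak[i]))
  })
}
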