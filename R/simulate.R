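#' @include annotate.R quant.R
NULL

#' Configuration of the synthetic-data generator
#'
#' The generator stands in for the two instruments. Noise models are the
#' simplest ones consistent with the scales the method reports: additive
#' Gaussian error in ppm space on m/z values (MS1 sigma 2 ppm, fragment
#' sigma 5 ppm), Bernoulli fragment dropout (0.2), multiplicative Gaussian
#' noise on peak areas (CV 5%), and lognormal between-sample content
#' variation (CV 30%).
#'
#' One global seed expands into fixed per-stage substreams, so each stage
#' can be regenerated independently and every generator is a pure function
#' of (inputs, seed).
#'
#' @param seed Integer seed recorded in every output.
#' @param ms1SigmaPpm MS1 mass-error sigma in ppm (default 2).
#' @param fragmentSigmaPpm Fragment mass-error sigma in ppm (default 5).
#' @param fragmentDropoutProb Per-fragment dropout probability (default 0.2).
#' @param rtJitterMin Half-width of uniform retention-time jitter in
#'   minutes (default 0.1).
#' @param areaCv CV of the multiplicative area noise (default 0.05).
#' @param isAreaMean,isAreaCv Mean and CV of the per-injection internal
#'   standard area.
#' @param contentLognormalCv Between-sample lognormal CV of true contents
#'   (default 0.3).
#' @param groupEffect Optional named numeric vector of per-analyte
#'   multiplicative Sichuan/Fujian content ratios (NULL keeps the ratios
#'   implied by the content table the generator is given).
#' @param nReplicates Injection replicates per sample (default 3).
#' @param nFujian,nSichuan Samples per origin group (defaults 21 and 22,
#'   the batch structure of the packaged study).
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, ms1SigmaPpm = 2, fragmentSigmaPpm = 5,
                      fragmentDropoutProb = 0.2, rtJitterMin = 0.1,
                      areaCv = 0.05, isAreaMean = 1e5, isAreaCv = 0.05,
                      contentLognormalCv = 0.3, groupEffect = NULL,
                      nReplicates = 3L, nFujian = 21L, nSichuan = 22L) {
  cfg <- list(seed = as.integer(seed), ms1SigmaPpm = ms1SigmaPpm,
              fragmentSigmaPpm = fragmentSigmaPpm,
              fragmentDropoutProb = fragmentDropoutProb,
              rtJitterMin = rtJitterMin, areaCv = areaCv,
              isAreaMean = isAreaMean, isAreaCv = isAreaCv,
              contentLognormalCv = contentLognormalCv,
              groupEffect = groupEffect,
              nReplicates = as.integer(nReplicates),
              nFujian = as.integer(nFujian), nSichuan = as.integer(nSichuan))
  if (cfg$fragmentDropoutProb < 0 || cfg$fragmentDropoutProb > 1)
    stop("fragmentDropoutProb must lie in [0, 1]")
  if (any(c(cfg$ms1SigmaPpm, cfg$fragmentSigmaPpm, cfg$areaCv, cfg$isAreaCv,
            cfg$contentLognormalCv, cfg$rtJitterMin) < 0))
    stop("sigmas and CVs must be non-negative")
  class(cfg) <- "SimConfig"
  cfg
}

## per-stage substream seed, kept inside 32-bit integer range
.stageSeed <- function(cfg, stage) {
  off <- c(qtof = 1L, contents = 2L, mrm = 3L, dilution = 4L, arms = 5L)
  as.integer((as.numeric(cfg$seed) * 7919 + off[[stage]]) %% 2147483647)
}

#' Simulate QTOF features from the reference library
#'
#' One feature per library entry: the precursor is the theoretical [M+H]+
#' m/z of the entry's formula perturbed by Normal(0, ms1SigmaPpm) relative
#' error; fragments are the entry's recorded fragment list with per-peak
#' ppm jitter and Bernoulli dropout; retention time gets uniform jitter;
#' the UV lambda-max follows the entry's structural type (287 nm for type
#' I, 245 nm for types II and VII, none otherwise). With all noise
#' parameters zero the features reproduce the library exactly (precursor =
#' theoretical [M+H]+).
#'
#' @param library Library table from \code{\link{loadFixtures}("library")}.
#' @param cfg A \code{\link{simConfig}}.
#' @return A list: \code{features} (list of \linkS4class{FeatureRecord})
#'   and \code{truth} (data.frame \code{feature_id}, \code{name},
#'   \code{formula}, \code{type}, plus the seed as an attribute).
#' @export
simulateQtofFeatures <- function(library, cfg = simConfig()) {
  if (!is.data.frame(library) || nrow(library) == 0L)
    stop("'library' must be a non-empty library table")
  set.seed(.stageSeed(cfg, "qtof"))
  uvForType <- c(I = 287, II = 245, III = NA, IV = NA, V = NA, VI = NA,
                 VII = 245)
  features <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    theo <- mzProtonated(library$formula[i])
    prec <- theo * (1 + rnorm(1) * cfg$ms1SigmaPpm * 1e-6)
    frag <- library$fragment_mz[[i]]
    keep <- runif(length(frag)) >= cfg$fragmentDropoutProb
    frag <- frag[keep]
    frag <- frag * (1 + rnorm(length(frag)) * cfg$fragmentSigmaPpm * 1e-6)
    rt <- library$rt_min[i] + runif(1, -cfg$rtJitterMin, cfg$rtJitterMin)
    features[[i]] <- featureRecord(
      precursorMz = prec, retentionTime = rt, fragmentMz = frag,
      fragmentIntensity = runif(length(frag), 100, 1000),
      uvLambdaMax = unname(uvForType[library$type[i]]),
      featureId = sprintf("sim%02d", library$peak[i]))
  }
  truth <- data.frame(feature_id = vapply(features, featureId, character(1)),
                      name = library$name, formula = library$formula,
                      type = library$type, stringsAsFactors = FALSE)
  attr(truth, "seed") <- cfg$seed
  list(features = features, truth = truth)
}

#' Simulate true contents for a two-origin batch
#'
#' Per analyte and origin group, contents are drawn lognormally around the
#' group mean of a template content table (ND cells excluded from the
#' means), with \code{contentLognormalCv} between-sample variation -- so
#' simulated effect sizes match the template's. An optional
#' \code{groupEffect} rescales the Sichuan means.
#'
#' @param template A \linkS4class{ContentMatrix} to take per-origin means
#'   from (default: the packaged 43-batch table).
#' @param cfg A \code{\link{simConfig}}.
#' @return A \linkS4class{ContentMatrix} with \code{nFujian + nSichuan}
#'   samples.
#' @export
simulateContents <- function(template = loadFixtures("contents"),
                             cfg = simConfig()) {
  set.seed(.stageSeed(cfg, "contents"))
  m <- contentValues(template)
  org <- origins(template)
  n <- c(Fujian = cfg$nFujian, Sichuan = cfg$nSichuan)
  cv <- cfg$contentLognormalCv
  sdlog <- sqrt(log(1 + cv^2))
  out <- matrix(NA_real_, nrow(m), sum(n),
                dimnames = list(rownames(m),
                                paste0("sim", seq_len(sum(n)))))
  outOrg <- rep(names(n), n)
  for (an in rownames(m)) {
    for (g in names(n)) {
      mu <- mean(m[an, org == g], na.rm = TRUE)
      if (g == "Sichuan" && !is.null(cfg$groupEffect) &&
          an %in% names(cfg$groupEffect))
        mu <- mean(m[an, org == "Fujian"], na.rm = TRUE) *
          cfg$groupEffect[[an]]
      meanlog <- log(mu) - sdlog^2 / 2
      out[an, outOrg == g] <- exp(rnorm(n[[g]], meanlog, sdlog))
    }
  }
  ContentMatrix(out, origin = outOrg)
}

#' Simulate MRM peak areas from known contents
#'
#' The exact inverse of \code{\link{quantifyBatch}} plus noise: the true
#' content is converted back to an injected-solution concentration, pushed
#' through the analyte's calibration curve to an area ratio, and multiplied
#' by a per-injection internal-standard area; multiplicative Gaussian noise
#' at \code{areaCv} is applied to the analyte area and the IS area is drawn
#' per injection. ND cells of the truth (below-LOD contents) are emitted at
#' half the analyte's LOD so the quantification stage reports them as ND.
#' With all noise zero, \code{quantifyBatch} recovers the truth exactly.
#'
#' @param curves Curve registry (table or named list, see
#'   \code{\link{quantifyBatch}}).
#' @param trueContents A \linkS4class{ContentMatrix} of true mg/g contents.
#' @param cfg A \code{\link{simConfig}}.
#' @param prep \code{\link{prepConstants}}.
#' @param lods Optional named LOD vector (ng/mL) used to emit ND cells.
#' @return A list: \code{areas} (long data.frame \code{sample_id},
#'   \code{analyte}, \code{replicate}, \code{area}, \code{is_area}),
#'   \code{truth} (the input \linkS4class{ContentMatrix}) and
#'   \code{origin} (named vector for \code{\link{quantifyBatch}}).
#' @export
simulateMrmBatch <- function(curves, trueContents, cfg = simConfig(),
                             prep = prepConstants(), lods = NULL) {
  curves <- .asCurveList(curves)
  set.seed(.stageSeed(cfg, "mrm"))
  m <- contentValues(trueContents)
  missing <- setdiff(rownames(m), names(curves))
  if (length(missing))
    stop("no calibration curve for analyte(s): ",
         paste(missing, collapse = ", "))
  factor <- prep$is_mix_dilution * prep$extraction_volume /
    (prep$sample_mass * 1000)
  rows <- vector("list", nrow(m) * ncol(m) * cfg$nReplicates)
  k <- 0L; nOutside <- 0L
  for (s in colnames(m)) {
    for (an in rownames(m)) {
      cur <- curves[[an]]
      x <- m[an, s] / factor
      if (is.na(x))
        x <- if (!is.null(lods) && an %in% names(lods))
          lods[[an]] / 1000 / 2 else 0
      if (x < cur@rangeLow || x > cur@rangeHigh) nOutside <- nOutside + 1L
      y <- cur@slope * x + cur@intercept
      for (r in seq_len(cfg$nReplicates)) {
        isArea <- cfg$isAreaMean * (1 + rnorm(1) * cfg$isAreaCv)
        area <- max(y * isArea * (1 + rnorm(1) * cfg$areaCv), 0)
        k <- k + 1L
        rows[[k]] <- data.frame(sample_id = s, analyte = an, replicate = r,
                                area = area, is_area = isArea,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (nOutside)
    warning(nOutside, " sample x analyte cell(s) fall outside the linear ",
            "range; areas generated anyway")
  areas <- do.call(rbind, rows)
  org <- setNames(origins(trueContents), colnames(m))
  list(areas = areas, truth = trueContents, origin = org)
}

#' Simulate a dilution series with an analytically known LOD
#'
#' A 2-fold dilution ladder with signal = response x concentration (with
#' multiplicative jitter at \code{areaCv}) over a constant noise floor, so
#' the true S/N is \code{response * concentration / noiseFloor} and the
#' analytic LOD and LOQ are \code{3 * noiseFloor / response} and
#' \code{10 * noiseFloor / response} (stored as attributes).
#'
#' @param analyte Analyte name (metadata only).
#' @param response Signal per unit concentration.
#' @param noiseFloor Constant noise level (> 0).
#' @param cfg A \code{\link{simConfig}}.
#' @param topConc Highest concentration of the ladder (ug/mL).
#' @param nLevels Number of 2-fold dilution levels.
#' @return A data.frame (\code{concentration}, \code{signal}, \code{noise})
#'   with attributes \code{analytic_lod} and \code{analytic_loq}.
#' @export
simulateDilutionSeries <- function(analyte = "standard", response = 300,
                                   noiseFloor = 1, cfg = simConfig(),
                                   topConc = 1, nLevels = 14L) {
  if (noiseFloor <= 0) stop("'noiseFloor' must be positive")
  set.seed(.stageSeed(cfg, "dilution"))
  conc <- topConc / 2^(seq_len(nLevels) - 1L)
  signal <- response * conc * (1 + rnorm(nLevels) * cfg$areaCv)
  out <- data.frame(concentration = conc, signal = signal,
                    noise = noiseFloor)
  attr(out, "analyte") <- analyte
  attr(out, "analytic_lod") <- 3 * noiseFloor / response
  attr(out, "analytic_loq") <- 10 * noiseFloor / response
  out
}

#' Simulate all method-validation arms
#'
#' Generates, per analyte, the replicate sets of a standard validation
#' design: intra-day precision (6 injections), inter-day precision
#' (duplicates on 3 days), repeatability (6 independent preparations),
#' stability (7 timepoints at 0--24 h, with optional linear drift) and
#' spike recovery (6 replicates spiked at 100\% of the native content).
#' All measurements carry multiplicative Gaussian noise at \code{cv}; with
#' \code{cv = 0} and no drift every RSD is 0 and every recovery is 100\%.
#'
#' @param trueContent Named numeric vector of native contents per analyte.
#' @param cfg A \code{\link{simConfig}}.
#' @param cv Measurement CV (defaults to \code{cfg$areaCv}).
#' @param stabilityDriftPerHour Fractional signal drift per hour (default 0).
#' @param spikeFraction Spike level as a fraction of native content
#'   (default 1, i.e. ~100\%).
#' @return A list of arms suitable for \code{\link{validationReport}},
#'   plus a \code{truth} element.
#' @export
simulateValidationArms <- function(trueContent, cfg = simConfig(),
                                   cv = cfg$areaCv,
                                   stabilityDriftPerHour = 0,
                                   spikeFraction = 1) {
  stopifnot(is.numeric(trueContent), !is.null(names(trueContent)))
  set.seed(.stageSeed(cfg, "arms"))
  noisy <- function(x, n) x * (1 + rnorm(n) * cv)
  hours <- c(0, 4, 8, 12, 16, 20, 24)
  arms <- list(intra_day = list(), inter_day = list(),
               repeatability = list(), stability = list(), recovery = list())
  for (an in names(trueContent)) {
    m <- trueContent[[an]]
    arms$intra_day[[an]] <- noisy(m, 6L)
    arms$inter_day[[an]] <- noisy(m, 6L)   # 2 injections x 3 days
    arms$repeatability[[an]] <- noisy(m, 6L)
    arms$stability[[an]] <- m * (1 + stabilityDriftPerHour * hours) *
      (1 + rnorm(length(hours)) * cv)
    added <- spikeFraction * m
    arms$recovery[[an]] <- data.frame(
      detected = noisy(m + added, 6L), original = m, added = added)
  }
  arms$truth <- trueContent
  arms
}
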