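#' @include annotate.R quant.R
NULL

.fixtureFiles <- c(
  transitions = "mrm_transitions.csv",
  library = "compound_library.csv",
  curves = "calibration_curves.csv",
  contents = "batch_contents.csv"
)

#' Load a packaged fixture table
#'
#' The four reference tables shipped with the package: the MRM transition
#' registry (14 analytes + 1 internal standard), the 25-compound QTOF
#' reference library, the 14 calibration curves with LOD/LOQ values, and
#' the 43-batch content table. Each table is shape-validated on load; a
#' mismatch raises a fixture-corruption error.
#'
#' @param name One of \code{"transitions"}, \code{"library"},
#'   \code{"curves"}, \code{"contents"}.
#' @return \code{"contents"} returns a \linkS4class{ContentMatrix}; the
#'   other names return a data.frame. The library table carries the
#'   fragment list parsed into list-columns \code{fragment_mz} and
#'   \code{fragment_losses} (each chain a character vector of loss labels).
#' @examples
#' nrow(loadFixtures("library"))       # 25
#' loadFixtures("contents")
#' @export
loadFixtures <- function(name = c("transitions", "library", "curves",
                                  "contents")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixtureFiles[[name]],
                      package = "ProtostaneMS", mustWork = TRUE)
  switch(name,
    transitions = {
      tab <- read.csv(path, check.names = FALSE)
      if (nrow(tab) != 15L || sum(tab$is_internal_standard) != 1L)
        stop("fixture corruption: transition registry must have 15 rows ",
             "with exactly one internal standard")
      tab
    },
    library = {
      tab <- read.csv(path, check.names = FALSE)
      tab$fragment_mz <- lapply(strsplit(tab$fragments, ";", fixed = TRUE),
                                function(fr) {
        as.numeric(vapply(strsplit(fr, ":", fixed = TRUE), `[`, character(1),
                          1L))
      })
      tab$fragment_losses <- lapply(strsplit(tab$fragments, ";",
                                             fixed = TRUE), function(fr) {
        vapply(strsplit(fr, ":", fixed = TRUE), `[`, character(1), 2L)
      })
      if (nrow(tab) != 25L || sum(tab$standard_confirmed) != 21L ||
          sum(tab$quantified) != 14L)
        stop("fixture corruption: library must have 25 entries, 21 ",
             "standard-confirmed, 14 quantified")
      tab
    },
    curves = {
      tab <- read.csv(path, check.names = FALSE)
      if (nrow(tab) != 14L || any(tab$slope <= 0) ||
          any(tab$range_low >= tab$range_high))
        stop("fixture corruption: calibration table must have 14 valid ",
             "curves")
      tab
    },
    contents = {
      cm <- readContentMatrix(path)
      if (ncol(contentValues(cm)) != 43L ||
          nrow(contentValues(cm)) != 14L ||
          sum(origins(cm) == "Fujian") != 21L)
        stop("fixture corruption: content table must be 43 samples x 14 ",
             "analytes with 21 Fujian batches")
      cm
    })
}

#' Read / write content matrices as wide CSV
#'
#' The on-disk dialect mirrors the published content table: one row per
#' sample, columns \code{sample_id}, \code{origin}, then one column per
#' analyte, with the literal sentinel \code{"ND"} for below-LOD cells.
#' Decimal separator is always the period, encoding UTF-8.
#'
#' @param path CSV file path.
#' @return \code{readContentMatrix}: a \linkS4class{ContentMatrix}.
#' @export
readContentMatrix <- function(path) {
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "origin") %in% names(tab)))
    stop("content CSV needs 'sample_id' and 'origin' columns")
  analytes <- setdiff(names(tab), c("sample_id", "origin"))
  m <- vapply(analytes, function(a) {
    v <- tab[[a]]
    v[v == "ND"] <- NA
    as.numeric(v)
  }, numeric(nrow(tab)))
  m <- matrix(m, nrow = nrow(tab), dimnames = list(NULL, analytes))
  m <- t(m)
  colnames(m) <- tab$sample_id
  ContentMatrix(m, origin = tab$origin)
}

#' @rdname readContentMatrix
#' @param x A \linkS4class{ContentMatrix}.
#' @param digits Decimal places written (default 3, the reporting
#'   precision of mg/g contents).
#' @export
writeContentMatrix <- function(x, path, digits = 3L) {
  stopifnot(is(x, "ContentMatrix"))
  m <- contentValues(x)
  wide <- data.frame(sample_id = colnames(m), origin = origins(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
  for (an in rownames(m)) {
    v <- formatC(m[an, ], format = "f", digits = digits)
    v[is.na(m[an, ])] <- "ND"
    wide[[an]] <- v
  }
  write.csv(wide, path, row.names = FALSE, quote = TRUE, fileEncoding =
              "UTF-8")
  invisible(path)
}

#' Read / write long-format MRM area tables
#'
#' Columns: \code{sample_id}, \code{analyte}, \code{replicate},
#' \code{area}, \code{is_area}.
#'
#' @param path CSV file path.
#' @export
readAreaTable <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  need <- c("sample_id", "analyte", "area", "is_area")
  if (!all(need %in% names(tab)))
    stop("area CSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readAreaTable
#' @param areas Long-format area data.frame.
#' @export
writeAreaTable <- function(areas, path) {
  write.csv(areas, path, row.names = FALSE, quote = TRUE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write feature peak lists as MGF
#'
#' A minimal Mascot Generic Format dialect: one \code{BEGIN IONS} /
#' \code{END IONS} block per feature with \code{TITLE}, \code{PEPMASS},
#' \code{RTINSECONDS}, the non-standard extension key \code{UVLAMBDAMAX}
#' (nm; omitted when absent), and one \code{mz intensity} pair per line.
#'
#' @param path MGF file path.
#' @return \code{readMgf}: a list of \linkS4class{FeatureRecord}.
#' @export
readMgf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  starts <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  lapply(seq_along(starts), function(i) {
    blk <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    kv <- grep("=", blk, fixed = TRUE, value = TRUE)
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    getv <- function(k, default = NA) {
      if (k %in% keys) vals[match(k, keys)] else default
    }
    peaks <- blk[!grepl("=", blk, fixed = TRUE) & nzchar(trimws(blk))]
    pm <- do.call(rbind, lapply(strsplit(trimws(peaks), "\\s+"),
                                as.numeric))
    featureRecord(
      precursorMz = as.numeric(strsplit(getv("PEPMASS"), "\\s+")[[1]][1]),
      retentionTime = as.numeric(getv("RTINSECONDS", "0")) / 60,
      fragmentMz = if (length(peaks)) pm[, 1] else numeric(0),
      fragmentIntensity = if (length(peaks)) pm[, 2] else numeric(0),
      uvLambdaMax = as.numeric(getv("UVLAMBDAMAX", NA)),
      featureId = getv("TITLE", NA_character_))
  })
}

#' @rdname readMgf
#' @param features List of \linkS4class{FeatureRecord}.
#' @export
writeMgf <- function(features, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (f in features) {
    writeLines("BEGIN IONS", con)
    if (!is.na(featureId(f)))
      writeLines(paste0("TITLE=", featureId(f)), con)
    writeLines(sprintf("PEPMASS=%.6f", precursorMz(f)), con)
    writeLines(sprintf("RTINSECONDS=%.3f", retentionTime(f) * 60), con)
    if (!is.na(uvLambdaMax(f)))
      writeLines(sprintf("UVLAMBDAMAX=%g", uvLambdaMax(f)), con)
    pk <- fragmentPeaks(f)
    if (nrow(pk))
      writeLines(sprintf("%.6f %.2f", pk$mz, pk$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Write an annotation report
#'
#' Writes the per-feature identification table as CSV and the run summary
#' as JSON, mirroring the column layout of the reference characterisation
#' table.
#'
#' @param report Result of \code{\link{annotateRun}}.
#' @param csvPath,jsonPath Output paths (either may be NULL to skip).
#' @export
writeAnnotationReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(report$results, csvPath, row.names = FALSE, quote = TRUE,
              fileEncoding = "UTF-8")
  if (!is.null(jsonPath)) {
    summ <- report$summary
    summ$type_tally <- as.list(summ$type_tally)
    jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline in one serializable object, with
#' defaults matching the analytical method the package implements. A run's
#' effective configuration can be echoed to YAML alongside its outputs.
#'
#' @param ms1TolPpm MS1 / precursor tolerance in ppm (default 5).
#' @param fragTolPpm,fragTolMdaFloor Fragment tolerance (15 ppm, 3 mDa
#'   floor).
#' @param adduct Adduct convention (see \code{\link{adductMass}}).
#' @param rtWindow Retention-time window in minutes (default 0.5).
#' @param minFragmentHits Minimum matched fragments for a standard match.
#' @param maxLossDepth Maximum neutral-loss chain depth (default 4).
#' @param tTestVariant \code{"student"} (pooled variance) or
#'   \code{"welch"}.
#' @param alpha Significance level for group flags (default 0.05).
#' @param seed Simulation seed.
#' @param prep \code{\link{prepConstants}}.
#' @return A named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(ms1TolPpm = 5, fragTolPpm = 15,
                           fragTolMdaFloor = 3,
                           adduct = c("hydrogen-atom", "proton"),
                           rtWindow = 0.5, minFragmentHits = 2L,
                           maxLossDepth = 4L,
                           tTestVariant = c("student", "welch"),
                           alpha = 0.05, seed = 1L,
                           prep = prepConstants()) {
  cfg <- list(ms1TolPpm = ms1TolPpm, fragTolPpm = fragTolPpm,
              fragTolMdaFloor = fragTolMdaFloor,
              adduct = match.arg(adduct), rtWindow = rtWindow,
              minFragmentHits = as.integer(minFragmentHits),
              maxLossDepth = as.integer(maxLossDepth),
              tTestVariant = match.arg(tTestVariant), alpha = alpha,
              seed = as.integer(seed), prep = unclass(prep))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @param cfg A \code{"PipelineConfig"} (for writing).
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  for (k in intersect(names(raw), setdiff(names(cfg), "prep")))
    cfg[[k]] <- raw[[k]]
  if (!is.null(raw$prep))
    cfg$prep <- unclass(do.call(prepConstants, raw$prep))
  cfg$adduct <- match.arg(cfg$adduct, c("hydrogen-atom", "proton"))
  cfg
}
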