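# Independent brute-force oracles used by property tests. These deliberately
# re-derive everything from first principles (triple loops, exhaustive chain
# enumeration) rather than calling the implementation under test.

.oracleMasses <- c(C = 12.0, H = 1.00782503, O = 15.99491462)

oracleFormulaMass <- function(C, H, O) {
  C * .oracleMasses[["C"]] + H * .oracleMasses[["H"]] +
    O * .oracleMasses[["O"]]
}

# exhaustive triple-loop CHO enumeration
oracleEnumerate <- function(observed, tolPpm, bounds, add = 1.007825) {
  hits <- list()
  for (C in bounds$cMin:bounds$cMax)
    for (H in bounds$hMin:bounds$hMax)
      for (O in bounds$oMin:bounds$oMax) {
        if (bounds$evenElectron && H %% 2L != 0L) next
        r <- C - H / 2 + 1
        if (r < bounds$rdbeMin || r > bounds$rdbeMax) next
        th <- oracleFormulaMass(C, H, O) + add
        ppm <- (observed - th) / th * 1e6
        if (abs(ppm) <= tolPpm) {
          hill <- paste0(
            if (C > 0) paste0("C", if (C > 1) C),
            if (H > 0) paste0("H", if (H > 1) H),
            if (O > 0) paste0("O", if (O > 1) O))
          hits[[length(hits) + 1L]] <- data.frame(formula = hill,
                                                  ppm = ppm)
        }
      }
  if (!length(hits))
    return(data.frame(formula = character(0), ppm = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(abs(out$ppm), out$formula), , drop = FALSE]
}

# exhaustive loss-chain search: enumerate every multiset of vocabulary
# losses up to maxDepth and apply the documented tie-break
oracleLossChain <- function(precursor, fragment, vocab, tolPpm, tolMdaFloor,
                            maxDepth) {
  all <- list(list(idx = integer(0)))
  frontier <- all
  for (d in seq_len(maxDepth)) {
    nxt <- list()
    for (node in frontier) {
      from <- if (length(node$idx)) max(node$idx) else 1L
      for (i in from:nrow(vocab))
        nxt[[length(nxt) + 1L]] <- list(idx = c(node$idx, i))
    }
    all <- c(all, nxt)
    frontier <- nxt
  }
  target <- precursor - fragment
  tol <- max(tolPpm * 1e-6 * fragment, tolMdaFloor / 1000)
  best <- NULL
  for (node in all) {
    mass <- sum(vocab$mass[node$idx])
    if (abs(mass - target) > tol) next
    expMz <- precursor - mass
    ppm <- (fragment - expMz) / expMz * 1e6
    lab <- paste(vocab$label[node$idx], collapse = "+")
    cand <- list(depth = length(node$idx), ppm = ppm, lab = lab)
    if (is.null(best) ||
        cand$depth < best$depth ||
        (cand$depth == best$depth && abs(cand$ppm) < abs(best$ppm)) ||
        (cand$depth == best$depth && abs(cand$ppm) == abs(best$ppm) &&
           cand$lab < best$lab))
      best <- cand
  }
  best
}

# closed-form ordinary least squares via the normal equations
oracleOls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  a <- sxy / sxx
  c(slope = a, intercept = mean(y) - a * mean(x))
}

# canonical elemental composition of a neutral-loss chain: chains that are
# permutations or mass-degenerate regroupings of the same atoms (e.g.
# H2O + C4H8O versus C4H10O2) share one key
lossCompositionKey <- function(chain) {
  vocab <- lossVocabulary()
  labels <- strsplit(chain, "+", fixed = TRUE)[[1]]
  total <- c(C = 0L, H = 0L, O = 0L)
  for (lab in labels) {
    f <- parseFormula(vocab$formula[match(lab, vocab$label)])
    total[names(f@counts)] <- total[names(f@counts)] + f@counts
  }
  paste(names(total), total, sep = ":", collapse = ",")
}

# printed fragment m/z values whose loss arithmetic does not reproduce them
# (transcription-level anomalies in the source table; peak 17 is excluded
# wholesale because its printed precursor is itself inconsistent)
knownAnomalousFragments <- data.frame(
  peak = c(1L, 5L, 5L, 11L, 15L, 15L, 20L, 22L),
  fragment_mz = c(451.3416, 415.2650, 379.3427, 415.2652, 495.3598,
                  435.3592, 451.3321, 437.2426)
)
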