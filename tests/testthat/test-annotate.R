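test_that("single neutral losses are annotated from precursor-fragment gaps", {
  ann <- annotateLosses(529.3522, c(511.3424, 469.3313))
  expect_equal(ann$chain, c("H2O", "HAc"))
  expect_true(all(ann$annotated))

  # a fragment equal to the precursor carries the empty chain at 0 ppm
  self <- annotateLosses(500, 500)
  expect_identical(self$chain, "")
  expect_equal(self$depth, 0L)
  expect_equal(self$ppm, 0)
  expect_true(self$annotated)

  # an inexplicable gap stays unannotated
  none <- annotateLosses(500, 470)
  expect_false(none$annotated)
  expect_identical(none$chain, "")

  expect_error(annotateLosses(500, 490, losses = data.frame()), "empty")
  expect_error(annotateLosses(500, 510), "precursor")
})

test_that("mass-degenerate chains resolve to the shortest chain", {
  # H2O + C4H8O has exactly the mass of C4H10O2; depth 1 must win
  ann <- annotateLosses(505.3529, 505.3529 - monoisotopicMass("C4H10O2"))
  expect_identical(ann$chain, "C4H10O2")
  expect_identical(ann$depth, 1L)
})

test_that("loss-chain search equals the exhaustive oracle", {
  vocab <- lossVocabulary()[1:6, ]
  set.seed(7)
  for (k in seq_len(40)) {
    prec <- runif(1, 450, 560)
    frag <- prec - runif(1, 0, 200)
    got <- annotateLosses(prec, frag, losses = vocab, maxDepth = 3L)
    want <- oracleLossChain(prec, frag, vocab, tolPpm = 15,
                            tolMdaFloor = 3, maxDepth = 3L)
    if (is.null(want)) {
      expect_false(got$annotated)
    } else {
      expect_identical(got$chain, want$lab,
                       label = sprintf("instance %d", k))
      expect_equal(got$ppm, want$ppm, tolerance = 1e-9)
    }
  }
  # and on gaps built to be annotatable
  set.seed(8)
  for (k in seq_len(40)) {
    prec <- runif(1, 450, 560)
    idx <- sample(nrow(vocab), sample(3, 1), replace = TRUE)
    frag <- prec - sum(vocab$mass[idx]) + rnorm(1, 0, 0.001)
    got <- annotateLosses(prec, frag, losses = vocab, maxDepth = 3L)
    want <- oracleLossChain(prec, frag, vocab, tolPpm = 15,
                            tolMdaFloor = 3, maxDepth = 3L)
    expect_identical(got$chain, want$lab)
  }
})

test_that("library fragment lists annotate to their printed loss chains", {
  lib <- loadFixtures("library")
  for (i in seq_len(nrow(lib))) {
    if (lib$mass_anomaly[i]) next   # printed precursor inconsistent
    ann <- annotateLosses(lib$ms1_mz[i], lib$fragment_mz[[i]])
    for (j in seq_along(lib$fragment_mz[[i]])) {
      mzj <- lib$fragment_mz[[i]][j]
      anomalous <- any(knownAnomalousFragments$peak == lib$peak[i] &
                         abs(knownAnomalousFragments$fragment_mz - mzj) <
                           1e-6)
      if (anomalous) next   # transcription anomalies: recorded, not asserted
      expect_true(ann$annotated[j],
                  label = sprintf("peak %d fragment %.4f annotated",
                                  lib$peak[i], mzj))
      # compare total loss compositions: mass-degenerate regroupings of
      # the same atoms (H2O + C4H8O vs C4H10O2, ...) count as agreement
      expect_identical(lossCompositionKey(ann$chain[j]),
                       lossCompositionKey(lib$fragment_losses[[i]][j]),
                       label = sprintf("peak %d fragment %.4f chain",
                                       lib$peak[i], mzj))
    }
  }
})

test_that("UV classes bin lambda-max into the 287/245/none windows", {
  expect_identical(uvClass(287), "287")
  expect_identical(uvClass(291), "287")
  expect_identical(uvClass(245), "245")
  expect_identical(uvClass(241), "245")
  expect_identical(uvClass(NA), "none")
  expect_identical(uvClass(198), "none")
  expect_identical(uvClass(260), "none")
})

test_that("type rules reproduce representative assignments", {
  alisolL <- featureRecord(469.3315, 25.91, c(451.3216, 397.2745),
                           uvLambdaMax = 287)
  expect_identical(classifyType(alisolL), "I")

  alisolB23 <- featureRecord(515.3739, 49.06,
                             c(497.3631, 479.3519, 437.3431, 383.2983))
  expect_identical(classifyType(alisolB23), "III")

  empty <- featureRecord(515.3739, 49.06)
  expect_true(is.na(classifyType(empty)))
  expect_match(attr(classifyType(empty), "reason"), "no fragments")

  # characteristic ion present but UV class inconsistent -> unclassified
  odd <- featureRecord(469.3315, 25.91, 397.2745, uvLambdaMax = 260)
  expect_true(is.na(classifyType(odd)))
  expect_match(attr(classifyType(odd), "reason"), "UV class")
})

test_that("classification ignores fragment order and intensity scale", {
  mz <- c(497.3631, 479.3519, 437.3431, 383.2983)
  base <- classifyType(featureRecord(515.3739, 49.06, mz))
  shuffled <- classifyType(featureRecord(515.3739, 49.06, rev(mz),
                                         fragmentIntensity = rep(7, 4)))
  scaled <- classifyType(featureRecord(515.3739, 49.06, mz,
                                       fragmentIntensity = c(1, 2, 3, 4) *
                                         1e6))
  expect_identical(base, shuffled)
  expect_identical(base, scaled)
})

test_that("the packaged library classifies into the published seven-type grouping", {
  lib <- loadFixtures("library")
  feats <- referenceFeatures(lib)
  got <- vapply(feats, classifyType, character(1))
  expect_identical(got, lib$type)
  groups <- split(lib$peak, got)
  expect_identical(groups$I, c(6L, 14L, 20L))
  expect_identical(groups$II, c(1L, 2L, 3L, 5L, 11L))
  expect_identical(groups$III, c(16L, 17L, 18L, 21L, 22L, 23L))
  expect_identical(groups$IV, c(9L, 10L, 15L))
  expect_identical(groups$V, c(24L, 25L))
  expect_identical(groups$VI, c(4L, 8L, 12L, 19L))
  expect_identical(groups$VII, c(7L, 13L))
})

test_that("identification distinguishes standard matches, tentative hits and misses", {
  lib <- loadFixtures("library")

  # alisol L: retention time, formula and fragments all agree
  f14 <- featureRecord(469.3315, 25.91, c(451.3216, 397.2745),
                       uvLambdaMax = 287)
  r <- identifyFeature(f14, lib)
  expect_identical(r$mode, "standard-match")
  expect_identical(r$matched_name, "alisol L")

  # the new compound: no standard, but formula and type resolve
  f7 <- featureRecord(489.3562, 19.72, c(471.3471, 453.3367, 399.2896),
                      uvLambdaMax = 245)
  r <- identifyFeature(f7, lib)
  expect_identical(r$mode, "tentative")
  expect_identical(r$assigned_formula, "C30H48O5")
  expect_identical(r$assigned_type, "VII")

  # fragmentless feature far from everything
  bare <- featureRecord(641.1111, 70.0)
  expect_identical(identifyFeature(bare, lib)$mode, "unidentified")
})

test_that("annotateRun reports identification and type tallies over the fixture", {
  lib <- loadFixtures("library")
  rep <- annotateRun(referenceFeatures(lib), lib)
  expect_identical(rep$summary$n_features, 25L)
  expect_identical(rep$summary$n_identified, 25L)
  expect_identical(as.integer(rep$summary$type_tally),
                   c(3L, 5L, 6L, 3L, 2L, 4L, 2L))
  # every standard-confirmed entry's feature is identified; the one entry
  # with an inconsistent printed precursor resolves tentatively, the rest
  # as standard matches
  expect_identical(rep$summary$n_standard_match, 20L)
  anomalous <- sprintf("peak%02d", lib$peak[lib$mass_anomaly])
  modes <- setNames(rep$results$mode, rep$results$feature_id)
  expect_identical(unname(modes[anomalous]), rep("tentative",
                                                 length(anomalous)))

  empty <- annotateRun(list(), lib)
  expect_identical(empty$summary$n_features, 0L)
})
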