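test_that("calibration fitting recovers exact linear responses", {
  x <- c(0.008, 0.02, 0.04, 0.06, 0.08, 0.103)
  cur <- fitCalibration(x, 15.87 * x - 0.014, analyte = "a")
  expect_equal(cur@slope, 15.87, tolerance = 1e-10)
  expect_equal(cur@intercept, -0.014, tolerance = 1e-10)
  expect_equal(cur@r, 1)
  expect_equal(c(cur@rangeLow, cur@rangeHigh), range(x))

  expect_error(fitCalibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fitCalibration(c(1, 2, 3), c(5, 5, 5)), "degenerate")
})

test_that("noisy calibration fits agree with the normal-equations oracle", {
  set.seed(11)
  for (k in seq_len(10)) {
    x <- sort(runif(7, 0.01, 5))
    y <- 2.5 * x - 0.02 + rnorm(7, 0, 0.05)
    cur <- fitCalibration(x, y)
    want <- oracleOls(x, y)
    expect_equal(cur@slope, unname(want["slope"]), tolerance = 1e-10)
    expect_equal(cur@intercept, unname(want["intercept"]),
                 tolerance = 1e-10)
    expect_equal(cur@r, cor(x, y))
  }
})

test_that("calibration inversion flags the linear range", {
  cur <- calibrationCurve("x", 15.87, -0.014, 0.9999, 0.008, 0.103)
  inv <- invertCalibration(cur, 1.573)
  expect_equal(inv$concentration, 0.100, tolerance = 1e-4)

  expect_identical(invertCalibration(cur, -0.014)$flag, "below-range")

  b23 <- calibrationCurve("alisol B 23-acetate", 2.678, -0.023, 0.9993,
                          0.294, 9.790)
  inv <- invertCalibration(b23, 13.0)
  expect_equal(inv$concentration, 4.863, tolerance = 1e-3)
  expect_identical(inv$flag, "in-range")

  # fit-then-invert is the identity on noise-free data
  x <- c(0.05, 0.2, 0.5, 1, 2)
  cur <- fitCalibration(x, 3.1 * x - 0.02)
  expect_equal(invertCalibration(cur, 3.1 * x - 0.02)$concentration, x,
               tolerance = 1e-10)
})

test_that("mg/g conversion applies the preparation constants", {
  expect_equal(contentMgPerG(4.0), 1.0)
  expect_equal(contentMgPerG(0), 0)
  expect_equal(contentMgPerG(4.928), 1.232)
  # linear and homogeneous
  x <- c(0.3, 1.7, 8)
  expect_equal(contentMgPerG(2 * x), 2 * contentMgPerG(x))
  expect_equal(contentMgPerG(x[1] + x[2]),
               contentMgPerG(x[1]) + contentMgPerG(x[2]))
  # custom preparation
  p <- prepConstants(sample_mass = 0.5, extraction_volume = 10,
                     is_mix_dilution = 1)
  expect_equal(contentMgPerG(5, p), 5 * 10 / 500)
  expect_error(contentMgPerG(-1), "non-negative")
  expect_error(prepConstants(sample_mass = 0), "positive")
})

test_that("LOD/LOQ come from S/N crossings of the dilution series", {
  c0 <- 0.9
  series <- data.frame(concentration = c(c0, c0 / 3, c0 / 10, c0 / 30),
                       signal = c(30, 10, 3, 1), noise = 1)
  ll <- estimateLodLoq(series)
  expect_equal(unname(ll["lod"]), c0 / 10, tolerance = 1e-12)
  expect_equal(unname(ll["loq"]), c0 / 3, tolerance = 1e-12)
  expect_gt(ll["loq"], ll["lod"])

  # log-linear interpolation between non-exact brackets: S/N proportional
  # to concentration gives back the analytic crossing
  series2 <- data.frame(concentration = 2^seq(4, -8),
                        signal = 7 * 2^seq(4, -8), noise = 1)
  ll2 <- estimateLodLoq(series2)
  expect_equal(unname(ll2["lod"]), 3 / 7, tolerance = 1e-9)
  expect_equal(unname(ll2["loq"]), 10 / 7, tolerance = 1e-9)

  short <- data.frame(concentration = c(1, 0.5), signal = c(100, 50),
                      noise = 1)
  expect_error(estimateLodLoq(short), "bracket")
})

test_that("noise-free batch quantification inverts the forward model exactly", {
  curves <- loadFixtures("curves")
  truth <- loadFixtures("contents")
  # strip NDs so the inverse-pair property is exact everywhere
  m <- contentValues(truth)
  m[is.na(m)] <- 0.05
  truth <- ContentMatrix(m, origin = origins(truth))

  cfg <- simConfig(seed = 5, areaCv = 0, isAreaCv = 0)
  sim <- suppressWarnings(simulateMrmBatch(curves, truth, cfg))
  got <- quantifyBatch(sim$areas, curves, origin = sim$origin)
  expect_equal(contentValues(got)[, colnames(m)], m, tolerance = 1e-9)
  expect_identical(origins(got)[match(colnames(m),
                                      colnames(contentValues(got)))],
                   origins(truth))
})

test_that("contents below the LOD are reported as ND", {
  curves <- loadFixtures("curves")[1, ]
  lods <- setNames(curves$lod_ng_ml, curves$analyte)
  cur <- curvesFromTable(curves)[[1]]
  lowX <- lods[[1]] / 1000 / 2            # half the LOD, in ug/mL
  okX <- 0.05
  areas <- data.frame(
    sample_id = c("A", "B"), analyte = curves$analyte,
    area = (cur@slope * c(lowX, okX) + cur@intercept) * 1e5, is_area = 1e5)
  cm <- quantifyBatch(areas, curves, lods = lods)
  expect_true(is.na(contentValues(cm)[1, "A"]))
  expect_equal(contentValues(cm)[1, "B"], contentMgPerG(okX),
               tolerance = 1e-9)
})

test_that("quantification is invariant to measurement order and skips bad IS areas", {
  curves <- loadFixtures("curves")
  truth <- loadFixtures("contents")
  cfg <- simConfig(seed = 17)
  sim <- suppressWarnings(
    simulateMrmBatch(curves, truth, cfg,
                     lods = setNames(curves$lod_ng_ml, curves$analyte)))
  a <- quantifyBatch(sim$areas, curves)
  set.seed(1)
  shuffled <- sim$areas[sample(nrow(sim$areas)), ]
  b <- quantifyBatch(shuffled, curves)
  expect_equal(contentValues(a), contentValues(b))

  broken <- sim$areas
  broken$is_area[1] <- NA
  expect_warning(quantifyBatch(broken, curves), "skipped")
})
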