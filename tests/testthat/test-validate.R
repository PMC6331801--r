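test_that("rsd is the sample-sd over the mean in percent", {
  expect_equal(rsd(c(5, 5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_error(rsd(7), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
  # scale invariance
  set.seed(3)
  x <- rnorm(20, 10, 1)
  for (c in c(0.01, 3, 1e4))
    expect_equal(rsd(c * x), rsd(x))
})

test_that("recovery follows the spiked-known definition", {
  expect_equal(recovery(2.0, 1.0, 1.0), 100)
  expect_equal(recovery(1.981, 1.0, 1.0), 98.1)
  expect_equal(recovery(0.7, 0.7, 5), 0)
  expect_error(recovery(1, 1, 0), "positive")
  # perfect detection recovers 100% for any positive spike
  set.seed(4)
  for (k in 1:10) {
    orig <- runif(1, 0.1, 2); add <- runif(1, 0.1, 2)
    expect_equal(recovery(orig + add, orig, add), 100)
  }
})

test_that("validation report has the full per-analyte column structure", {
  truth <- setNames(c(0.011, 1.086, 1.465), c("a", "b", "c"))
  arms <- simulateValidationArms(truth, simConfig(seed = 2), cv = 0.02)
  rep <- validationReport(arms)
  expect_identical(rep$analyte, names(truth))
  expect_identical(names(rep),
                   c("analyte", "intra_day_rsd", "inter_day_rsd",
                     "repeatability_rsd", "repeatability_mean",
                     "stability_rsd", "recovery_mean", "recovery_sd",
                     "recovery_rsd"))
  # noise-free arms: all dispersion zero, recoveries exactly 100%
  clean <- simulateValidationArms(truth, simConfig(seed = 2), cv = 0)
  repc <- validationReport(clean)
  expect_equal(repc$intra_day_rsd, rep(0, 3))
  expect_equal(repc$stability_rsd, rep(0, 3))
  expect_equal(repc$recovery_mean, rep(100, 3))
  expect_equal(repc$repeatability_mean, unname(truth))

  short <- arms
  short$stability$b <- 1
  expect_error(validationReport(short), "stability.*'b'")
})

test_that("simulated validation RSDs sit in the expected band at 2% CV", {
  truth <- setNames(rep(0.5, 14), paste0("an", 1:14))
  rsds <- unlist(lapply(1:20, function(s) {
    rep <- validationReport(simulateValidationArms(
      truth, simConfig(seed = 100 + s), cv = 0.02))
    c(rep$intra_day_rsd, rep$repeatability_rsd, rep$stability_rsd)
  }))
  expect_true(all(rsds > 0.2 & rsds < 6))
  expect_equal(mean(rsds), 2, tolerance = 0.15)
})

test_that("batch summaries exclude ND cells and find the dominant analyte", {
  cm <- loadFixtures("contents")
  s <- batchSummary(cm)
  b <- s[s$analyte == "alisol B", ]
  expect_equal(c(b$min, b$max), c(0.104, 1.232))
  b23 <- s[s$analyte == "alisol B 23-acetate", ]
  expect_equal(c(b23$min, b23$max), c(1.131, 2.032))
  f24 <- s[s$analyte == "alisol F 24-acetate", ]
  expect_identical(f24$n_nd, sum(is.na(contentValues(cm)["alisol F 24-acetate", ])))
  expect_gt(f24$n_nd, 0)

  expect_identical(unname(dominantAnalyte(cm)),
                   rep("alisol B 23-acetate", 43))

  one <- ContentMatrix(matrix(0.4, 1, 1, dimnames = list("a", "s")), "X")
  s1 <- batchSummary(one)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, 0.4)
})

test_that("origin comparison computes Student's t per analyte", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1,
              dimnames = list("a", paste0("s", 1:6)))
  cm <- ContentMatrix(m, origin = rep(c("F", "S"), each = 3))
  res <- compareOrigins(cm, "F", "S")
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_true(res$flag)
  expect_identical(res$direction, "higher-in-b")

  ident <- ContentMatrix(matrix(c(1, 2, 3, 1, 2, 3), 1,
                                dimnames = list("a", paste0("s", 1:6))),
                         origin = rep(c("F", "S"), each = 3))
  res0 <- compareOrigins(ident, "F", "S")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_false(res0$flag)

  # analytes without two non-ND values per group are skipped, not guessed
  m2 <- rbind(m, sparse = c(1, NA, NA, 2, 2.4, NA))
  rownames(m2) <- c("a", "sparse")
  cm2 <- ContentMatrix(m2, origin = rep(c("F", "S"), each = 3))
  res2 <- compareOrigins(cm2, "F", "S")
  expect_identical(attr(res2, "skipped"), "sparse")
  expect_identical(res2$analyte, "a")
})

test_that("the batch fixture reproduces the published origin differences", {
  cm <- loadFixtures("contents")
  res <- compareOrigins(cm, "Fujian", "Sichuan")
  higher <- c("16-oxo-alisol A 23-acetate", "16-oxo-alisol A 24-acetate",
              "alisol C", "alisol F", "alisol A", "alisol A 23-acetate",
              "alisol A 24-acetate", "alisol G", "alisol B")
  for (an in higher) {
    row <- res[res$analyte == an, ]
    expect_true(row$flag, label = paste(an, "flagged"))
    expect_identical(row$direction, "higher-in-b")
  }
  low <- res[res$analyte == "11-deoxy-alisol B", ]
  expect_true(low$flag)
  expect_identical(low$direction, "lower-in-b")
  # the remaining four analytes show no significant difference
  rest <- setdiff(res$analyte, c(higher, "11-deoxy-alisol B"))
  expect_identical(sort(rest),
                   sort(c("alisol C 23-acetate", "alisol L",
                          "alisol F 24-acetate", "alisol B 23-acetate")))
  expect_false(any(res$flag[res$analyte %in% rest]))
})
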