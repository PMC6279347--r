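test_that("label-shuffled strong-signal data decode at chance", {
  ds <- strongSignalDataset("exp1", nVoxels = 15, noiseSd = 0.3, seed = 5)
  ti <- trialInfo(ds)
  set.seed(99)
  accs <- vapply(1:8, function(i) {
    shuffled <- ds
    shuffled@trialInfo$category <- sample(ti$category)
    loroWithin(shuffled, "current", tr = 5)
  }, numeric(1))
  # chance = 33.33% within Monte-Carlo tolerance
  expect_lt(abs(mean(accs) - 1 / 3), 3 * sd(accs) / sqrt(length(accs)) + 0.02)
})

test_that("noiseless upright data decode perfectly", {
  ds <- strongSignalDataset("exp1", nVoxels = 12, noiseSd = 0.001, seed = 2)
  expect_equal(loroWithin(ds, "current", 5), 1.0)
  ds2 <- strongSignalDataset("exp2", nVoxels = 12, noiseSd = 0.001, seed = 2)
  expect_equal(balancedLoro(ds2, "prospective", 5), 1.0)
})

test_that("leave-one-run-out matches fold-by-fold manual enumeration", {
  ds <- microDataset()
  acc <- loroWithin(ds, "current", 1)
  # oracle: enumerate both folds with the same fitted models
  ti <- trialInfo(ds)
  p <- patterns(ds)[, 1, ]
  manual <- vapply(1:2, function(r) {
    tr_i <- ti$run != r
    fit <- fitOvrLogistic(p[tr_i, ], ti$category[tr_i])
    mean(predict(fit, p[!tr_i, ]) == ti$category[!tr_i])
  }, numeric(1))
  expect_equal(acc, mean(manual))
  # every test trial scored exactly once: folds are disjoint and exhaustive
  expect_equal(sort(unique(ti$run)), 1:2)
})

test_that("balanced CV has the canonical 99-fit structure", {
  ds <- noiseDataset("exp2", nVoxels = 8, seed = 21)
  res <- balancedLoro(ds, "current", 1, details = TRUE)
  fits <- attr(res, "fits")
  expect_equal(nrow(fits), 99L)                 # 9 folds x 11 repetitions
  expect_true(all(fits$n_train == 30L))         # 30 training trials
  expect_true(all(fits[, c("X1", "X2", "X3")] == 10L))  # 10 per category
  expect_equal(max(fits$repetition), 11L)
  # pre-exclusion fold sizes are 32 per condition with counts (10,11,11)
  ti <- trialInfo(ds)
  for (r in 1:9) {
    y <- ti$category[ti$condition == "current" & ti$run != r]
    expect_equal(length(y), 32L)
    expect_equal(sort(as.integer(table(y))), c(10L, 11L, 11L))
  }
})

test_that("balanced CV rejects designs without the (n,n+1,n+1) structure", {
  ds <- microDataset()   # 2 runs x 3 balanced categories
  expect_error(balancedLoro(ds, "current", 1), "not a permutation")
})

test_that("balanced accuracy equals plain accuracy for equinumerous classes", {
  set.seed(8)
  pred <- sample(1:3, 30, replace = TRUE)
  truth <- rep(1:3, 10)
  plain <- mean(pred == truth)
  ba <- mean(vapply(1:3, function(k) mean(pred[truth == k] == k), numeric(1)))
  expect_equal(ba, plain)
})

test_that("cross-relevance decoding reports both directions and the average", {
  ds <- strongSignalDataset("exp1", nVoxels = 10, noiseSd = 0.5, seed = 3)
  cr <- crossRelevance(ds, "current", "prospective", 5)
  expect_named(cr, c("ab", "ba", "average"))
  expect_equal(cr$average, (cr$ab + cr$ba) / 2)
  expect_error(crossRelevance(ds, "current", "current", 5), "within scheme")
  expect_error(crossRelevance(ds, "current", "missing", 5), "absent")
})

test_that("timecourses have the design length and flat inputs give flat output", {
  design <- generateDesign("exp2", seed = 3)
  pat <- patterns(simulateTPatterns(design,
    simParams("exp2", nVoxels = 6, seed = 5,
              schedules = flatSchedules("exp2", a = 1))))
  constantPat <- pat
  for (t in 2:16) constantPat[, t, ] <- constantPat[, 1, ]  # TR-constant
  ds <- methods::new("PatternDataset", patterns = constantPat,
                     trialInfo = design, subjectId = "flat",
                     chanceLevel = 1 / 3, provenance = list())
  tc <- decodeTimecourse(ds, decodingScheme("current"), trs = c(1, 7, 16))
  acc <- accuracy(tc)
  expect_equal(length(acc), 16L)
  expect_equal(acc[1], acc[7])
  expect_equal(acc[1], acc[16])
  expect_true(all(is.na(acc[c(2:6, 8:15)])))
})

test_that("interval averaging is an arithmetic mean with strict bounds", {
  tc <- c(rep(0.5, 4), 0.2, 0.4, 0.6, rep(0.9, 9))
  iv <- intervalAverage(tc, list(delay = 5:7, search1 = 9:11, single = 2L))
  expect_equal(unname(iv["delay"]), mean(c(0.2, 0.4, 0.6)))
  expect_equal(unname(iv["search1"]), 0.9)
  expect_equal(unname(iv["single"]), 0.5)
  expect_equal(length(intervalAverage(rep(0.4, 16),
                                      defaultIntervals("exp2"))), 3L)
  expect_error(intervalAverage(tc, list(bad = integer(0))), "empty")
  expect_error(intervalAverage(tc, list(bad = 90L)), "out of range")
})

test_that("within accuracy is non-decreasing in generator amplitude", {
  amps <- c(0, 0.7, 2.5)
  grid <- vapply(amps, function(a) {
    mean(vapply(1:3, function(seed) {
      design <- generateDesign("exp1", seed = seed)
      ds <- simulateTPatterns(design,
        simParams("exp1", nVoxels = 20, noiseSd = 1, ar1 = 0,
                  schedules = flatSchedules("exp1", a = a), seed = seed))
      loroWithin(ds, "current", 5)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(grid) >= -0.02))
  expect_gt(grid[3], grid[1] + 0.2)
})
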