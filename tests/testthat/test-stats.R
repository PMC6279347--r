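test_that("paired t matches the textbook formula and handles edge cases", {
  # toy vector (1,2,3) vs 0: t = mean/ (sd/sqrt(n)) = 2/(1/sqrt(3))
  res <- pairedT(c(1, 2, 3), 0)
  expect_equal(res$t, 2 / (1 / sqrt(3)))
  expect_equal(res$df, 2L)
  expect_equal(res$d, 2 / 1)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), 2))
  # agreement with the reference implementation
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  ref <- t.test(x, y, paired = TRUE)
  mine <- pairedT(x, y)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
  one <- pairedT(x, y, tail = "greater")
  expect_equal(one$p, t.test(x, y, paired = TRUE,
                             alternative = "greater")$p.value)
  # x = y degenerates
  expect_error(pairedT(c(1, 2), c(1, 2)), "zero-variance")
  expect_error(pairedT(1, 1), "n >= 2")
  expect_error(pairedT(1:3, 1:2), "lengths")
})

test_that("paired t is antisymmetric in its arguments", {
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  a <- pairedT(x, y); b <- pairedT(y, x)
  expect_equal(a$t, -b$t)
  expect_equal(a$d, -b$d)
  expect_equal(a$p, b$p)
})

test_that("RM-ANOVA matches hand-decomposed sums of squares and aov", {
  data <- rbind(c(4, 6, 7), c(3, 5, 6), c(5, 6, 9), c(2, 4, 5))
  res <- rmAnovaOneway(data, correction = "none")
  # oracle: brute-force SS decomposition
  grand <- mean(data)
  ssC <- 4 * sum((colMeans(data) - grand)^2)
  ssS <- 3 * sum((rowMeans(data) - grand)^2)
  ssE <- sum((data - grand)^2) - ssC - ssS
  expect_equal(res$F, (ssC / 2) / (ssE / 6))
  expect_equal(res$etaP2, ssC / (ssC + ssE))
  # independent route: base aov with an Error stratum
  long <- data.frame(y = as.numeric(data),
                     subj = factor(rep(1:4, 3)),
                     cond = factor(rep(1:3, each = 4)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = long))
  tab <- fit[["Error: subj:cond"]][[1]]
  expect_equal(res$F, tab["cond", "F value"])
  expect_equal(res$p, tab["cond", "Pr(>F)"])
})

test_that("RM-ANOVA reproduces an independent reference implementation", {
  # frozen oracle values computed with pingouin's rm_anova on this table
  data <- rbind(c(0.40, 0.55, 0.62), c(0.35, 0.45, 0.50),
                c(0.52, 0.61, 0.58), c(0.30, 0.40, 0.55),
                c(0.44, 0.52, 0.49), c(0.38, 0.50, 0.66))
  unc <- rmAnovaOneway(data, correction = "none")
  expect_equal(unc$F, 15.269006, tolerance = 1e-6)
  expect_equal(unc$p, 0.000913, tolerance = 1e-3)
  expect_equal(unc$etaP2, 0.753318, tolerance = 1e-6)
  gg <- rmAnovaOneway(data, correction = "GG")
  expect_equal(gg$ggEpsilon, 0.535937, tolerance = 1e-6)
  expect_equal(gg$p, 0.009412, tolerance = 1e-4)
  expect_equal(gg$dfNum, 2 * 0.535937, tolerance = 1e-5)
})

test_that("two-condition RM-ANOVA equals the squared paired t", {
  set.seed(9)
  data <- cbind(rnorm(8, 1), rnorm(8, 1.4))
  res <- rmAnovaOneway(data, correction = "none")
  tt <- pairedT(data[, 2], data[, 1])
  expect_equal(res$F, tt$t^2)
  expect_equal(res$p, 2 * pt(-abs(tt$t), 7))
})

test_that("RM-ANOVA degrees of freedom and degenerate inputs", {
  set.seed(4)
  data <- matrix(rnorm(25 * 3, 0.4, 0.05), 25, 3)
  res <- rmAnovaOneway(data, correction = "none")
  expect_equal(res$dfNum, 2)
  expect_equal(res$dfDen, 48)
  # identical columns -> F = 0
  same <- matrix(rep(rnorm(6), 3), 6, 3)
  expect_equal(rmAnovaOneway(same, correction = "none")$F, 0)
  data[2, 3] <- NA
  expect_error(rmAnovaOneway(data), "missing")
})

test_that("within-subject SEM removes additive subject offsets", {
  base <- c(0.4, 0.5, 0.6)
  offsets <- c(-1, 0, 2, 5)
  data <- outer(offsets, rep(1, 3)) + matrix(base, 4, 3, byrow = TRUE)
  sem <- withinSubjectSem(data)
  expect_true(all(abs(sem) < 1e-12))
  # 3x3 toy against the step-by-step normalization oracle
  set.seed(6)
  d3 <- matrix(rnorm(9), 3, 3)
  norm <- d3 - rowMeans(d3) + mean(d3)
  oracle <- apply(norm, 2, sd) / sqrt(3) * sqrt(3 / 2)
  expect_equal(unname(withinSubjectSem(d3)), oracle)
  expect_warning(s1 <- withinSubjectSem(d3[, 1, drop = FALSE]), "classical")
  expect_equal(unname(s1), sd(d3[, 1]) / sqrt(3))
})

test_that("per-TR uncorrected masks behave under null and strong signal", {
  set.seed(10)
  null <- matrix(rnorm(40 * 150, 1 / 3, 0.05), 40, 150)
  m <- perTrUncorrected(null, 1 / 3, tail = "two.sided")
  expect_equal(nrow(m), 150L)
  expect_lt(abs(mean(m$significant) - 0.05), 0.04)
  strong <- matrix(rnorm(40 * 5, 0.8, 0.05), 40, 5)
  expect_true(all(perTrUncorrected(strong, 1 / 3)$significant))
})

test_that("ROI mean timecourse recovers an injected amplitude profile", {
  design <- generateDesign("exp2", seed = 2)
  ramp <- seq(0, 1.5, length.out = 16)
  datasets <- lapply(1:3, function(i) {
    set.seed(i)
    pat <- array(rnorm(108 * 16 * 30, sd = 0.5), c(108, 16, 30)) +
      rep(ramp, each = 108)                  # uniform TR-wise drive
    methods::new("PatternDataset", patterns = pat, trialInfo = design,
                 subjectId = paste0("s", i), chanceLevel = 1 / 3,
                 provenance = list())
  })
  tc <- roiMeanTimecourse(datasets)
  expect_equal(nrow(tc), 16L)
  expect_equal(tc$mean, ramp, tolerance = 0.05)
  expect_true(all(tc$sem >= 0))
  zero <- roiMeanTimecourse(noiseDataset("exp2", nVoxels = 40, seed = 3))
  expect_lt(max(abs(zero$mean)), 0.05)
  expect_true(all(is.na(zero$sem)))
})
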