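test_that("each trial carries one regressor per TR (16 for the 9-run design)", {
  d <- generateDesign("exp2", seed = 1)[1:12, ]  # one run is enough
  d$trial_id <- seq_len(nrow(d))
  ds <- simulateBoldGlm(d, simParams("exp2", nVoxels = 5, seed = 1))
  expect_equal(ds@provenance$nRegressors, 16L)
  expect_equal(dim(patterns(ds))[2], 16L)
  d1 <- generateDesign("exp1", seed = 1)[1:12, ]
  d1$trial_id <- seq_len(nrow(d1))
  ds1 <- simulateBoldGlm(d1, simParams("exp1", nVoxels = 5, seed = 1))
  expect_equal(ds1@provenance$nRegressors, 15L)
})

test_that("GLM betas recover the injected neural amplitudes at low noise", {
  design <- generateDesign("exp1", seed = 3)[1:6, ]
  design$trial_id <- 1:6
  params <- simParams("exp1", nVoxels = 6, noiseSd = 0.01, ar1 = 0,
                      seed = 21)
  ds <- simulateBoldGlm(design, params, restTrs = 8L)
  # oracle: direct least-squares against the known generating design matrix
  X <- mvdecode:::.trialDesignMatrix(15L, 23L, 2, params$hrf)
  bank <- makeCategoryPatterns(6, exemplarJitterSd = params$exemplarJitterSd,
                               seed = params$bankSeed)
  proto <- attr(bank, "prototypes")
  set.seed(params$seed)
  for (i in 1:6) {
    cond <- as.character(design$condition[i])
    a <- params$schedules$a[cond, 1:15]
    s <- params$schedules$s[cond, 1:15]
    b <- params$schedules$b[cond, 1:15]
    N <- outer(a * s, bank[design$category[i], design$exemplar[i], ]) +
      outer(b, proto[design$category[i], ])
    Y <- X %*% N + matrix(rnorm(23 * 6, sd = 0.01), 23, 6)
    betaOracle <- qr.coef(qr(cbind(1, X)), Y)[-1, ]
    # leverage of the FIR regressors bounds the estimation error
    lev <- sqrt(max(diag(chol2inv(chol(crossprod(cbind(1, X)))))))
    expect_lt(max(abs(betaOracle - N)), 6 * 0.01 * lev)
  }
  # the packaged t-patterns track the injected amplitudes tightly
  tp <- patterns(ds)
  for (i in 1:6) {
    cond <- as.character(design$condition[i])
    a <- params$schedules$a[cond, 1:15]
    s <- params$schedules$s[cond, 1:15]
    b <- params$schedules$b[cond, 1:15]
    N <- outer(a * s, bank[design$category[i], design$exemplar[i], ]) +
      outer(b, proto[design$category[i], ])
    keep <- abs(N) > 1e-8
    expect_gt(cor(as.numeric(tp[i, , ][keep]), as.numeric(N[keep])), 0.9)
  }
})

test_that("all-zero neural schedules yield t-values distributed around 0", {
  design <- generateDesign("exp2", seed = 5)[1:24, ]
  design$trial_id <- seq_len(nrow(design))
  params <- simParams("exp2", nVoxels = 8,
                      schedules = flatSchedules("exp2", a = 0), seed = 2)
  ds <- simulateBoldGlm(design, params)
  tv <- as.numeric(patterns(ds))
  expect_lt(abs(mean(tv)), 3 * sd(tv) / sqrt(length(tv)))
})

test_that("degenerate GLM inputs are rejected", {
  design <- generateDesign("exp2", seed = 1)[1:12, ]
  design$trial_id <- 1:12
  expect_error(
    simulateBoldGlm(design, simParams("exp2", nVoxels = 4, noiseSd = 0,
                                      seed = 1)),
    "noiseSd must be > 0")
  expect_error(
    simulateBoldGlm(design, simParams("exp2", nVoxels = 4, seed = 1),
                    restTrs = 0L),
    "degrees of freedom")
})

test_that("direct and haemodynamic paths agree at low noise on signal TRs", {
  design <- generateDesign("exp1", seed = 6)
  params <- simParams("exp1", nVoxels = 12, noiseSd = 0.01, ar1 = 0,
                      seed = 8)
  dsT <- simulateTPatterns(design, params)
  dsG <- simulateBoldGlm(design, params, restTrs = 10L)
  signalTrs <- which(colSums(params$schedules$a + params$schedules$b) > 0)
  for (t in signalTrs) {
    r <- cor(as.numeric(patterns(dsT)[, t, ]),
             as.numeric(patterns(dsG)[, t, ]))
    expect_gt(r, 0.9)
  }
})

test_that("double-gamma HRF peaks near the peak delay and undershoots", {
  t <- seq(0, 32, by = 0.1)
  h <- doubleGammaHrf(t)
  expect_equal(max(h), 1)
  expect_equal(t[which.max(h)], 5, tolerance = 1.2)  # mode of gamma(6,1)
  expect_lt(min(h), 0)                               # undershoot present
  expect_equal(doubleGammaHrf(-1), 0)
  expect_error(doubleGammaHrf(t, peak = -1), "invalid")
})
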