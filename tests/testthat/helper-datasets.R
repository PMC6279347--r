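# Shared fixture builders. Everything is generated in code at test time.

# schedules with a single constant amplitude/inversion everywhere
flatSchedules <- function(experiment, a = 1, s = 1, b = 0) {
  sch <- defaultSchedules(experiment)
  sch$a[] <- a
  sch$s[] <- s
  sch$b[] <- b
  sch
}

# high-SNR dataset: constant upright signal, tiny noise
strongSignalDataset <- function(experiment = "exp1", nVoxels = 12,
                                noiseSd = 0.01, seed = 1, a = 2, s = 1) {
  design <- generateDesign(experiment, seed = seed)
  params <- simParams(experiment, nVoxels = nVoxels, noiseSd = noiseSd,
                      ar1 = 0, schedules = flatSchedules(experiment, a, s),
                      seed = seed)
  simulateTPatterns(design, params)
}

# pure-noise dataset (no category signal anywhere)
noiseDataset <- function(experiment = "exp2", nVoxels = 20, seed = 1,
                         noiseSd = 1) {
  design <- generateDesign(experiment, seed = seed)
  params <- simParams(experiment, nVoxels = nVoxels, noiseSd = noiseSd,
                      schedules = flatSchedules(experiment, a = 0),
                      seed = seed)
  simulateTPatterns(design, params)
}

# dataset with upright delay code and inverted prospective search code,
# mirroring the package's default schedules at configurable SNR
invertedDataset <- function(experiment = "exp1", nVoxels = 40, seed = 1,
                            noiseSd = 1) {
  design <- generateDesign(experiment, seed = seed)
  params <- simParams(experiment, nVoxels = nVoxels, noiseSd = noiseSd,
                      seed = seed)
  simulateTPatterns(design, params)
}

# tiny hand-checkable dataset: 2 runs x 6 trials (3 categories x 2 runs),
# one trial per category per run per condition not needed -- single condition
microDataset <- function(nVoxels = 4, noiseSd = 0.3, seed = 7) {
  design <- data.frame(
    trial_id = 1:6, run = rep(1:2, each = 3), condition = "current",
    category = rep(1:3, 2), exemplar = 1L, target_present = TRUE,
    n_trs = 2L)
  set.seed(seed)
  proto <- matrix(rnorm(3 * nVoxels), 3)
  pat <- array(0, c(6, 2, nVoxels))
  for (i in 1:6)
    pat[i, , ] <- matrix(rep(proto[design$category[i], ], each = 2), 2) +
      rnorm(2 * nVoxels, sd = noiseSd)
  methods::new("PatternDataset", patterns = pat, trialInfo = design,
               subjectId = "micro", chanceLevel = 1 / 3,
               provenance = list(generator = "helper"))
}

# independent penalized-logistic oracle: BFGS on the identical objective
oracleLogistic <- function(X, y, lambda = 1e-4) {
  Xd <- cbind(1, X)
  p <- ncol(X)
  pen <- c(0, rep(lambda, p))
  classes <- sort(unique(y))
  W <- sapply(classes, function(k) {
    z <- as.numeric(y == k)
    f <- function(w) {
      eta <- drop(Xd %*% w)
      sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - z * eta) +
        sum(pen * w^2) / 2
    }
    gr <- function(w) {
      eta <- drop(Xd %*% w)
      mu <- 1 / (1 + exp(-eta))
      -drop(crossprod(Xd, z - mu)) + pen * w
    }
    optim(numeric(p + 1), f, gr, method = "BFGS",
          control = list(maxit = 2000, reltol = 1e-14))$par
  })
  W
}

# independent oracle: max cluster mass by brute-force neighbour merging
oracleMaxMass <- function(tmat, thr) {
  supra <- which(tmat > thr, arr.ind = TRUE)
  if (nrow(supra) == 0) return(0)
  labs <- seq_len(nrow(supra))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(supra))) for (j in seq_len(nrow(supra))) {
      if (sum(abs(supra[i, ] - supra[j, ])) == 1 && labs[i] != labs[j]) {
        labs[labs == max(labs[i], labs[j])] <- min(labs[i], labs[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  max(vapply(unique(labs), function(l)
    sum(tmat[supra[labs == l, , drop = FALSE]]), numeric(1)))
}

# brute-force Spearman: average ranks then the Pearson formula
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
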