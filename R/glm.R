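#' Double-gamma haemodynamic response function
#'
#' Canonical difference-of-gammas impulse response: a peak gamma minus a
#' scaled undershoot gamma, normalized to unit peak amplitude.
#'
#' @param t time in seconds (vector).
#' @param peak peak delay in seconds (gamma shape with unit rate).
#' @param undershoot undershoot delay in seconds.
#' @param ratio undershoot-to-peak amplitude ratio.
#' @return numeric vector of HRF values at `t`.
#' @export
doubleGammaHrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  if (peak <= 0 || undershoot <= 0 || ratio < 0)
    stop("invalid HRF parameters")
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  m <- max(h)
  if (m > 0) h <- h / m
  h
}

## Finite-impulse-response design matrix for one trial: one boxcar regressor
## per TR (duration = TR seconds), convolved with the HRF and sampled on the
## acquisition grid of nScan TRs. Built at fine resolution dt then sampled.
.trialDesignMatrix <- function(nTrs, nScan, tr = 2, hrfPar, dt = 0.1) {
  tFine <- seq(0, nScan * tr, by = dt)
  hrf <- doubleGammaHrf(tFine, hrfPar[["peak"]], hrfPar[["undershoot"]],
                        hrfPar[["ratio"]])
  X <- matrix(0, nScan, nTrs)
  sampleIdx <- round((seq_len(nScan) - 1L) * tr / dt) + 1L
  for (r in seq_len(nTrs)) {
    box <- as.numeric(tFine >= (r - 1L) * tr & tFine < r * tr)
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tFine)] * dt
    X[, r] <- conv[sampleIdx]
  }
  X
}

#' Simulate BOLD time series and recover per-TR t-patterns with a GLM
#'
#' The haemodynamic counterpart of [simulateTPatterns()]: the per-TR neural
#' amplitude of every voxel (the same
#' `a * s * P(category, exemplar) + b * P(category)` schedule) is convolved
#' with a double-gamma HRF, Gaussian noise is added, and a per-trial
#' ordinary-least-squares GLM with one boxcar regressor per TR (plus
#' intercept) is fitted to the trial's acquisition window. The returned
#' pattern for (trial, TR, voxel) is t = beta / SE(beta). Experiment-2
#' trials yield 16 per-TR regressors, Experiment-1 trials 15; the
#' acquisition window extends `restTrs` TRs past the trial (the fixed
#' inter-trial interval) so the model has residual degrees of freedom.
#'
#' @param design trial design from [generateDesign()].
#' @param params parameters from [simParams()]; `noiseSd` must be > 0,
#'   otherwise t = beta/SE is undefined.
#' @param subjectId identifier stored in the dataset.
#' @param tr repetition time in seconds.
#' @param restTrs post-trial rest TRs included in each trial's GLM window.
#' @return a [PatternDataset-class] of t-values; the number of per-TR
#'   regressors is recorded in `provenance`.
#' @export
simulateBoldGlm <- function(design, params, subjectId = "sim01", tr = 2,
                            restTrs = 6L) {
  stopifnot(inherits(params, "SimulationParams"))
  if (params$noiseSd <= 0)
    stop("noiseSd must be > 0 for the GLM path (t = beta/SE undefined)")
  nTrial <- nrow(design)
  if (nTrial == 0L) stop("design has no trials")
  nTrs <- design$n_trs[1L]
  nScan <- nTrs + as.integer(restTrs)
  nVox <- params$nVoxels
  if (nScan <= nTrs + 1L)
    stop("acquisition window too short: no residual degrees of freedom")

  bank <- makeCategoryPatterns(nVox, nCategories = max(design$category, 3L),
                               nExemplars = max(design$exemplar, 4L),
                               exemplarJitterSd = params$exemplarJitterSd,
                               seed = params$bankSeed)
  proto <- attr(bank, "prototypes")
  X <- .trialDesignMatrix(nTrs, nScan, tr, params$hrf)
  Xd <- cbind(1, X)                       # intercept + one regressor per TR
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) stop("rank-deficient trial design matrix")
  df <- nScan - ncol(Xd)
  XtXinv <- chol2inv(qr.R(qrX))
  cdiag <- diag(XtXinv)[-1L]              # leverage factors of TR regressors

  set.seed(params$seed)
  tpat <- array(NA_real_, c(nTrial, nTrs, nVox))
  for (i in seq_len(nTrial)) {
    cond <- as.character(design$condition[i])
    a <- .scheduleRow(params$schedules, cond, nTrs, "a")
    s <- .scheduleRow(params$schedules, cond, nTrs, "s")
    b <- .scheduleRow(params$schedules, cond, nTrs, "b")
    # neural amplitude per TR per voxel
    N <- outer(a * s, bank[design$category[i], design$exemplar[i], ]) +
      outer(b, proto[design$category[i], ])
    Y <- X %*% N + matrix(stats::rnorm(nScan * nVox, sd = params$noiseSd),
                          nScan, nVox)
    beta <- qr.coef(qrX, Y)
    resid <- Y - Xd %*% beta
    sigma2 <- colSums(resid^2) / df
    if (any(sigma2 <= 0)) stop("zero residual variance: t undefined")
    se <- sqrt(outer(cdiag, sigma2))
    tpat[i, , ] <- beta[-1L, , drop = FALSE] / se
  }
  methods::new("PatternDataset", patterns = tpat, trialInfo = design,
               subjectId = subjectId,
               chanceLevel = 1 / length(unique(design$category)),
               provenance = list(generator = "simulateBoldGlm",
                                 seed = params$seed,
                                 bankSeed = params$bankSeed,
                                 nVoxels = nVox, noiseSd = params$noiseSd,
                                 nRegressors = nTrs, restTrs = restTrs,
                                 tr = tr, df = df))
}
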