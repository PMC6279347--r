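#' Generate a bank of category/exemplar voxel patterns
#'
#' Draws one unit-norm prototype pattern per category and derives exemplar
#' patterns as prototype + jitter, where the jitter vector has expected
#' Euclidean norm `exemplarJitterSd` (element-wise sd
#' `exemplarJitterSd / sqrt(nVoxels)`). With independent Gaussian prototypes
#' the expected between-category pattern correlation is 0, while
#' within-category exemplars correlate at roughly
#' `1 / (1 + exemplarJitterSd^2)`.
#'
#' @param nVoxels number of voxels (>= 1).
#' @param nCategories number of categories.
#' @param nExemplars exemplars per category.
#' @param exemplarJitterSd non-negative jitter magnitude (0 makes all
#'   exemplars of a category identical).
#' @param seed integer seed.
#' @return array `[category x exemplar x voxel]` with the unit-norm category
#'   prototypes attached as `attr(, "prototypes")` (`category x voxel`).
#' @export
makeCategoryPatterns <- function(nVoxels, nCategories = 3L, nExemplars = 4L,
                                 exemplarJitterSd = 0.3, seed = 1L) {
  if (nVoxels < 1L) stop("nVoxels must be >= 1")
  if (exemplarJitterSd < 0) stop("exemplarJitterSd must be >= 0")
  set.seed(as.integer(seed))
  proto <- matrix(stats::rnorm(nCategories * nVoxels), nCategories, nVoxels)
  proto <- proto / sqrt(rowSums(proto^2))
  bank <- array(NA_real_, c(nCategories, nExemplars, nVoxels))
  for (k in seq_len(nCategories)) {
    for (e in seq_len(nExemplars)) {
      bank[k, e, ] <- proto[k, ] +
        exemplarJitterSd * stats::rnorm(nVoxels) / sqrt(nVoxels)
    }
  }
  attr(bank, "prototypes") <- proto
  bank
}

#' Default amplitude/inversion/stimulus-drive schedules
#'
#' The generative model of a trial is, per TR t and condition c,
#' \deqn{x(t) = a(c,t) s(c,t) P(cat, ex) + b(c,t) P(cat) + \epsilon,}
#' where `a` is the category-signal amplitude, `s` in [-1, 1] the
#' representational inversion coefficient, and `b` the display-evoked drive
#' of the trial's own category (non-zero only while that category is
#' actually on screen). The defaults emulate the task phases after a ~4 s
#' haemodynamic lag: encoding of the memory item, the 8 s delay, Search 1
#' and Search 2 epochs. Currently relevant templates carry the strongest
#' signal (plus display drive during their search); prospective templates
#' carry a moderate delay signal, a sign-inverted signal during Search 1
#' (the anti-correlated prospective code) and a strong upright signal during
#' Search 2; irrelevant items carry delay signal only. In Experiment 1 the
#' no-longer-relevant current template is also inverted during Search 2.
#'
#' @param experiment `"exp1"` (15 TRs, conditions current/prospective) or
#'   `"exp2"` (16 TRs, current/prospective/irrelevant).
#' @return list with numeric matrices `a`, `s`, `b` (condition x TR,
#'   rownames = conditions).
#' @seealso [defaultIntervals()] for the matching analysis windows.
#' @export
defaultSchedules <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp2") {
    nTrs <- 16L
    conds <- c("current", "prospective", "irrelevant")
    a <- matrix(0, 3, nTrs, dimnames = list(conds, NULL))
    s <- matrix(1, 3, nTrs, dimnames = list(conds, NULL))
    b <- matrix(0, 3, nTrs, dimnames = list(conds, NULL))
    # encoding (TRs 3-4, lagged stimulus presentation at trial start)
    a[, 3:4] <- 0.8; b[, 3:4] <- 0.8
    # delay (TRs 5-7) and transition TR 8
    a["current", 5:7] <- 1.5;     a["current", 8] <- 1.7
    a["prospective", 5:7] <- 1.0; a["prospective", 8] <- 0.6
    a["irrelevant", 5:7] <- 0.9;  a["irrelevant", 8] <- 0.4
    # Search 1 (TRs 9-11) + transition TR 12
    a["current", 9:11] <- 2.0; b["current", 9:11] <- 1.0
    a["current", 12] <- 1.2
    a["prospective", 9:11] <- 0.8; s["prospective", 9:12] <- -1
    a["prospective", 12] <- 0.8
    # Search 2 (TRs 13-15) + tail TR 16
    a["current", 13:15] <- 0.4; s["current", 13:16] <- -1
    a["current", 16] <- 0.2
    a["prospective", 13:15] <- 1.8; b["prospective", 13:15] <- 1.0
    a["prospective", 16] <- 0.8
  } else {
    nTrs <- 15L
    conds <- c("current", "prospective")
    a <- matrix(0, 2, nTrs, dimnames = list(conds, NULL))
    s <- matrix(1, 2, nTrs, dimnames = list(conds, NULL))
    b <- matrix(0, 2, nTrs, dimnames = list(conds, NULL))
    a[, 2:3] <- 0.8; b[, 2:3] <- 0.8
    a["current", 4:6] <- 1.5;     a["current", 7] <- 1.7
    a["prospective", 4:6] <- 1.0; a["prospective", 7] <- 0.6
    a["current", 8:10] <- 2.0; b["current", 8:10] <- 1.0
    a["current", 11] <- 1.2
    a["prospective", 8:10] <- 0.8; s["prospective", 8:11] <- -1
    a["prospective", 11] <- 0.8
    a["current", 12:14] <- 0.8; s["current", 12:15] <- -1
    a["current", 15] <- 0.3
    a["prospective", 12:14] <- 1.8; b["prospective", 12:14] <- 1.0
    a["prospective", 15] <- 0.8
  }
  list(a = a, s = s, b = b)
}

#' Default analysis intervals (three TRs each)
#'
#' Delay, Search 1 and Search 2 windows covering the 8 s task epochs shifted
#' by the haemodynamic lag; the exact indices are a configuration choice.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return named list of integer TR vectors.
#' @export
defaultIntervals <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp2")
    list(delay = 5:7, search1 = 9:11, search2 = 13:15)
  else
    list(delay = 4:6, search1 = 8:10, search2 = 12:14)
}

#' Construct simulation parameters
#'
#' @param experiment `"exp1"` or `"exp2"` (selects default schedules).
#' @param nVoxels number of voxels in the simulated region of interest.
#' @param noiseSd additive Gaussian noise sd per voxel (must be > 0 for data
#'   fed to the GLM path).
#' @param ar1 AR(1) coefficient of the noise across TRs, in [0, 1); the
#'   marginal sd stays `noiseSd`.
#' @param exemplarJitterSd exemplar jitter magnitude (see
#'   [makeCategoryPatterns()]).
#' @param schedules list of `a`, `s`, `b` condition x TR matrices (defaults
#'   to [defaultSchedules()]).
#' @param hrf double-gamma haemodynamic response parameters for the BOLD
#'   path: `peak` delay (s), `undershoot` delay (s), `ratio` of undershoot
#'   to peak amplitude.
#' @param seed integer seed for the noise.
#' @param bankSeed integer seed for the category pattern bank (defaults to
#'   `seed + 1`).
#' @return list of class `"SimulationParams"`.
#' @export
simParams <- function(experiment = c("exp1", "exp2"), nVoxels = 100L,
                      noiseSd = 1, ar1 = 0.3, exemplarJitterSd = 0.3,
                      schedules = NULL,
                      hrf = c(peak = 6, undershoot = 16, ratio = 1 / 6),
                      seed = 1L, bankSeed = NULL) {
  experiment <- match.arg(experiment)
  if (is.null(schedules)) schedules <- defaultSchedules(experiment)
  if (is.null(bankSeed)) bankSeed <- as.integer(seed) + 1L
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)")
  stopifnot(all(c("a", "s", "b") %in% names(schedules)))
  if (any(schedules$a < 0)) stop("amplitude schedule must be >= 0")
  if (any(abs(schedules$s) > 1)) stop("inversion schedule must lie in [-1, 1]")
  if (any(schedules$b < 0)) stop("stimulus-drive schedule must be >= 0")
  structure(list(experiment = experiment, nVoxels = as.integer(nVoxels),
                 noiseSd = noiseSd, ar1 = ar1,
                 exemplarJitterSd = exemplarJitterSd,
                 schedules = schedules, hrf = hrf,
                 seed = as.integer(seed), bankSeed = as.integer(bankSeed)),
            class = "SimulationParams")
}

## look up schedule values for one trial, with an explicit error naming the
## missing (condition, TR) entry
.scheduleRow <- function(sched, condition, nTrs, what) {
  m <- sched[[what]]
  if (!condition %in% rownames(m))
    stop("schedule '", what, "' has no entry for condition '", condition, "'")
  if (ncol(m) < nTrs)
    stop("schedule '", what, "' is missing entries for (", condition,
         ", TR ", ncol(m) + 1L, "..", nTrs, ")")
  m[condition, seq_len(nTrs)]
}

## stationary AR(1) Gaussian noise, trials x TRs x voxels
.simNoise <- function(nTrial, nTrs, nVox, sd, ar1) {
  eps <- array(stats::rnorm(nTrial * nTrs * nVox, sd = sd),
               c(nTrial, nTrs, nVox))
  if (ar1 > 0 && nTrs > 1L) {
    scale <- sqrt(1 - ar1^2)
    for (t in 2:nTrs)
      eps[, t, ] <- ar1 * eps[, t - 1L, ] + scale * eps[, t, ]
  }
  eps
}

#' Simulate per-trial, per-TR voxel t-patterns directly
#'
#' Generates the pattern model
#' `x(trial, tr) = a * s * P(category, exemplar) + b * P(category) + noise`
#' without passing through the BOLD/GLM stage (see [simulateBoldGlm()] for
#' the haemodynamic path). Deterministic for a fixed seed.
#'
#' @param design trial design from [generateDesign()].
#' @param params parameters from [simParams()].
#' @param subjectId identifier stored in the dataset.
#' @return a [PatternDataset-class].
#' @examples
#' d <- generateDesign("exp2", seed = 1)
#' ds <- simulateTPatterns(d, simParams("exp2", nVoxels = 20, seed = 1))
#' ds
#' @export
simulateTPatterns <- function(design, params, subjectId = "sim01") {
  stopifnot(inherits(params, "SimulationParams"))
  nTrial <- nrow(design)
  if (nTrial == 0L) stop("design has no trials")
  nTrs <- design$n_trs[1L]
  nVox <- params$nVoxels
  bank <- makeCategoryPatterns(nVox, nCategories = max(design$category, 3L),
                               nExemplars = max(design$exemplar, 4L),
                               exemplarJitterSd = params$exemplarJitterSd,
                               seed = params$bankSeed)
  proto <- attr(bank, "prototypes")

  # validate schedule coverage before consuming randomness
  for (cond in unique(as.character(design$condition)))
    for (what in c("a", "s", "b"))
      .scheduleRow(params$schedules, cond, nTrs, what)

  set.seed(params$seed)
  x <- .simNoise(nTrial, nTrs, nVox, params$noiseSd, params$ar1)
  for (i in seq_len(nTrial)) {
    cond <- as.character(design$condition[i])
    a <- .scheduleRow(params$schedules, cond, nTrs, "a")
    s <- .scheduleRow(params$schedules, cond, nTrs, "s")
    b <- .scheduleRow(params$schedules, cond, nTrs, "b")
    pex <- bank[design$category[i], design$exemplar[i], ]
    pcat <- proto[design$category[i], ]
    x[i, , ] <- x[i, , ] + outer(a * s, pex) + outer(b, pcat)
  }
  methods::new("PatternDataset", patterns = x, trialInfo = design,
               subjectId = subjectId,
               chanceLevel = 1 / length(unique(design$category)),
               provenance = list(generator = "simulateTPatterns",
                                 seed = params$seed,
                                 bankSeed = params$bankSeed,
                                 nVoxels = nVox,
                                 noiseSd = params$noiseSd, ar1 = params$ar1))
}
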