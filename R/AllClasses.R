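## Central containers of the package. All of them are deliberately light:
## a validated array/matrix plus the metadata needed to interpret it.

#' PatternDataset: per-trial, per-TR voxel patterns with trial metadata
#'
#' The currency of every analysis stage. `patterns` holds one t-value (or
#' simulated t-value) per voxel, per TR, per trial; `trialInfo` describes the
#' trials (run, relevance condition, category, exemplar, target presence).
#'
#' @slot patterns numeric array, trial x TR x voxel.
#' @slot trialInfo data.frame with one row per trial (columns `trial_id`,
#'   `run`, `condition`, `category`, `exemplar`, `target_present`, `n_trs`).
#' @slot subjectId character scalar identifying the (simulated) subject.
#' @slot chanceLevel numeric scalar, 1 / number of distinct categories.
#' @slot provenance list recording how the data were produced (generator
#'   parameter digest or ingest path).
#'
#' @seealso [simulateTPatterns()], [simulateBoldGlm()], [decodeTimecourse()]
#' @export
setClass("PatternDataset",
  slots = c(
    patterns = "array",
    trialInfo = "data.frame",
    subjectId = "character",
    chanceLevel = "numeric",
    provenance = "list"
  )
)

setValidity("PatternDataset", function(object) {
  msg <- character(0)
  p <- object@patterns
  if (length(dim(p)) != 3L)
    msg <- c(msg, "patterns must be a 3-d array (trial x TR x voxel)")
  if (!all(is.finite(p)))
    msg <- c(msg, "patterns must be finite")
  ti <- object@trialInfo
  req <- c("trial_id", "run", "condition", "category", "exemplar", "n_trs")
  miss <- setdiff(req, names(ti))
  if (length(miss))
    msg <- c(msg, paste0("trialInfo lacks columns: ", paste(miss, collapse = ", ")))
  if (length(dim(p)) == 3L && nrow(ti) != dim(p)[1L])
    msg <- c(msg, "trial axis length must equal nrow(trialInfo)")
  if (length(dim(p)) == 3L && nrow(ti) > 0L && !all(ti$n_trs == dim(p)[2L]))
    msg <- c(msg, "TR axis length must equal trialInfo$n_trs")
  if (length(object@chanceLevel) != 1L || object@chanceLevel <= 0 ||
      object@chanceLevel > 1)
    msg <- c(msg, "chanceLevel must be a single value in (0, 1]")
  if (nrow(ti) > 0L) {
    expected <- 1 / length(unique(ti$category))
    if (abs(object@chanceLevel - expected) > 1e-12)
      msg <- c(msg, "chanceLevel must equal 1/number-of-categories in the design")
  }
  if (length(msg)) msg else TRUE
})

#' DecodingScheme: which condition is trained, which is tested, and how
#'
#' @slot trainCondition character, relevance condition used for training.
#' @slot testCondition character, relevance condition used for testing
#'   (equal to `trainCondition` for within-relevance schemes).
#' @slot cv character, one of `"loro"` (leave-one-run-out),
#'   `"balanced_loro"` (the balanced 99-fit scheme for 9-run designs) or
#'   `"train_all_cross"` (cross-relevance: train on all trials of one
#'   condition, test on all of the other, both directions averaged).
#' @slot label character display label.
#' @export
setClass("DecodingScheme",
  slots = c(
    trainCondition = "character",
    testCondition = "character",
    cv = "character",
    label = "character"
  )
)

setValidity("DecodingScheme", function(object) {
  msg <- character(0)
  if (!object@cv %in% c("loro", "balanced_loro", "train_all_cross"))
    msg <- c(msg, "cv must be one of 'loro', 'balanced_loro', 'train_all_cross'")
  within <- identical(object@trainCondition, object@testCondition)
  if (within && object@cv == "train_all_cross")
    msg <- c(msg, "train_all_cross requires trainCondition != testCondition")
  if (!within && object@cv != "train_all_cross")
    msg <- c(msg, "within-relevance schemes require trainCondition == testCondition")
  if (length(msg)) msg else TRUE
})

#' DecodingTimecourse: per-TR decoding accuracy for one scheme and subject
#'
#' @slot accuracy numeric vector of accuracies (chance = `chanceLevel` of the
#'   dataset, 1/3 for three categories); `NA` at TRs that were not computed.
#' @slot trs integer vector of the TR indices that were computed.
#' @slot scheme the [DecodingScheme-class] that produced the timecourse.
#' @slot subjectId character scalar.
#' @slot nFits integer vector, number of classifier fits per computed TR.
#' @export
setClass("DecodingTimecourse",
  slots = c(
    accuracy = "numeric",
    trs = "integer",
    scheme = "DecodingScheme",
    subjectId = "character",
    nFits = "integer"
  )
)

setValidity("DecodingTimecourse", function(object) {
  msg <- character(0)
  acc <- object@accuracy[object@trs]
  if (any(!is.na(acc) & (acc < 0 | acc > 1)))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (any(object@trs < 1L) || any(object@trs > length(object@accuracy)))
    msg <- c(msg, "trs out of range")
  if (length(msg)) msg else TRUE
})

#' GeneralizationMatrix: train-TR x test-TR decoding accuracy
#'
#' @slot accuracy numeric square matrix; entry (i, j) is the accuracy of a
#'   classifier trained at TR i and tested at TR j under the scheme's
#'   cross-validation, so train and test trials never overlap even at i = j.
#' @slot scheme the [DecodingScheme-class] used.
#' @slot subjectId character scalar.
#' @export
setClass("GeneralizationMatrix",
  slots = c(
    accuracy = "matrix",
    scheme = "DecodingScheme",
    subjectId = "character"
  )
)

setValidity("GeneralizationMatrix", function(object) {
  msg <- character(0)
  a <- object@accuracy
  if (nrow(a) != ncol(a))
    msg <- c(msg, "accuracy matrix must be square (train TR x test TR)")
  if (any(!is.na(a) & (a < 0 | a > 1)))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RDM: labelled representational dissimilarity matrix
#'
#' @slot d numeric square symmetric matrix with zero diagonal. On the
#'   `"one_minus_rho"` scale cells are 1 - Spearman rho (range [0, 2]); on
#'   the `"fisher"` scale cells are -atanh(rho).
#' @slot labels data.frame with columns `category`, `exemplar`, `relevance`,
#'   one row per matrix row/column.
#' @slot scope character, TR index or interval name the RDM refers to.
#' @slot nRunsAveraged numeric matrix (same shape as `d`) giving, per cell,
#'   the number of runs that contributed to the average.
#' @slot scale character, `"one_minus_rho"`, `"fisher"` or `"rank"`.
#' @export
setClass("RDM",
  slots = c(
    d = "matrix",
    labels = "data.frame",
    scope = "character",
    nRunsAveraged = "matrix",
    scale = "character"
  )
)

setValidity("RDM", function(object) {
  msg <- character(0)
  d <- object@d
  if (nrow(d) != ncol(d))
    msg <- c(msg, "d must be square")
  if (nrow(object@labels) != nrow(d))
    msg <- c(msg, "labels must have one row per matrix row")
  if (!all(abs(diag(d)) < 1e-8))
    msg <- c(msg, "diagonal must be zero")
  if (max(abs(d - t(d)), 0) > 1e-8)
    msg <- c(msg, "d must be symmetric")
  if (object@scale == "one_minus_rho" &&
      any(d < -1e-8 | d > 2 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "1 - rho cells must lie in [0, 2]")
  if (!object@scale %in% c("one_minus_rho", "fisher", "rank"))
    msg <- c(msg, "scale must be 'one_minus_rho', 'fisher' or 'rank'")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: output of the 2-D cluster-based sign-flip permutation test
#'
#' @slot clusters list of clusters; each is a list with `cells` (two-column
#'   matrix of (train TR, test TR) indices), `mass` (summed t), `p`
#'   (permutation p-value) and `tail` (`"positive"`/`"negative"`).
#' @slot tMap numeric matrix of per-cell one-sample t statistics.
#' @slot sigMask logical matrix marking cells in significant clusters.
#' @slot alpha numeric, corrected significance level.
#' @slot clusterAlpha numeric, cluster-forming threshold level.
#' @slot nPerm numeric, number of permutations (2^n in exhaustive mode).
#' @slot tail character, `"positive"`, `"negative"` or `"two.sided"`.
#' @slot exhaustive logical, whether all sign assignments were enumerated.
#' @export
setClass("ClusterResult",
  slots = c(
    clusters = "list",
    tMap = "matrix",
    sigMask = "matrix",
    alpha = "numeric",
    clusterAlpha = "numeric",
    nPerm = "numeric",
    tail = "character",
    exhaustive = "logical"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character(0)
  ps <- vapply(object@clusters, function(cl) cl$p, numeric(1))
  if (any(ps <= 0 | ps > 1))
    msg <- c(msg, "permutation p-values must lie in (0, 1]")
  if (object@nPerm < 1)
    msg <- c(msg, "nPerm must be >= 1")
  if (length(msg)) msg else TRUE
})
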