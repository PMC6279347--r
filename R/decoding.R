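#' Fit a one-vs-rest logistic-regression category classifier
#'
#' One binary logistic regression per category (that category versus the
#' rest), fitted by iteratively reweighted least squares with a small L2
#' ridge on the weights (not the intercept) to stabilize separable data.
#' Prediction is the argmax of the per-class linear scores; ties are broken
#' toward the lowest category index so the classifier is deterministic.
#'
#' @param X numeric matrix, trials x voxels (features used as-is; optional
#'   per-feature standardization via `standardize`).
#' @param y category labels (integer or factor), at least two distinct.
#' @param maxIter iteration cap of the IRLS algorithm.
#' @param lambda L2 ridge penalty on the weights.
#' @param standardize center/scale features before fitting (also applied at
#'   prediction time); off by default.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @return object of class `"ovrLogistic"` with per-class weight vectors.
#' @examples
#' X <- rbind(c(0, 0), c(1, 1))
#' fit <- fitOvrLogistic(X, c(1, 2))
#' predict(fit, X)
#' @export
fitOvrLogistic <- function(X, y, maxIter = 5000L, lambda = 1e-4,
                           standardize = FALSE, tol = 1e-8) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features")
  classes <- sort(unique(as.integer(y)))
  if (length(classes) < 2L) stop("need at least 2 distinct labels")
  y <- as.integer(y)
  ctr <- NULL; scl <- NULL
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(1, X)
  pen <- c(0, rep(lambda, p))             # intercept unpenalized
  W <- matrix(0, p + 1L, length(classes))
  converged <- logical(length(classes))
  negll <- function(w, z) {
    eta <- drop(Xd %*% w)
    # numerically stable -log-likelihood + ridge
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - z * eta) +
      sum(pen * w^2) / 2
  }
  for (ci in seq_along(classes)) {
    z <- as.numeric(y == classes[ci])
    w <- numeric(p + 1L)
    obj <- negll(w, z)
    for (iter in seq_len(maxIter)) {
      eta <- drop(Xd %*% w)
      mu <- 1 / (1 + exp(-eta))
      wt <- pmax(mu * (1 - mu), 1e-10)
      # Newton/IRLS step on the penalized log-likelihood
      H <- crossprod(Xd, Xd * wt) + diag(pen, p + 1L)
      g <- crossprod(Xd, z - mu) - pen * w
      step <- drop(tryCatch(solve(H, g), error = function(e)
        solve(H + diag(1e-8, p + 1L), g)))
      # step-halving keeps the penalized deviance monotone (full Newton can
      # oscillate on separable data)
      objNew <- negll(w + step, z)
      halvings <- 0L
      while (objNew > obj && halvings < 30L) {
        step <- step / 2
        objNew <- negll(w + step, z)
        halvings <- halvings + 1L
      }
      w <- w + step
      if (max(abs(step)) < tol ||
          abs(obj - objNew) < 1e-10 * (1 + abs(objNew))) {
        converged[ci] <- TRUE
        break
      }
      obj <- objNew
    }
    if (!converged[ci])
      warning("IRLS did not converge within ", maxIter,
              " iterations for class ", classes[ci],
              "; returning current iterate")
    W[, ci] <- w
  }
  structure(list(weights = W, classes = classes, center = ctr, scale = scl),
            class = "ovrLogistic")
}

#' Predict categories (or class scores) from a fitted one-vs-rest model
#'
#' @param object an `"ovrLogistic"` fit.
#' @param newdata numeric matrix, trials x voxels.
#' @param type `"class"` for argmax labels (ties toward the lowest category
#'   index), `"score"` for linear scores, `"prob"` for per-class logistic
#'   probabilities (not normalized across classes).
#' @param ... unused.
#' @return integer labels, or a trials x classes matrix.
#' @export
predict.ovrLogistic <- function(object, newdata, type = c("class", "score",
                                                          "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  scores <- cbind(1, X) %*% object$weights
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  if (type == "prob") return(1 / (1 + exp(-scores)))
  object$classes[max.col(scores, ties.method = "first")]
}

## extract the feature matrix and labels of one condition at one TR
.conditionSlice <- function(dataset, condition, tr) {
  ti <- trialInfo(dataset)
  idx <- which(as.character(ti$condition) == condition)
  if (!length(idx)) stop("condition '", condition, "' absent from dataset")
  if (tr < 1L || tr > nTRs(dataset)) stop("tr ", tr, " out of range")
  list(X = patterns(dataset)[idx, tr, , drop = TRUE],
       y = ti$category[idx], run = ti$run[idx], idx = idx)
}

#' Within-relevance leave-one-run-out decoding accuracy at one TR
#'
#' Standard leave-one-run-out cross-validation on the trials of one
#' relevance condition: train on all runs but one, test on the left-out run,
#' average accuracy over folds (every trial is tested exactly once).
#'
#' @param dataset a [PatternDataset-class] with >= 2 runs of the condition.
#' @param condition relevance condition (`"current"`, `"prospective"`, ...).
#' @param tr TR index (training and testing use the same TR; see
#'   [crossTemporalMatrix()] for train/test at different TRs).
#' @param testTr optional distinct test TR (defaults to `tr`).
#' @param ... passed to [fitOvrLogistic()].
#' @return mean accuracy over folds.
#' @export
loroWithin <- function(dataset, condition, tr, testTr = tr, ...) {
  sl <- .conditionSlice(dataset, condition, tr)
  slTest <- if (testTr == tr) sl else .conditionSlice(dataset, condition, testTr)
  runs <- sort(unique(sl$run))
  if (length(runs) < 2L) stop("need >= 2 runs of condition '", condition, "'")
  acc <- vapply(runs, function(r) {
    tr_i <- sl$run != r
    te_i <- slTest$run == r
    if (length(unique(sl$y[tr_i])) < 2L)
      stop("training fold (run ", r, " left out) has a single category")
    fit <- fitOvrLogistic(sl$X[tr_i, , drop = FALSE], sl$y[tr_i], ...)
    mean(predict(fit, slTest$X[te_i, , drop = FALSE]) == slTest$y[te_i])
  }, numeric(1))
  mean(acc)
}

## For a 9-run design the training set of a fold holds 32 trials of the
## condition whose category counts are a permutation of (10, 11, 11); the
## exclusion plan pairs the i-th surplus trial of each 11-count category so
## that every surplus trial is excluded exactly once over the 11 repetitions.
.balancedFoldPlan <- function(yTrain, foldName) {
  counts <- table(yTrain)
  u <- sort(unique(as.integer(names(counts))))
  cnt <- as.integer(counts[as.character(u)])
  mx <- max(cnt); mn <- min(cnt)
  if (mx != mn + 1L || sum(cnt == mx) != 2L || sum(cnt == mn) != 1L)
    stop("fold ", foldName, ": training category counts (",
         paste(cnt, collapse = ","),
         ") are not a permutation of (n, n+1, n+1)")
  surplus <- u[cnt == mx]
  reps <- mx
  lapply(seq_len(reps), function(i) {
    # indices (within the training subset) to exclude at repetition i
    vapply(surplus, function(k) which(yTrain == k)[i], integer(1))
  })
}

#' Balanced leave-one-run-out decoding (9-run designs) at one TR
#'
#' The modified cross-validation for designs whose per-fold training counts
#' are not a multiple of the number of categories: for each left-out run the
#' two categories with a surplus training trial have one trial each excluded,
#' repeated so that every surplus trial is excluded exactly once (11
#' repetitions for the canonical 9-run design), leaving 30 training trials
#' (10 per category). Each repetition's fold score is the balanced accuracy
#' (per-class accuracy averaged over classes) on the left-out run; the
#' overall score is the mean over all fits (99 per TR for 9 runs).
#'
#' @param dataset a [PatternDataset-class] with an Experiment-2 style design.
#' @param condition relevance condition.
#' @param tr TR index.
#' @param testTr optional distinct test TR (defaults to `tr`).
#' @param details if TRUE, attach a data.frame of per-fit diagnostics
#'   (fold, repetition, training size, per-category training counts, score)
#'   as attribute `"fits"`.
#' @param ... passed to [fitOvrLogistic()].
#' @return mean balanced accuracy over all fits.
#' @export
balancedLoro <- function(dataset, condition, tr, testTr = tr,
                         details = FALSE, ...) {
  sl <- .conditionSlice(dataset, condition, tr)
  slTest <- if (testTr == tr) sl else .conditionSlice(dataset, condition, testTr)
  runs <- sort(unique(sl$run))
  if (length(runs) < 2L) stop("need >= 2 runs of condition '", condition, "'")
  cats <- sort(unique(sl$y))
  scores <- numeric(0)
  diag_ <- if (details) list() else NULL
  for (r in runs) {
    trIdx <- which(sl$run != r)
    teIdx <- which(slTest$run == r)
    plan <- .balancedFoldPlan(sl$y[trIdx], paste0("run ", r, " left out"))
    for (rep_i in seq_along(plan)) {
      keep <- trIdx[-plan[[rep_i]]]
      fit <- fitOvrLogistic(sl$X[keep, , drop = FALSE], sl$y[keep], ...)
      pred <- predict(fit, slTest$X[teIdx, , drop = FALSE])
      yTest <- slTest$y[teIdx]
      perClass <- vapply(cats[cats %in% yTest], function(k)
        mean(pred[yTest == k] == k), numeric(1))
      ba <- mean(perClass)
      scores <- c(scores, ba)
      if (details) {
        cnt <- table(factor(sl$y[keep], levels = cats))
        diag_[[length(diag_) + 1L]] <-
          data.frame(fold = r, repetition = rep_i, n_train = length(keep),
                     t(as.matrix(cnt)), score = ba)
      }
    }
  }
  out <- mean(scores)
  if (details) attr(out, "fits") <- do.call(rbind, diag_)
  out
}

#' Cross-relevance decoding accuracy at one TR
#'
#' Trains on all trials of one relevance condition and tests on all trials
#' of another (the two sets are disjoint by condition, so no run-splitting
#' is needed), in both directions. The average of the two directions is the
#' headline statistic; below-chance values indicate systematically
#' anti-correlated patterns across relevance.
#'
#' @param dataset a [PatternDataset-class].
#' @param condTrain,condTest two distinct relevance conditions.
#' @param tr TR index.
#' @param testTr optional distinct test TR (defaults to `tr`).
#' @param runSplit if TRUE, use leave-one-run-out structure also across
#'   conditions (train on all-but-one run of `condTrain`, test on the
#'   left-out run of `condTest`); a sensitivity variant.
#' @param ... passed to [fitOvrLogistic()].
#' @return list with `ab` (train `condTrain` / test `condTest`), `ba` (the
#'   reverse) and `average`.
#' @export
crossRelevance <- function(dataset, condTrain, condTest, tr, testTr = tr,
                           runSplit = FALSE, ...) {
  if (identical(condTrain, condTest))
    stop("cross-relevance requires two different conditions; ",
         "use the within scheme for condTrain == condTest")
  oneWay <- function(cTrain, cTest) {
    a <- .conditionSlice(dataset, cTrain, tr)
    b <- .conditionSlice(dataset, cTest, testTr)
    if (!runSplit) {
      fit <- fitOvrLogistic(a$X, a$y, ...)
      mean(predict(fit, b$X) == b$y)
    } else {
      runs <- sort(unique(b$run))
      mean(vapply(runs, function(r) {
        fit <- fitOvrLogistic(a$X[a$run != r, , drop = FALSE],
                              a$y[a$run != r], ...)
        te <- b$run == r
        mean(predict(fit, b$X[te, , drop = FALSE]) == b$y[te])
      }, numeric(1)))
    }
  }
  ab <- oneWay(condTrain, condTest)
  ba <- oneWay(condTest, condTrain)
  list(ab = ab, ba = ba, average = (ab + ba) / 2)
}

#' Construct a decoding scheme
#'
#' @param train,test relevance conditions (equal for within-relevance).
#' @param cv `"loro"`, `"balanced_loro"` or `"train_all_cross"`; defaults to
#'   `"loro"` for within schemes and `"train_all_cross"` for cross schemes.
#' @param label display label.
#' @return a [DecodingScheme-class].
#' @export
decodingScheme <- function(train, test = train, cv = NULL, label = NULL) {
  if (is.null(cv))
    cv <- if (identical(train, test)) "loro" else "train_all_cross"
  if (is.null(label))
    label <- if (identical(train, test)) paste0("within-", train)
             else paste0("cross-", train, "-", test)
  methods::new("DecodingScheme", trainCondition = train, testCondition = test,
               cv = cv, label = label)
}

## accuracy of a scheme at (trainTr, testTr); nFits attribute optional
.schemeAccuracy <- function(dataset, scheme, tr, testTr = tr, ...) {
  switch(scheme@cv,
    loro = loroWithin(dataset, scheme@trainCondition, tr, testTr, ...),
    balanced_loro = balancedLoro(dataset, scheme@trainCondition, tr, testTr,
                                 ...),
    train_all_cross = crossRelevance(dataset, scheme@trainCondition,
                                     scheme@testCondition, tr, testTr,
                                     ...)$average)
}

.schemeNFits <- function(dataset, scheme) {
  ti <- trialInfo(dataset)
  nRuns <- length(unique(ti$run[as.character(ti$condition) ==
                                  scheme@trainCondition]))
  switch(scheme@cv,
    loro = nRuns,
    balanced_loro = {
      # repetitions per fold = max per-category training count (11 for the
      # canonical 9-run design), giving 99 fits in total
      nPerCond <- sum(as.character(ti$condition) == scheme@trainCondition)
      nCat <- length(unique(ti$category))
      reps <- ceiling((nPerCond - nPerCond / nRuns) / nCat)
      as.integer(nRuns * reps)
    },
    train_all_cross = 2L)
}

#' Decode a full timecourse for one scheme
#'
#' Applies a decoding scheme at every requested TR (training and testing at
#' the same TR). Errors from individual TRs are re-signalled with the TR
#' index attached.
#'
#' @param dataset a [PatternDataset-class].
#' @param scheme a [DecodingScheme-class] (see [decodingScheme()]).
#' @param trs TR indices to compute (default: all).
#' @param ... passed to the underlying decoders.
#' @return a [DecodingTimecourse-class]; accuracies at TRs not in `trs` are
#'   `NA`.
#' @export
decodeTimecourse <- function(dataset, scheme, trs = NULL, ...) {
  nT <- nTRs(dataset)
  if (is.null(trs)) trs <- seq_len(nT)
  trs <- as.integer(trs)
  acc <- rep(NA_real_, nT)
  for (t in trs) {
    acc[t] <- tryCatch(.schemeAccuracy(dataset, scheme, t, ...),
                       error = function(e)
                         stop("TR ", t, ": ", conditionMessage(e),
                              call. = FALSE))
  }
  methods::new("DecodingTimecourse", accuracy = acc, trs = trs,
               scheme = scheme, subjectId = subjectId(dataset),
               nFits = rep(.schemeNFits(dataset, scheme), length(trs)))
}

#' Average a decoding timecourse over named TR intervals
#'
#' @param tc a [DecodingTimecourse-class] or plain numeric accuracy vector.
#' @param intervals named list of TR index vectors (see
#'   [defaultIntervals()]); three TRs each in the canonical analysis.
#' @return named numeric vector of per-interval mean accuracies.
#' @export
intervalAverage <- function(tc, intervals) {
  acc <- if (methods::is(tc, "DecodingTimecourse")) accuracy(tc) else tc
  if (!length(intervals)) stop("no intervals supplied")
  out <- vapply(seq_along(intervals), function(i) {
    idx <- intervals[[i]]
    if (!length(idx)) stop("interval '", names(intervals)[i], "' is empty")
    if (any(idx < 1L | idx > length(acc)))
      stop("interval '", names(intervals)[i], "' has TR indices out of range")
    mean(acc[idx])
  }, numeric(1))
  names(out) <- names(intervals)
  out
}
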