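#' Cross-temporal generalization matrix
#'
#' Trains the scheme's classifier at every TR and tests it at every other TR,
#' producing a train-TR x test-TR accuracy matrix (no smoothing). The
#' scheme's cross-validation is kept, so train and test trials never overlap
#' even on the diagonal, and the diagonal reproduces
#' [decodeTimecourse()] exactly (same folds, same fits).
#'
#' @param dataset a [PatternDataset-class].
#' @param scheme a [DecodingScheme-class].
#' @param trs TR indices to include (default: all); the matrix is square
#'   over these.
#' @param ... passed to the underlying decoders.
#' @return a [GeneralizationMatrix-class].
#' @export
crossTemporalMatrix <- function(dataset, scheme, trs = NULL, ...) {
  nT <- nTRs(dataset)
  if (is.null(trs)) trs <- seq_len(nT)
  trs <- as.integer(trs)
  acc <- matrix(NA_real_, length(trs), length(trs),
                dimnames = list(train = trs, test = trs))
  for (i in seq_along(trs)) {
    for (j in seq_along(trs)) {
      acc[i, j] <- tryCatch(
        .schemeAccuracy(dataset, scheme, trs[i], testTr = trs[j], ...),
        error = function(e)
          stop("train TR ", trs[i], ", test TR ", trs[j], ": ",
               conditionMessage(e), call. = FALSE))
    }
  }
  methods::new("GeneralizationMatrix", accuracy = acc, scheme = scheme,
               subjectId = subjectId(dataset))
}

## connected components of supra-threshold cells; returns list of integer
## cell-index vectors. connectivity 4 or 8.
.connectedClusters <- function(supra, nr, nc, connectivity = 4L) {
  cells <- which(supra)
  if (!length(cells)) return(list())
  remaining <- rep(TRUE, length(cells))
  names(remaining) <- cells
  inSupra <- logical(nr * nc)
  inSupra[cells] <- TRUE
  offsets <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  visited <- logical(nr * nc)
  out <- list()
  for (start in cells) {
    if (visited[start]) next
    stack <- start
    visited[start] <- TRUE
    comp <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, cur)
      ci <- ((cur - 1L) %% nr) + 1L
      cj <- ((cur - 1L) %/% nr) + 1L
      for (off in offsets) {
        ni <- ci + off[1L]; nj <- cj + off[2L]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc) {
          idx <- (nj - 1L) * nr + ni
          if (inSupra[idx] && !visited[idx]) {
            visited[idx] <- TRUE
            stack <- c(stack, idx)
          }
        }
      }
    }
    out[[length(out) + 1L]] <- comp
  }
  out
}

## max cluster mass of one permutation's t-vector for one tail
.maxClusterMass <- function(tvec, thr, nr, nc, connectivity, sign = 1) {
  tv <- sign * tvec
  supra <- !is.na(tv) & tv > thr
  if (!any(supra)) return(0)
  comps <- .connectedClusters(supra, nr, nc, connectivity)
  max(vapply(comps, function(idx) sum(tv[idx]), numeric(1)))
}

#' Two-dimensional cluster-based sign-flip permutation test
#'
#' Compares a group of per-subject generalization matrices against chance.
#' Each cell gets a one-sample t statistic of (accuracy - chance); cells
#' exceeding the cluster-forming threshold are grouped into 4-connected (or
#' 8-connected) clusters scored by their summed t (cluster mass). The null
#' distribution of the maximum cluster mass is built by randomly flipping
#' the sign of each subject's deviation matrix; a cluster's p-value is the
#' proportion of permutations whose maximum mass reaches its mass, with the
#' +1 correction so p is never exactly 0. When `2^n <= nPerm` (or
#' `exact = TRUE`) all sign assignments are enumerated instead of sampled.
#'
#' Two-sided testing is performed as two one-sided tests (positive and
#' negative clusters), each formed at `clusterAlpha / 2` and evaluated
#' against its own max-mass null at `alpha / 2`.
#'
#' @param matrices list of [GeneralizationMatrix-class] objects or plain
#'   numeric matrices of identical dimension, one per subject (>= 2).
#' @param chance chance accuracy subtracted from every cell (e.g. 1/3).
#' @param clusterAlpha cluster-forming threshold level (per-cell one-sided
#'   t quantile; halved per tail for two-sided tests).
#' @param alpha corrected family-wise significance level for cluster
#'   p-values (halved per tail for two-sided tests).
#' @param nPerm number of Monte-Carlo permutations (>= 1).
#' @param tail `"positive"`, `"negative"` or `"two.sided"`.
#' @param seed integer seed for the Monte-Carlo sign flips.
#' @param connectivity 4 (default) or 8.
#' @param exact force (TRUE) or forbid (FALSE) exhaustive enumeration of all
#'   2^n sign assignments; `NULL` enumerates automatically when feasible.
#' @return a [ClusterResult-class]. Cells with zero variance across subjects
#'   are excluded from cluster formation with a warning.
#' @export
clusterPermutation2d <- function(matrices, chance, clusterAlpha = 0.05,
                                 alpha = 0.05, nPerm = 10000L,
                                 tail = c("two.sided", "positive", "negative"),
                                 seed = 1L, connectivity = 4L, exact = NULL) {
  tail <- match.arg(tail)
  if (nPerm < 1) stop("nPerm must be >= 1")
  mats <- lapply(matrices, function(m)
    if (methods::is(m, "GeneralizationMatrix")) accuracy(m) else as.matrix(m))
  n <- length(mats)
  if (n < 2L) stop("need >= 2 subjects")
  dims <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1))))
    stop("matrices are not congruent")
  nr <- dims[1L]; nc <- dims[2L]
  D <- t(vapply(mats, function(m) as.numeric(m) - chance, numeric(nr * nc)))

  ssq <- colSums(D^2)
  obsMean <- colMeans(D)
  v <- (ssq - n * obsMean^2) / (n - 1)
  zeroVar <- v <= .Machine$double.eps * 100
  if (any(zeroVar))
    warning(sum(zeroVar), " zero-variance cell(s) excluded from cluster ",
            "formation")
  tObs <- obsMean / sqrt(v / n)
  tObs[zeroVar] <- NA_real_
  df <- n - 1L

  tailSpec <- switch(tail,
    positive = list(list(sign = 1, name = "positive")),
    negative = list(list(sign = -1, name = "negative")),
    two.sided = list(list(sign = 1, name = "positive"),
                     list(sign = -1, name = "negative")))
  nTails <- length(tailSpec)
  formAlpha <- clusterAlpha / nTails
  sigAlpha <- alpha / nTails
  thr <- stats::qt(1 - formAlpha, df)

  # sign-flip matrix (permutations x subjects)
  exhaustive <- if (is.null(exact)) (n <= 30 && 2^n <= nPerm) else isTRUE(exact)
  if (exhaustive) {
    if (n > 20L) stop("exhaustive enumeration infeasible for n > 20")
    m <- as.integer(2^n)
    S <- matrix(1, m, n)
    for (j in seq_len(n))
      S[, j] <- ifelse(bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                       -1, 1)
  } else {
    set.seed(as.integer(seed))
    m <- as.integer(nPerm)
    S <- matrix(sample(c(-1, 1), m * n, replace = TRUE), m, n)
  }

  # vectorized permutation t-statistics: flipping signs leaves sums of
  # squares unchanged, so only the mean changes
  permMean <- (S %*% D) / n
  permVar <- sweep(-n * permMean^2, 2L, ssq, "+") / (n - 1)
  permT <- permMean / sqrt(permVar / n)
  permT[, zeroVar] <- NA_real_

  clustersOut <- list()
  sigMask <- matrix(FALSE, nr, nc)
  for (ts in tailSpec) {
    tv <- ts$sign * tObs
    supra <- !is.na(tv) & tv > thr
    comps <- .connectedClusters(supra, nr, nc, connectivity)
    if (!length(comps)) next
    nullMax <- vapply(seq_len(m), function(pi)
      .maxClusterMass(permT[pi, ], thr, nr, nc, connectivity, ts$sign),
      numeric(1))
    for (comp in comps) {
      mass <- sum(tv[comp])
      p <- if (exhaustive) mean(nullMax >= mass)
           else (1 + sum(nullMax >= mass)) / (1 + m)
      p <- max(p, if (exhaustive) 1 / m else 1 / (1 + m))
      cellIdx <- cbind(((comp - 1L) %% nr) + 1L, ((comp - 1L) %/% nr) + 1L)
      colnames(cellIdx) <- c("train_tr", "test_tr")
      sig <- p <= sigAlpha
      if (sig) sigMask[cellIdx] <- TRUE
      clustersOut[[length(clustersOut) + 1L]] <-
        list(cells = cellIdx, mass = ts$sign * mass, p = p, tail = ts$name,
             significant = sig)
    }
  }
  methods::new("ClusterResult", clusters = clustersOut,
               tMap = matrix(tObs, nr, nc), sigMask = sigMask,
               alpha = alpha, clusterAlpha = clusterAlpha, nPerm = m,
               tail = tail, exhaustive = exhaustive)
}
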