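#' Per-run mean voxel patterns for each category/exemplar/relevance combination
#'
#' Averages the trials of every (category, exemplar, relevance) combination
#' within each run at one TR. Combinations absent from a run are returned as
#' `NA` rows (missingness is data, not an error: a 12-trial run of the
#' two-condition design holds only half of the 24 combinations).
#'
#' @param dataset a [PatternDataset-class].
#' @param tr TR index.
#' @param conditions relevance conditions to include (default: all present).
#' @return list with `patterns` (array combination x voxel x run) and
#'   `labels` (data.frame with columns `category`, `exemplar`, `relevance`).
#' @export
exemplarPatterns <- function(dataset, tr, conditions = NULL) {
  ti <- trialInfo(dataset)
  if (tr < 1L || tr > nTRs(dataset)) stop("tr ", tr, " out of range")
  if (is.null(conditions)) conditions <- sort(unique(as.character(ti$condition)))
  labels <- expand.grid(exemplar = sort(unique(ti$exemplar)),
                        category = sort(unique(ti$category)),
                        relevance = conditions, stringsAsFactors = FALSE)
  labels <- labels[, c("category", "exemplar", "relevance")]
  runs <- sort(unique(ti$run))
  p <- patterns(dataset)
  out <- array(NA_real_, c(nrow(labels), dim(p)[3L], length(runs)))
  for (ri in seq_along(runs)) {
    for (li in seq_len(nrow(labels))) {
      idx <- which(ti$run == runs[ri] &
                     ti$category == labels$category[li] &
                     ti$exemplar == labels$exemplar[li] &
                     as.character(ti$condition) == labels$relevance[li])
      if (length(idx))
        out[li, , ri] <- apply(p[idx, tr, , drop = FALSE], 3L, mean)
    }
  }
  list(patterns = out, labels = labels, runs = runs)
}

## Spearman-based dissimilarity between two pattern vectors
.rdmCell <- function(x, y, scale) {
  rho <- stats::cor(x, y, method = "spearman")
  if (scale == "fisher") -atanh(max(min(rho, 1 - 1e-12), -1 + 1e-12))
  else 1 - rho
}

#' Compute a representational dissimilarity matrix
#'
#' For each run, every pair of combination patterns present in that run gets
#' a dissimilarity of 1 - Spearman rho; cell values are averaged over the
#' runs in which both members exist, then over the requested TRs (three TRs
#' per interval in the canonical analysis). For the two-condition design at
#' 3 categories x 4 exemplars this yields the 24 x 24 matrix.
#'
#' @param dataset a [PatternDataset-class].
#' @param trs TR indices to average over (a single TR or an interval).
#' @param conditions relevance conditions to include (default: all present).
#' @param scale `"one_minus_rho"` (default) or `"fisher"`
#'   (cells are -atanh(rho), averaged on that scale).
#' @param runAverage `"pooled"` (default: average each combination's pattern
#'   across the runs where it occurs, then correlate once per TR) or
#'   `"per_run"` (correlate within each run and average cells over the runs
#'   where both members exist). The per-run mode requires every pair to
#'   co-occur in at least one run, which 12-trial runs of the 24-combination
#'   design cannot guarantee; it errors listing the first empty pair.
#' @param scope label stored in the result (defaults to the TR list).
#' @return an [RDM-class].
#' @export
computeRdm <- function(dataset, trs, conditions = NULL,
                       scale = c("one_minus_rho", "fisher"),
                       runAverage = c("pooled", "per_run"), scope = NULL) {
  scale <- match.arg(scale)
  runAverage <- match.arg(runAverage)
  trs <- as.integer(trs)
  if (is.null(scope)) scope <- paste(trs, collapse = ",")
  perTr <- vector("list", length(trs))
  labels <- NULL
  for (k in seq_along(trs)) {
    ep <- exemplarPatterns(dataset, trs[k], conditions)
    labels <- ep$labels
    nL <- nrow(labels)
    if (nL < 2L) stop("need >= 2 combinations with patterns")
    acc <- matrix(0, nL, nL)
    cnt <- matrix(0L, nL, nL)
    if (runAverage == "pooled") {
      nRunsIn <- apply(ep$patterns[, 1L, , drop = FALSE], 1L,
                       function(v) sum(!is.na(v)))
      if (any(nRunsIn == 0L)) {
        bad <- which(nRunsIn == 0L)[1L]
        stop("combination (", paste(labels$category[bad],
             labels$exemplar[bad], labels$relevance[bad], sep = "/"),
             ") occurs in no run")
      }
      pooled <- apply(ep$patterns, c(1L, 2L), mean, na.rm = TRUE)
      for (i in seq_len(nL - 1L)) {
        for (j in (i + 1L):nL) {
          acc[i, j] <- .rdmCell(pooled[i, ], pooled[j, ], scale)
          cnt[i, j] <- min(nRunsIn[i], nRunsIn[j])
        }
      }
    } else {
      for (ri in seq_len(dim(ep$patterns)[3L])) {
        pr <- ep$patterns[, , ri, drop = TRUE]
        present <- which(!is.na(pr[, 1L]))
        if (length(present) < 2L) next
        for (ii in seq_along(present)) {
          for (jj in seq_along(present)) {
            if (jj <= ii) next
            i <- present[ii]; j <- present[jj]
            dval <- .rdmCell(pr[i, ], pr[j, ], scale)
            acc[i, j] <- acc[i, j] + dval
            cnt[i, j] <- cnt[i, j] + 1L
          }
        }
      }
      if (any(cnt == 0L & upper.tri(cnt))) {
        bad <- which(cnt == 0L & upper.tri(cnt), arr.ind = TRUE)[1L, ]
        stop("no run contains both members of the pair (",
             paste(labels$category[bad[1L]], labels$exemplar[bad[1L]],
                   labels$relevance[bad[1L]], sep = "/"), ") vs (",
             paste(labels$category[bad[2L]], labels$exemplar[bad[2L]],
                   labels$relevance[bad[2L]], sep = "/"), ") at TR ", trs[k])
      }
      acc <- acc / pmax(cnt, 1L)
    }
    d <- acc + t(acc)
    perTr[[k]] <- list(d = d, cnt = cnt + t(cnt))
  }
  d <- Reduce(`+`, lapply(perTr, `[[`, "d")) / length(trs)
  cnt <- Reduce(`+`, lapply(perTr, `[[`, "cnt")) / length(trs)
  methods::new("RDM", d = d, labels = labels, scope = scope,
               nRunsAveraged = cnt, scale = scale)
}

#' Rank-transform an RDM to [0, 1]
#'
#' Replaces every off-diagonal element by its rank (average ranks for ties)
#' among the upper-triangle elements, scaled to [0, 1], mirrored to keep
#' symmetry. Order-preserving, hence invariant under monotone transforms of
#' the input and idempotent up to scaling. If all off-diagonal values are
#' equal, every cell becomes 0.5 by convention.
#'
#' @param rdm an [RDM-class].
#' @return an [RDM-class] on the `"rank"` scale.
#' @export
rankTransform <- function(rdm) {
  d <- dissimilarity(rdm)
  up <- upper.tri(d)
  vals <- d[up]
  r <- rank(vals)                       # average ranks for ties
  n <- length(vals)
  scaled <- if (n == 1L || max(r) == min(r)) rep(0.5, n)
            else (r - 1) / (n - 1)
  out <- matrix(0, nrow(d), ncol(d))
  out[up] <- scaled
  out <- out + t(out)
  methods::new("RDM", d = out, labels = rdmLabels(rdm), scope = rdm@scope,
               nRunsAveraged = rdm@nRunsAveraged, scale = "rank")
}

#' Classical (Torgerson) multidimensional scaling of an RDM
#'
#' Double-centering plus spectral decomposition via [stats::cmdscale()];
#' negative eigenvalues are truncated. Coordinates are defined up to
#' rotation/reflection. If fewer than `k` positive eigenvalues exist, the
#' dimensionality is reduced with a warning.
#'
#' @param rdm an [RDM-class] or a symmetric zero-diagonal matrix.
#' @param k target dimensionality (default 2).
#' @return matrix items x k of coordinates, with the labels (if available)
#'   as attribute `"labels"`.
#' @export
classicalMds <- function(rdm, k = 2L) {
  d <- if (methods::is(rdm, "RDM")) dissimilarity(rdm) else as.matrix(rdm)
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-8))
    stop("need a symmetric matrix with zero diagonal")
  if (all(d == 0)) {
    coords <- matrix(0, nrow(d), k)
  } else {
    kCap <- min(k, nrow(d) - 1L)
    fit <- stats::cmdscale(d, k = kCap, eig = TRUE)
    npos <- sum(fit$eig > 1e-10)
    if (npos < k) {
      warning("only ", npos, " positive eigenvalue(s); reducing k")
      kCap <- max(min(npos, kCap), 1L)
    }
    coords <- fit$points[, seq_len(min(kCap, ncol(fit$points))),
                         drop = FALSE]
  }
  if (methods::is(rdm, "RDM")) attr(coords, "labels") <- rdmLabels(rdm)
  coords
}

#' Same- versus different-category dissimilarity across two relevance levels
#'
#' Restricts the RDM to cells that cross the two relevance levels (e.g. a
#' current item against a prospective item), then averages cells where the
#' two items share the category (the 3 same-category blocks) and where they
#' do not (the 6 off-blocks). A negative difference (same < different) means
#' category structure is preserved across relevance; a positive difference
#' is the signature of an anti-correlated code. With `scale = "fisher"` each
#' contributing cell's underlying rho is Fisher-transformed and the
#' dissimilarity taken as -atanh(rho) before averaging.
#'
#' @param rdm an [RDM-class] on the `"one_minus_rho"` or `"fisher"` scale.
#' @param relevancePair character vector of two relevance levels.
#' @param scale `"raw"` (use the RDM's cells as-is) or `"fisher"`.
#' @return list with `sameCategoryMean`, `diffCategoryMean`,
#'   `difference` (same - different), `scale` and cell counts.
#' @export
sameVsDiffContrast <- function(rdm, relevancePair,
                               scale = c("fisher", "raw")) {
  scale <- match.arg(scale)
  lab <- rdmLabels(rdm)
  if (!all(relevancePair %in% lab$relevance))
    stop("relevance level(s) absent from RDM: ",
         paste(setdiff(relevancePair, lab$relevance), collapse = ", "))
  if (length(relevancePair) != 2L || relevancePair[1L] == relevancePair[2L])
    stop("relevancePair must name two distinct levels")
  d <- dissimilarity(rdm)
  if (scale == "fisher" && rdm@scale == "one_minus_rho") {
    rho <- pmax(pmin(1 - d, 1 - 1e-12), -1 + 1e-12)
    d <- -atanh(rho)
  } else if (scale == "fisher" && rdm@scale != "fisher") {
    stop("fisher scale requires a 'one_minus_rho' or 'fisher' RDM")
  }
  iA <- which(lab$relevance == relevancePair[1L])
  iB <- which(lab$relevance == relevancePair[2L])
  cross <- as.matrix(expand.grid(iA, iB))
  same <- lab$category[cross[, 1L]] == lab$category[cross[, 2L]]
  sameMean <- mean(d[cross[same, , drop = FALSE]])
  diffMean <- mean(d[cross[!same, , drop = FALSE]])
  list(sameCategoryMean = sameMean, diffCategoryMean = diffMean,
       difference = sameMean - diffMean, scale = scale,
       nSameCells = sum(same), nDiffCells = sum(!same))
}
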