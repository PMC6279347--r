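#' Paired / one-sample t-test with Cohen's d
#'
#' Standard paired t-test (or one-sample test against a constant), with the
#' effect size d = mean(diff) / sd(diff). Comparisons against chance in the
#' within-relevance decoding scheme are one-tailed (`tail = "greater"`),
#' since within-relevance decoding cannot meaningfully fall below chance;
#' everything else is two-tailed.
#'
#' @param x numeric vector of per-subject values.
#' @param y paired vector of the same length, or a single constant (e.g. the
#'   chance level 1/3).
#' @param tail `"two.sided"`, `"greater"` or `"less"` (direction of x - y).
#' @return list of class `"ttestResult"` with `t`, `df`, `p`, `d`, `tail`,
#'   `meanDiff`, `n`.
#' @export
pairedT <- function(x, y = 0, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (length(y) == 1L) y <- rep(y, length(x))
  if (length(x) != length(y)) stop("paired lengths differ")
  n <- length(x)
  if (n < 2L) stop("need n >= 2")
  diff <- x - y
  sdd <- stats::sd(diff)
  if (sdd == 0) stop("zero-variance difference: t undefined")
  tstat <- mean(diff) / (sdd / sqrt(n))
  df <- n - 1L
  p <- switch(tail,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  structure(list(t = tstat, df = df, p = p, d = mean(diff) / sdd,
                 tail = tail, meanDiff = mean(diff), n = n),
            class = "ttestResult")
}

#' @export
print.ttestResult <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (%s), d = %.3f\n",
              x$df, x$t, x$p, x$tail, x$d))
  invisible(x)
}

## Greenhouse-Geisser epsilon from the double-centered covariance matrix
.ggEpsilon <- function(data) {
  k <- ncol(data)
  S <- stats::cov(data)
  Sc <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  max(sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2)), 1 / (k - 1))
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Decomposes subjects x conditions data into condition, subject and error
#' sums of squares; reports F, partial eta squared
#' (SS_condition / (SS_condition + SS_error)) and the Greenhouse-Geisser
#' epsilon. Degrees of freedom are corrected by epsilon when sphericity is
#' in doubt (epsilon below `ggThreshold`, the automatic rule), always
#' (`"GG"`), or never (`"none"`).
#'
#' @param data numeric matrix or data.frame, subjects x conditions,
#'   complete (no missing cells).
#' @param correction `"auto"`, `"GG"` or `"none"`.
#' @param ggThreshold epsilon threshold below which the automatic rule
#'   applies the correction (default 0.75).
#' @return list of class `"anovaResult"` with `F`, `dfNum`, `dfDen`, `p`,
#'   `etaP2`, `ggEpsilon`, `corrected`.
#' @export
rmAnovaOneway <- function(data, correction = c("auto", "GG", "none"),
                          ggThreshold = 0.75) {
  correction <- match.arg(correction)
  data <- as.matrix(data)
  if (any(is.na(data))) stop("missing cells in subjects x conditions table")
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  grand <- mean(data)
  ssCond <- n * sum((colMeans(data) - grand)^2)
  ssSubj <- k * sum((rowMeans(data) - grand)^2)
  ssTot <- sum((data - grand)^2)
  ssErr <- ssTot - ssCond - ssSubj
  dfNum <- k - 1
  dfDen <- (k - 1) * (n - 1)
  msCond <- ssCond / dfNum
  msErr <- ssErr / dfDen
  Fval <- if (msErr <= 0) 0 else msCond / msErr
  eps <- .ggEpsilon(data)
  applyGG <- switch(correction, none = FALSE, GG = TRUE,
                    auto = eps < ggThreshold)
  if (applyGG) { dfNum <- dfNum * eps; dfDen <- dfDen * eps }
  p <- stats::pf(Fval, dfNum, dfDen, lower.tail = FALSE)
  structure(list(F = Fval, dfNum = dfNum, dfDen = dfDen, p = p,
                 etaP2 = if (ssCond + ssErr > 0) ssCond / (ssCond + ssErr)
                         else 0,
                 ggEpsilon = eps, corrected = applyGG),
            class = "anovaResult")
}

#' @export
print.anovaResult <- function(x, ...) {
  cat(sprintf("F(%.2f, %.2f) = %.3f, p = %.4g, eta_p^2 = %.3f%s\n",
              x$dfNum, x$dfDen, x$F, x$p, x$etaP2,
              if (x$corrected)
                sprintf(" (GG-corrected, eps = %.3f)", x$ggEpsilon) else ""))
  invisible(x)
}

#' Within-subject standard error of the mean (Cousineau-Morey)
#'
#' Removes each subject's mean (restoring the grand mean), applies the Morey
#' bias factor sqrt(C / (C - 1)), and returns the per-condition SEM of the
#' normalized data. Purely additive subject offsets therefore contribute
#' nothing.
#'
#' @param data numeric matrix, subjects x conditions, complete.
#' @return named numeric vector of per-condition SEMs.
#' @export
withinSubjectSem <- function(data) {
  data <- as.matrix(data)
  if (any(is.na(data))) stop("missing cells")
  n <- nrow(data); k <- ncol(data)
  if (k < 2L) {
    warning("single condition: returning the classical SEM")
    return(stats::setNames(apply(data, 2L, stats::sd) / sqrt(n),
                           colnames(data)))
  }
  norm <- data - rowMeans(data) + mean(data)
  morey <- sqrt(k / (k - 1))
  stats::setNames(apply(norm, 2L, stats::sd) / sqrt(n) * morey,
                  colnames(data))
}

#' Per-TR uncorrected significance tests against chance
#'
#' One paired t-test per TR against the chance level, flagging p < alpha
#' with no multiple-comparison correction (the per-TR significance lines
#' under decoding timecourses).
#'
#' @param timecourses numeric matrix, subjects x TRs.
#' @param chance chance accuracy.
#' @param tail passed to [pairedT()].
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `tr`, `t`, `p`, `significant`.
#' @export
perTrUncorrected <- function(timecourses, chance,
                             tail = c("two.sided", "greater", "less"),
                             alpha = 0.05) {
  tail <- match.arg(tail)
  timecourses <- as.matrix(timecourses)
  res <- lapply(seq_len(ncol(timecourses)), function(t) {
    tt <- pairedT(timecourses[, t], chance, tail)
    data.frame(tr = t, t = tt$t, p = tt$p, significant = tt$p < alpha)
  })
  do.call(rbind, res)
}

#' Mean ROI response timecourse across subjects
#'
#' Averages each subject's patterns over voxels and trials per TR, then
#' reports the group mean and the within-subject SEM per TR.
#'
#' @param datasets list of [PatternDataset-class] objects (one per subject)
#'   or a single dataset.
#' @return data.frame with columns `tr`, `mean`, `sem` (within-subject SEM
#'   across subjects; `NA` for a single subject).
#' @export
roiMeanTimecourse <- function(datasets) {
  if (methods::is(datasets, "PatternDataset")) datasets <- list(datasets)
  perSubj <- t(vapply(datasets, function(ds)
    apply(patterns(ds), 2L, mean), numeric(nTRs(datasets[[1L]]))))
  if (nrow(perSubj) >= 2L) {
    sem <- withinSubjectSem(perSubj)
  } else {
    sem <- rep(NA_real_, ncol(perSubj))
  }
  data.frame(tr = seq_len(ncol(perSubj)), mean = colMeans(perSubj),
             sem = as.numeric(sem))
}
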