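#' Generate a balanced trial design
#'
#' Builds the trial structure of the two search-task experiments. Experiment 1
#' has two relevance conditions (current, prospective) and 15 TRs per trial;
#' Experiment 2 has three (current, prospective, irrelevant) and 16 TRs.
#' Within every run each condition occurs equally often. Experiment 1 designs
#' are fully balanced within runs over condition x category; in Experiment 2
#' a run holds 4 trials per condition, so per-condition category counts within
#' a run are a rotation of (2, 1, 1) and only the totals across the whole
#' design are balanced (12 trials per condition x category for the canonical
#' 9-run, 12-trial design).
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param nRuns number of runs (default 8 for exp1, 9 for exp2).
#' @param trialsPerRun trials per run (default 12).
#' @param seed integer seed controlling trial order, exemplar assignment and
#'   target-presence balance.
#' @param nCategories number of target categories (default 3).
#' @param nExemplars number of exemplars per category (default 4).
#'
#' @return data.frame with columns `trial_id`, `run`, `condition`,
#'   `category`, `exemplar`, `target_present`, `n_trs`.
#'
#' @examples
#' d <- generateDesign("exp2", seed = 1)
#' nrow(d)                       # 108 trials
#' table(d$condition, d$category) # 12 per combination
#' @export
generateDesign <- function(experiment = c("exp1", "exp2"),
                           nRuns = NULL, trialsPerRun = 12L, seed = 1L,
                           nCategories = 3L, nExemplars = 4L) {
  experiment <- match.arg(experiment)
  conditions <- if (experiment == "exp1") c("current", "prospective")
                else c("current", "prospective", "irrelevant")
  if (is.null(nRuns)) nRuns <- if (experiment == "exp1") 8L else 9L
  nRuns <- as.integer(nRuns)
  trialsPerRun <- as.integer(trialsPerRun)
  nTrs <- if (experiment == "exp1") 15L else 16L
  nCond <- length(conditions)

  if (nRuns < 0L) stop("nRuns must be >= 0")
  if (nRuns == 0L) {
    return(data.frame(trial_id = integer(0), run = integer(0),
                      condition = character(0), category = integer(0),
                      exemplar = integer(0), target_present = logical(0),
                      n_trs = integer(0)))
  }
  if (trialsPerRun %% nCond != 0L)
    stop("infeasible balance: trialsPerRun (", trialsPerRun,
         ") must be divisible by the number of conditions (", nCond, ")")
  perCond <- trialsPerRun %/% nCond           # trials per condition per run
  extra <- perCond %% nCategories             # categories getting one extra
  if (extra != 0L && nRuns %% nCategories != 0L)
    stop("infeasible balance: with ", perCond, " trials per condition per ",
         "run, nRuns must be a multiple of ", nCategories,
         " to equalize condition x category totals")

  set.seed(as.integer(seed))
  rows <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    cond <- rep(conditions, each = perCond)
    cat <- integer(0)
    for (ci in seq_len(nCond)) {
      base <- rep(seq_len(nCategories), perCond %/% nCategories)
      if (extra > 0L) {
        # rotate which categories receive the surplus trial across runs,
        # offset per condition so conditions do not share a rotation phase
        extras <- ((r - 1L + ci - 1L + seq_len(extra) - 1L) %% nCategories) + 1L
        base <- c(base, extras)
      }
      cat <- c(cat, sort(base))
    }
    rows[[r]] <- data.frame(run = r, condition = cond, category = cat)
  }
  des <- do.call(rbind, rows)

  # Exemplars: within each condition x category cell, cycle through the
  # exemplar set in design order so totals are as equal as possible, then
  # a seeded shuffle of the starting phase decorrelates cells.
  des$exemplar <- NA_integer_
  for (cond in conditions) {
    for (k in seq_len(nCategories)) {
      idx <- which(des$condition == cond & des$category == k)
      phase <- sample.int(nExemplars, 1L)
      des$exemplar[idx] <-
        ((seq_along(idx) - 1L + phase - 1L) %% nExemplars) + 1L
    }
  }

  # Target presence: balanced within run (half present), seeded.
  des$target_present <- NA
  for (r in seq_len(nRuns)) {
    idx <- which(des$run == r)
    n <- length(idx)
    tp <- rep(c(TRUE, FALSE), length.out = n)
    des$target_present[idx] <- sample(tp)
  }

  # Shuffle trial order within run.
  ord <- unlist(lapply(seq_len(nRuns), function(r) {
    idx <- which(des$run == r)
    idx[sample.int(length(idx))]
  }))
  des <- des[ord, , drop = FALSE]
  des$trial_id <- seq_len(nrow(des))
  des$n_trs <- nTrs
  rownames(des) <- NULL
  des[, c("trial_id", "run", "condition", "category", "exemplar",
          "target_present", "n_trs")]
}

#' Check the balance invariants of a trial design
#'
#' @param design a design data.frame from [generateDesign()].
#' @param experiment `"exp1"` or `"exp2"`.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
checkDesignBalance <- function(design, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (nrow(design) == 0L) return(invisible(TRUE))
  tabRun <- table(design$run, design$condition)
  if (length(unique(c(tabRun))) != 1L)
    stop("unequal condition counts within some run")
  tot <- table(design$condition, design$category)
  if (length(unique(c(tot))) != 1L)
    stop("unequal condition x category totals across the design")
  if (experiment == "exp1") {
    percell <- table(design$run, design$condition, design$category)
    if (length(unique(c(percell))) != 1L)
      stop("exp1 requires equal condition x category counts within each run")
  } else {
    for (r in unique(design$run)) {
      for (cond in unique(design$condition)) {
        cnt <- table(factor(design$category[design$run == r &
                                              design$condition == cond],
                            levels = sort(unique(design$category))))
        if (!identical(sort(as.integer(cnt), decreasing = TRUE),
                       c(2L, 1L, 1L)))
          stop("exp2 run ", r, " condition ", cond,
               ": category counts are not a permutation of (2,1,1)")
      }
    }
  }
  invisible(TRUE)
}
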