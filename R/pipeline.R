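#' Build a pipeline configuration
#'
#' Bundles the experiment profile, simulation parameters, analysis intervals,
#' decoding schemes, statistics options and output location into one
#' validated list. Can also be loaded from YAML/JSON via [readConfig()].
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param nSubjects number of simulated subjects.
#' @param nVoxels voxels per simulated region of interest.
#' @param seed master seed; per-subject, per-stage sub-seeds are derived
#'   deterministically from it (no hidden global randomness).
#' @param intervals named list of TR index vectors (default
#'   [defaultIntervals()]).
#' @param schemes character vector of scheme names: `"within-<cond>"` or
#'   `"cross-<condA>-<condB>"`.
#' @param trs TR indices to decode (default: all; restricting to the
#'   interval TRs is much faster).
#' @param generator `"t"` (direct t-pattern path) or `"glm"` (BOLD + GLM).
#' @param noiseSd,ar1,exemplarJitterSd simulation noise settings (see
#'   [simParams()]).
#' @param outDir output directory for [runPipeline()] artifacts.
#' @param statsTail tail for the vs-chance tests of within schemes
#'   (one-tailed by default; cross schemes are always two-tailed).
#' @param pAdjust `"none"` (default, matching the uncorrected interval
#'   reporting) or `"holm"`: adjust the vs-chance p-values across intervals
#'   within each scheme.
#' @return list of class `"RunConfig"`.
#' @export
runConfig <- function(experiment = c("exp2", "exp1"), nSubjects = 24L,
                      nVoxels = 100L, seed = 1L, intervals = NULL,
                      schemes = NULL, trs = NULL,
                      generator = c("t", "glm"), noiseSd = 1, ar1 = 0.3,
                      exemplarJitterSd = 0.3, outDir = NULL,
                      statsTail = "greater",
                      pAdjust = c("none", "holm")) {
  pAdjust <- match.arg(pAdjust)
  experiment <- match.arg(experiment)
  generator <- match.arg(generator)
  if (is.null(intervals)) intervals <- defaultIntervals(experiment)
  if (is.null(schemes)) {
    schemes <- if (experiment == "exp1") {
      c("within-current", "within-prospective", "cross-current-prospective")
    } else {
      c("within-current", "within-prospective", "within-irrelevant",
        "cross-current-prospective", "cross-current-irrelevant",
        "cross-prospective-irrelevant")
    }
  }
  structure(list(experiment = experiment,
                 nRuns = if (experiment == "exp1") 8L else 9L,
                 trialsPerRun = 12L,
                 nTrs = if (experiment == "exp1") 15L else 16L,
                 conditions = if (experiment == "exp1")
                   c("current", "prospective")
                 else c("current", "prospective", "irrelevant"),
                 nSubjects = as.integer(nSubjects),
                 nVoxels = as.integer(nVoxels), seed = as.integer(seed),
                 intervals = intervals, schemes = schemes, trs = trs,
                 generator = generator, noiseSd = noiseSd, ar1 = ar1,
                 exemplarJitterSd = exemplarJitterSd, outDir = outDir,
                 statsTail = statsTail, pAdjust = pAdjust),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json` with fields matching
#'   the arguments of [runConfig()].
#' @return list of class `"RunConfig"`.
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$intervals))
    raw$intervals <- lapply(raw$intervals, as.integer)
  do.call(runConfig, raw)
}

.parseScheme <- function(name, conditions) {
  ok <- FALSE
  if (grepl("^within-", name)) {
    cond <- sub("^within-", "", name)
    ok <- cond %in% conditions
    if (ok) return(list(train = cond, test = cond))
  } else if (grepl("^cross-", name)) {
    parts <- strsplit(sub("^cross-", "", name), "-", fixed = TRUE)[[1L]]
    ok <- length(parts) == 2L && all(parts %in% conditions) &&
      parts[1L] != parts[2L]
    if (ok) return(list(train = parts[1L], test = parts[2L]))
  }
  NULL
}

#' Validate a pipeline configuration
#'
#' @param config list of class `"RunConfig"`.
#' @return character vector of violations (empty if the config is valid).
#' @export
validateConfig <- function(config) {
  v <- character(0)
  if (!inherits(config, "RunConfig")) return("not a RunConfig object")
  if (config$trialsPerRun %% length(config$conditions) != 0L)
    v <- c(v, sprintf("trialsPerRun (%d) not divisible by %d conditions",
                      config$trialsPerRun, length(config$conditions)))
  for (nm in names(config$intervals)) {
    idx <- config$intervals[[nm]]
    if (!length(idx) || any(idx < 1L) || any(idx > config$nTrs))
      v <- c(v, sprintf("interval '%s' has TR indices outside [1, %d]",
                        nm, config$nTrs))
    else if (!is.null(config$trs) && !all(idx %in% config$trs))
      v <- c(v, sprintf("interval '%s' includes TRs that are not decoded",
                        nm))
  }
  for (sn in config$schemes) {
    if (is.null(.parseScheme(sn, config$conditions)))
      v <- c(v, sprintf("unknown scheme name '%s'", sn))
  }
  if (config$nSubjects < 1L) v <- c(v, "nSubjects must be >= 1")
  if (config$nVoxels < 1L) v <- c(v, "nVoxels must be >= 1")
  if (!is.null(config$trs) &&
      (any(config$trs < 1L) || any(config$trs > config$nTrs)))
    v <- c(v, "trs outside the TR grid")
  v
}

## master seed -> reproducible per-subject sub-seeds (kept below 2^31)
.deriveSeeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the full simulate/decode/RSA/stats pipeline
#'
#' Simulates `nSubjects` datasets under the configured design and generator,
#' decodes every configured scheme at the configured TRs, averages over the
#' analysis intervals, runs the group statistics (vs-chance tests per scheme
#' and interval; one-way repeated-measures ANOVA across within-relevance
#' schemes per interval when three or more are configured), and computes
#' interval RDM contrasts for each cross pair. Re-running with the same
#' config reproduces every number exactly; if `outDir` is set, tidy CSV
#' tables and a JSON manifest are written there.
#'
#' @param config list of class `"RunConfig"` (see [runConfig()]).
#' @param verbose print progress to stderr.
#' @return list with `timecourses` (tidy data.frame: subject, scheme, tr,
#'   accuracy), `intervals` (subject, scheme, interval, accuracy), `stats`
#'   (per scheme x interval vs-chance tests), `anova` (per interval, if
#'   applicable), `rdmContrasts` (subject, pair, interval, same/diff means),
#'   `roiTimecourse`, and `chance`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  seeds <- .deriveSeeds(config$seed, config$nSubjects * 2L)
  subjSeeds <- seeds[seq_len(config$nSubjects)]
  bankSeeds <- seeds[config$nSubjects + seq_len(config$nSubjects)]
  chance <- 1 / 3
  schemeDefs <- lapply(config$schemes, .parseScheme,
                       conditions = config$conditions)
  names(schemeDefs) <- config$schemes

  tcRows <- list(); ivRows <- list(); rdmRows <- list()
  datasets <- vector("list", config$nSubjects)
  crossPairs <- unique(lapply(
    Filter(function(s) s$train != s$test, schemeDefs),
    function(s) sort(c(s$train, s$test))))

  for (si in seq_len(config$nSubjects)) {
    if (verbose) message("subject ", si, "/", config$nSubjects)
    sid <- sprintf("sim%02d", si)
    design <- generateDesign(config$experiment, config$nRuns,
                             config$trialsPerRun, seed = subjSeeds[si])
    params <- simParams(config$experiment, nVoxels = config$nVoxels,
                        noiseSd = config$noiseSd, ar1 = config$ar1,
                        exemplarJitterSd = config$exemplarJitterSd,
                        seed = subjSeeds[si], bankSeed = bankSeeds[si])
    ds <- if (config$generator == "t") {
      simulateTPatterns(design, params, subjectId = sid)
    } else {
      simulateBoldGlm(design, params, subjectId = sid)
    }
    datasets[[si]] <- ds
    if (si == 1L) chance <- chanceLevel(ds)
    cvWithin <-if (config$experiment == "exp1") "loro" else "balanced_loro"
    for (sn in config$schemes) {
      sd_ <- schemeDefs[[sn]]
      scheme <- decodingScheme(sd_$train, sd_$test,
                               cv = if (sd_$train == sd_$test) cvWithin
                                    else "train_all_cross", label = sn)
      tc <- decodeTimecourse(ds, scheme, trs = config$trs)
      acc <- accuracy(tc)
      tcRows[[length(tcRows) + 1L]] <-
        data.frame(subject = sid, scheme = sn, tr = tc@trs,
                   accuracy = acc[tc@trs], n_fits = tc@nFits)
      iv <- intervalAverage(tc, config$intervals)
      ivRows[[length(ivRows) + 1L]] <-
        data.frame(subject = sid, scheme = sn, interval = names(iv),
                   accuracy = as.numeric(iv))
    }
    for (pair in crossPairs) {
      for (nm in names(config$intervals)) {
        rdm <- computeRdm(ds, config$intervals[[nm]], conditions = pair)
        ct <- sameVsDiffContrast(rdm, pair, scale = "fisher")
        rdmRows[[length(rdmRows) + 1L]] <-
          data.frame(subject = sid, pair = paste(pair, collapse = "-"),
                     interval = nm, same = ct$sameCategoryMean,
                     diff = ct$diffCategoryMean,
                     difference = ct$difference)
      }
    }
  }
  tcTab <- do.call(rbind, tcRows)
  ivTab <- do.call(rbind, ivRows)
  rdmTab <- if (length(rdmRows)) do.call(rbind, rdmRows) else NULL

  # group statistics: vs-chance per scheme x interval
  statRows <- list()
  if (config$nSubjects >= 2L) {
    for (sn in config$schemes) {
      within <- schemeDefs[[sn]]$train == schemeDefs[[sn]]$test
      tailUse <- if (within) config$statsTail else "two.sided"
      for (nm in names(config$intervals)) {
        vals <- ivTab$accuracy[ivTab$scheme == sn & ivTab$interval == nm]
        tt <- pairedT(vals, chance, tail = tailUse)
        statRows[[length(statRows) + 1L]] <-
          data.frame(scheme = sn, interval = nm, mean = mean(vals),
                     t = tt$t, df = tt$df, p = tt$p, d = tt$d,
                     tail = tailUse)
      }
    }
  }
  statTab <- if (length(statRows)) do.call(rbind, statRows) else NULL
  if (!is.null(statTab) && identical(config$pAdjust, "holm")) {
    statTab$p_adj <- NA_real_
    for (sn in unique(statTab$scheme)) {
      i <- statTab$scheme == sn
      statTab$p_adj[i] <- stats::p.adjust(statTab$p[i], method = "holm")
    }
  }

  # one-way RM-ANOVA across within-relevance schemes per interval
  withinSchemes <- config$schemes[vapply(schemeDefs, function(s)
    s$train == s$test, logical(1))]
  anovaRows <- list()
  if (length(withinSchemes) >= 3L && config$nSubjects >= 2L) {
    for (nm in names(config$intervals)) {
      wide <- sapply(withinSchemes, function(sn)
        ivTab$accuracy[ivTab$scheme == sn & ivTab$interval == nm])
      a <- rmAnovaOneway(wide)
      anovaRows[[length(anovaRows) + 1L]] <-
        data.frame(interval = nm, F = a$F, dfNum = a$dfNum, dfDen = a$dfDen,
                   p = a$p, etaP2 = a$etaP2, ggEpsilon = a$ggEpsilon,
                   corrected = a$corrected)
    }
  }
  anovaTab <- if (length(anovaRows)) do.call(rbind, anovaRows) else NULL

  roi <- roiMeanTimecourse(datasets)

  out <- list(timecourses = tcTab, intervals = ivTab, stats = statTab,
              anova = anovaTab, rdmContrasts = rdmTab, roiTimecourse = roi,
              chance = chance, config = config)
  if (!is.null(config$outDir)) .writeReportBundle(out, config)
  out
}

.writeReportBundle <- function(result, config) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tab, name) {
    if (!is.null(tab))
      utils::write.csv(tab, file.path(config$outDir, name),
                       row.names = FALSE)
  }
  wr(result$timecourses, "decoding_timecourses.csv")
  wr(result$intervals, "interval_accuracies.csv")
  wr(result$stats, "stats_vs_chance.csv")
  wr(result$anova, "anova.csv")
  wr(result$rdmContrasts, "rdm_contrasts.csv")
  wr(result$roiTimecourse, "roi_timecourse.csv")
  cfg <- unclass(config)
  manifest <- list(
    package = "mvdecode",
    version = as.character(utils::packageVersion("mvdecode")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = cfg[setdiff(names(cfg), "outDir")],
    config_digest = sum(utf8ToInt(paste(
      vapply(cfg[order(names(cfg))], function(x)
        paste(format(x), collapse = ","), character(1)), collapse = ";"))))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
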