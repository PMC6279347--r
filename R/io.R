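#' Write a PatternDataset to plain-text files
#'
#' Persists the pattern array as a wide CSV (one row per trial x TR, one
#' column per voxel), the trial table as CSV, and a JSON sidecar with the
#' dimensions, chance level and provenance.
#'
#' @param dataset a [PatternDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePatternDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- patterns(dataset)
  d <- dim(p)
  flat <- matrix(aperm(p, c(2L, 1L, 3L)), nrow = d[1L] * d[2L],
                 ncol = d[3L])
  idx <- data.frame(trial = rep(seq_len(d[1L]), each = d[2L]),
                    tr = rep(seq_len(d[2L]), d[1L]))
  utils::write.csv(cbind(idx, as.data.frame(flat)),
                   file.path(dir, "patterns.csv"), row.names = FALSE)
  utils::write.csv(trialInfo(dataset), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  meta <- list(subject_id = subjectId(dataset),
               dims = list(trials = d[1L], trs = d[2L], voxels = d[3L]),
               chance_level = chanceLevel(dataset),
               provenance = dataset@provenance)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a PatternDataset written by [writePatternDataset()]
#'
#' @param dir directory holding `patterns.csv`, `trials.csv`, `meta.json`.
#' @return a [PatternDataset-class].
#' @export
readPatternDataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  flat <- utils::read.csv(file.path(dir, "patterns.csv"))
  ti <- utils::read.csv(file.path(dir, "trials.csv"))
  d <- c(meta$dims$trials, meta$dims$trs, meta$dims$voxels)
  vox <- as.matrix(flat[, -(1:2), drop = FALSE])
  p <- array(NA_real_, d)
  for (i in seq_len(nrow(vox)))
    p[flat$trial[i], flat$tr[i], ] <- vox[i, ]
  methods::new("PatternDataset", patterns = p, trialInfo = ti,
               subjectId = meta$subject_id, chanceLevel = meta$chance_level,
               provenance = as.list(meta$provenance))
}

#' Ingest per-TR t-maps from a NIfTI volume plus a trial table
#'
#' Optional ingest path for real data: a 4-D NIfTI file whose 4th dimension
#' enumerates trial x TR volumes in the row order of the accompanying TSV
#' trial table (columns `trial_id`, `run`, `condition`, `category`,
#' `exemplar`, `tr`), plus a 3-D mask selecting the region-of-interest
#' voxels. Requires the RNifti package.
#'
#' @param niftiFile path to the 4-D NIfTI t-map file.
#' @param trialTsv path to the TSV table described above.
#' @param maskFile path to a 3-D NIfTI mask (non-zero = in ROI).
#' @param subjectId identifier stored in the dataset.
#' @return a [PatternDataset-class].
#' @export
readNiftiPatterns <- function(niftiFile, trialTsv, maskFile,
                              subjectId = "ingest") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI ingest requires the RNifti package")
  vols <- RNifti::readNifti(niftiFile)
  mask <- RNifti::readNifti(maskFile)
  tab <- utils::read.delim(trialTsv)
  req <- c("trial_id", "run", "condition", "category", "exemplar", "tr")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  keep <- which(as.array(mask) != 0)
  nVol <- dim(vols)[4L]
  if (nVol != nrow(tab))
    stop("4th NIfTI dimension (", nVol, ") must match trial table rows (",
         nrow(tab), ")")
  trials <- sort(unique(tab$trial_id))
  trs <- sort(unique(tab$tr))
  p <- array(NA_real_, c(length(trials), length(trs), length(keep)))
  va <- as.array(vols)
  for (v in seq_len(nVol)) {
    vol <- va[, , , v]
    p[match(tab$trial_id[v], trials), match(tab$tr[v], trs), ] <- vol[keep]
  }
  ti <- unique(tab[, c("trial_id", "run", "condition", "category",
                       "exemplar")])
  ti <- ti[order(ti$trial_id), , drop = FALSE]
  ti$target_present <- NA
  ti$n_trs <- length(trs)
  rownames(ti) <- NULL
  if (any(is.na(p))) stop("incomplete trial x TR coverage in trial table")
  methods::new("PatternDataset", patterns = p, trialInfo = ti,
               subjectId = subjectId,
               chanceLevel = 1 / length(unique(ti$category)),
               provenance = list(generator = "readNiftiPatterns",
                                 nifti = niftiFile, mask = maskFile))
}
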