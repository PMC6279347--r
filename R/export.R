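#' Export an RDM as a labelled CSV matrix
#'
#' Row/column names combine category, exemplar and relevance
#' (`c<k>_e<j>_<relevance>`).
#'
#' @param rdm an [RDM-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeRdm <- function(rdm, path) {
  lab <- rdmLabels(rdm)
  nm <- sprintf("c%d_e%d_%s", lab$category, lab$exemplar, lab$relevance)
  d <- dissimilarity(rdm)
  dimnames(d) <- list(nm, nm)
  utils::write.csv(d, path, row.names = TRUE)
  invisible(path)
}

#' Export a generalization matrix as a CSV grid
#'
#' @param gm a [GeneralizationMatrix-class].
#' @param path output CSV path (rows = train TR, columns = test TR).
#' @return the path, invisibly.
#' @export
writeGeneralizationMatrix <- function(gm, path) {
  m <- accuracy(gm)
  rownames(m) <- paste0("train_tr", seq_len(nrow(m)))
  colnames(m) <- paste0("test_tr", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Export a cluster permutation result as CSV masks plus a JSON summary
#'
#' Writes `tmap.csv` (per-cell t statistics), `sigmask.csv` (significant
#' cluster membership) and `clusters.json` (per-cluster cells, mass,
#' p-value, tail) into a directory.
#'
#' @param res a [ClusterResult-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeClusterResult <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res@tMap, file.path(dir, "tmap.csv"), row.names = FALSE)
  utils::write.csv(res@sigMask, file.path(dir, "sigmask.csv"),
                   row.names = FALSE)
  summ <- list(
    tail = res@tail, alpha = res@alpha, cluster_alpha = res@clusterAlpha,
    n_perm = res@nPerm, exhaustive = res@exhaustive,
    clusters = lapply(res@clusters, function(cl)
      list(tail = cl$tail, mass = cl$mass, p = cl$p,
           significant = cl$significant,
           cells = apply(cl$cells, 1L, paste, collapse = ","))))
  jsonlite::write_json(summ, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
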