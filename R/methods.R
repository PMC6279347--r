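## Accessors and show methods for the S4 containers.

#' @describeIn PatternDataset pattern array accessor
#' @param x a PatternDataset
#' @export
setMethod("patterns", "PatternDataset", function(x) x@patterns)

#' @describeIn PatternDataset trial metadata accessor
#' @export
setMethod("trialInfo", "PatternDataset", function(x) x@trialInfo)

#' @describeIn PatternDataset number of TRs per trial
#' @export
setMethod("nTRs", "PatternDataset", function(x) dim(x@patterns)[2L])

#' @describeIn PatternDataset number of trials
#' @export
setMethod("nTrials", "PatternDataset", function(x) dim(x@patterns)[1L])

#' @describeIn PatternDataset number of voxels
#' @export
setMethod("nVoxels", "PatternDataset", function(x) dim(x@patterns)[3L])

#' @describeIn PatternDataset chance classification level
#' @export
setMethod("chanceLevel", "PatternDataset", function(x) x@chanceLevel)

#' @describeIn PatternDataset subject identifier
#' @export
setMethod("subjectId", "PatternDataset", function(x) x@subjectId)

setMethod("show", "PatternDataset", function(object) {
  d <- dim(object@patterns)
  cat("PatternDataset (subject ", object@subjectId, ")\n", sep = "")
  cat("  ", d[1L], " trials x ", d[2L], " TRs x ", d[3L], " voxels\n", sep = "")
  ti <- object@trialInfo
  if (nrow(ti)) {
    cat("  runs: ", length(unique(ti$run)),
        "; conditions: ", paste(sort(unique(as.character(ti$condition))),
                                collapse = ", "), "\n", sep = "")
    cat("  categories: ", length(unique(ti$category)),
        " (chance ", sprintf("%.2f%%", 100 * object@chanceLevel), ")\n",
        sep = "")
  }
  invisible(NULL)
})

#' @describeIn DecodingTimecourse subject identifier
#' @param x a DecodingTimecourse
#' @export
setMethod("subjectId", "DecodingTimecourse", function(x) x@subjectId)

#' @describeIn DecodingTimecourse per-TR accuracies (NA at TRs not computed)
#' @export
setMethod("accuracy", "DecodingTimecourse", function(x) x@accuracy)

setMethod("show", "DecodingTimecourse", function(object) {
  cat("DecodingTimecourse [", object@scheme@label, "] subject ",
      object@subjectId, "\n", sep = "")
  acc <- object@accuracy[object@trs]
  cat("  ", length(object@trs), " TRs computed; mean accuracy ",
      sprintf("%.3f", mean(acc)), "\n", sep = "")
  invisible(NULL)
})

#' @describeIn GeneralizationMatrix accuracy matrix (train TR x test TR)
#' @param x a GeneralizationMatrix
#' @export
setMethod("accuracy", "GeneralizationMatrix", function(x) x@accuracy)

#' @describeIn GeneralizationMatrix matrix side (number of TRs)
#' @export
setMethod("nTRs", "GeneralizationMatrix", function(x) nrow(x@accuracy))

#' @describeIn GeneralizationMatrix subject identifier
#' @export
setMethod("subjectId", "GeneralizationMatrix", function(x) x@subjectId)

setMethod("show", "GeneralizationMatrix", function(object) {
  cat("GeneralizationMatrix [", object@scheme@label, "] subject ",
      object@subjectId, ": ", nrow(object@accuracy), " x ",
      ncol(object@accuracy), " (train x test TR)\n", sep = "")
  invisible(NULL)
})

#' @describeIn RDM dissimilarity matrix accessor
#' @param x an RDM
#' @export
setMethod("dissimilarity", "RDM", function(x) x@d)

#' @describeIn RDM label table accessor
#' @export
setMethod("rdmLabels", "RDM", function(x) x@labels)

setMethod("show", "RDM", function(object) {
  cat("RDM (", nrow(object@d), " x ", ncol(object@d), "), scope ",
      object@scope, ", scale ", object@scale, "\n", sep = "")
  invisible(NULL)
})

#' @describeIn ClusterResult cluster list accessor
#' @param x a ClusterResult
#' @export
setMethod("clusters", "ClusterResult", function(x) x@clusters)

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@clusters), " cluster(s), tail ",
      object@tail, ", ", object@nPerm,
      if (object@exhaustive) " sign assignments (exhaustive)" else " permutations",
      "\n", sep = "")
  for (cl in object@clusters) {
    cat(sprintf("  %s cluster: %d cells, mass %.2f, p = %.4g\n",
                cl$tail, nrow(cl$cells), cl$mass, cl$p))
  }
  invisible(NULL)
})

setMethod("show", "DecodingScheme", function(object) {
  cat("DecodingScheme '", object@label, "': train ", object@trainCondition,
      ", test ", object@testCondition, ", cv ", object@cv, "\n", sep = "")
  invisible(NULL)
})
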