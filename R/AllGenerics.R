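#' Access the trial x TR x voxel pattern array
#' @param x a [PatternDataset-class]
#' @return numeric 3-d array
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))

#' Access the trial metadata table
#' @param x a [PatternDataset-class]
#' @return data.frame, one row per trial
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' Number of TRs per trial
#' @param x a [PatternDataset-class] or [GeneralizationMatrix-class]
#' @return integer scalar
#' @export
setGeneric("nTRs", function(x) standardGeneric("nTRs"))

#' Number of trials
#' @param x a [PatternDataset-class]
#' @return integer scalar
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of voxels
#' @param x a [PatternDataset-class]
#' @return integer scalar
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Chance classification level (1 / number of categories)
#' @param x a [PatternDataset-class]
#' @return numeric scalar
#' @export
setGeneric("chanceLevel", function(x) standardGeneric("chanceLevel"))

#' Subject identifier
#' @param x a dataset or result object
#' @return character scalar
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Accuracy values of a decoding result
#' @param x a [DecodingTimecourse-class] or [GeneralizationMatrix-class]
#' @return numeric vector (per TR) or matrix (train TR x test TR)
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' Dissimilarity matrix of an RDM
#' @param x an [RDM-class]
#' @return numeric square matrix
#' @export
setGeneric("dissimilarity", function(x) standardGeneric("dissimilarity"))

#' Condition/exemplar labels of an RDM
#' @param x an [RDM-class]
#' @return data.frame with columns category, exemplar, relevance
#' @export
setGeneric("rdmLabels", function(x) standardGeneric("rdmLabels"))

#' Clusters of a permutation test result
#' @param x a [ClusterResult-class]
#' @return list of clusters (cells, mass, p, tail)
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
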