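#' @include AllClasses.R
NULL

#' Transform data with a fitted projector
#'
#' @param model a fitted projector (`PcaProjector`, `LdaProjector`,
#'   `SrelmProjector`).
#' @param data a `GraspFeatureSet` or a numeric matrix (rows = windows) in the
#'   feature space the model was fitted on.
#' @return an object of the same kind as `data` with k projected columns
#'   Y1..Yk.
#' @export
setGeneric("projectData", function(model, data) standardGeneric("projectData"))

#' Feature matrix of a feature set
#'
#' @param x a `GraspFeatureSet`.
#' @return numeric matrix, windows x features.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Grasp labels of a feature set
#' @param x a `GraspFeatureSet`.
#' @return factor of per-window grasp labels.
#' @export
setGeneric("graspLabels", function(x) standardGeneric("graspLabels"))

#' Position labels of a feature set
#' @param x a `GraspFeatureSet`.
#' @return factor of per-window placement positions.
#' @export
setGeneric("positionLabels", function(x) standardGeneric("positionLabels"))

#' Subject labels of a feature set
#' @param x a `GraspFeatureSet`.
#' @return character vector of per-window subject ids.
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))

#' Fold assignment of a feature set
#' @param x a `GraspFeatureSet`.
#' @return integer vector of fold ids, or NULL if unassigned.
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))

#' Assign cross-validation folds
#' @param x a `GraspFeatureSet`.
#' @param value integer vector of fold ids (one per window).
#' @return `x` with the fold column set.
#' @export
setGeneric("foldIds<-", function(x, value) standardGeneric("foldIds<-"))
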