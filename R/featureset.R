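#' @include AllGenerics.R
NULL

#' Construct a GraspFeatureSet
#'
#' @param x numeric matrix of feature values, one row per analysis window.
#'   Column names become the feature names; unnamed columns are named F1..Fm.
#' @param grasp,position,subject per-window labels (recycled if scalar).
#' @param trial per-window trial ids.
#' @param window per-window window indices within the trial.
#' @param fold optional fold assignment.
#' @return a [GraspFeatureSet-class].
#' @examples
#' fs <- GraspFeatureSet(matrix(rnorm(20), 10, 2), grasp = rep(c("a", "b"), 5),
#'                       position = "P1", subject = "S01",
#'                       trial = 1L, window = 1:10)
#' featureMatrix(fs)
#' @export
GraspFeatureSet <- function(x, grasp, position, subject,
                            trial = 1L, window = seq_len(nrow(x)),
                            fold = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  n <- nrow(x)
  cd <- DataFrame(
    grasp = as.character(rep_len(grasp, n)),
    position = as.character(rep_len(position, n)),
    subject = as.character(rep_len(subject, n)),
    trial = as.integer(rep_len(trial, n)),
    window = as.integer(rep_len(window, n))
  )
  if (!is.null(fold)) cd$fold <- as.integer(rep_len(fold, n))
  a <- t(x)
  colnames(a) <- sprintf("w%06d", seq_len(n))
  se <- SummarizedExperiment(assays = list(features = a), colData = cd)
  methods::new("GraspFeatureSet", se)
}

#' @describeIn GraspFeatureSet windows-by-features matrix
#' @export
setMethod("featureMatrix", "GraspFeatureSet", function(x) t(assay(x)))

#' @describeIn GraspFeatureSet per-window grasp factor
#' @export
setMethod("graspLabels", "GraspFeatureSet", function(x) factor(colData(x)$grasp))

#' @describeIn GraspFeatureSet per-window position factor
#' @export
setMethod("positionLabels", "GraspFeatureSet", function(x) factor(colData(x)$position))

#' @describeIn GraspFeatureSet per-window subject ids
#' @export
setMethod("subjectLabels", "GraspFeatureSet", function(x) colData(x)$subject)

#' @describeIn GraspFeatureSet fold ids (NULL if never assigned)
#' @export
setMethod("foldIds", "GraspFeatureSet", function(x) colData(x)$fold)

#' @describeIn GraspFeatureSet set fold ids
#' @export
setMethod("foldIds<-", "GraspFeatureSet", function(x, value) {
  stopifnot(length(value) == ncol(x))
  colData(x)$fold <- as.integer(value)
  x
})

## replace the feature block, keeping labels: used by normalization/projection
setFeatureMatrix <- function(fs, x, featureNames = colnames(x)) {
  x <- as.matrix(x)
  if (is.null(featureNames)) featureNames <- paste0("F", seq_len(ncol(x)))
  a <- t(x)
  rownames(a) <- featureNames
  colnames(a) <- colnames(assay(fs))
  se <- SummarizedExperiment(assays = list(features = a), colData = colData(fs))
  methods::new("GraspFeatureSet", se)
}

#' Subset a feature set by window index
#'
#' @param fs a `GraspFeatureSet`.
#' @param idx integer or logical index over windows (columns).
#' @return the subsetted `GraspFeatureSet`.
#' @export
subsetWindows <- function(fs, idx) {
  fs[, idx]
}

#' Bind two feature sets over the same feature space
#'
#' @param a,b `GraspFeatureSet` objects with identical feature names.
#' @return the row-concatenated `GraspFeatureSet` (windows of `a` first).
#' @export
bindWindows <- function(a, b) {
  stopifnot(identical(rownames(a), rownames(b)))
  cda <- colData(a)[, c("grasp", "position", "subject", "trial", "window")]
  cdb <- colData(b)[, c("grasp", "position", "subject", "trial", "window")]
  m <- cbind(assay(a), assay(b))
  colnames(m) <- sprintf("w%06d", seq_len(ncol(m)))
  cd <- rbind(cda, cdb)
  rownames(cd) <- colnames(m)
  se <- SummarizedExperiment(assays = list(features = m), colData = cd)
  methods::new("GraspFeatureSet", se)
}

#' Write / read a feature set as CSV
#'
#' The delimited-text interchange format: one row per window, the named
#' feature columns first, then the label columns `grasp`, `position`,
#' `subject`, `trial`, `window` (and `fold` when assigned).
#'
#' @param fs a `GraspFeatureSet`.
#' @param path CSV file path.
#' @return `writeFeatureCsv` returns `path` invisibly; `readFeatureCsv`
#'   returns the reconstructed `GraspFeatureSet`.
#' @export
writeFeatureCsv <- function(fs, path) {
  df <- as.data.frame(featureMatrix(fs))
  cd <- as.data.frame(colData(fs))
  out <- cbind(df, cd)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @export
readFeatureCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  labelCols <- intersect(c("grasp", "position", "subject", "trial", "window", "fold"),
                         colnames(df))
  x <- as.matrix(df[, setdiff(colnames(df), labelCols), drop = FALSE])
  GraspFeatureSet(x,
    grasp = df$grasp, position = df$position, subject = df$subject,
    trial = df$trial, window = df$window,
    fold = if ("fold" %in% labelCols) df$fold else NULL)
}
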