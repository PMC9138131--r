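#' @include emgrasp-package.R
NULL

#' Single-trial grasp recording
#'
#' Container for one trial of a grasp experiment: six surface-EMG channels
#' sampled at `emgRate` Hz and six IMU channels (3-axis accelerometer in g,
#' 3-axis gyroscope in deg/s) sampled at `imuRate` Hz, with the trial labels.
#'
#' @slot emg numeric matrix, 6 x (duration * emgRate), rows EMG1..EMG6.
#' @slot imu numeric matrix, 6 x (duration * imuRate), rows ACCX..GYRZ.
#' @slot emgRate,imuRate sampling rates in Hz.
#' @slot subject subject identifier.
#' @slot grasp grasp-class label.
#' @slot position placement-position label (P1..P9).
#' @slot rep repetition number.
#' @slot trialId integer trial counter, unique within a dataset.
#'
#' @exportClass GraspRecording
setClass("GraspRecording",
  representation(
    emg = "matrix", imu = "matrix",
    emgRate = "numeric", imuRate = "numeric",
    subject = "character", grasp = "character", position = "character",
    rep = "integer", trialId = "integer"
  )
)

setValidity("GraspRecording", function(object) {
  msg <- character()
  if (nrow(object@emg) != 6L) msg <- c(msg, "emg must have exactly 6 channel rows")
  if (nrow(object@imu) != 6L) msg <- c(msg, "imu must have exactly 6 channel rows")
  if (anyNA(object@emg) || anyNA(object@imu)) msg <- c(msg, "missing samples are not allowed")
  if (length(object@emgRate) != 1L || object@emgRate <= 0) msg <- c(msg, "emgRate must be a positive scalar")
  if (length(object@imuRate) != 1L || object@imuRate <= 0) msg <- c(msg, "imuRate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' @describeIn GraspRecording compact display
#' @param object a `GraspRecording`
#' @export
setMethod("show", "GraspRecording", function(object) {
  cat("GraspRecording:", object@subject, "/", object@grasp, "/",
      object@position, "/ rep", object@rep, "\n")
  cat(sprintf("  emg: 6 x %d @ %g Hz | imu: 6 x %d @ %g Hz\n",
              ncol(object@emg), object@emgRate, ncol(object@imu), object@imuRate))
})

#' Labeled feature dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one feature
#' vector per analysis window: the assay is features x windows, and `colData`
#' carries the window labels `grasp`, `position`, `subject`, `trial`, `window`
#' and (optionally) `fold`. Before projection the feature space is the
#' documented 66-dimensional time-domain set; after projection it is Y1..Yk.
#'
#' @exportClass GraspFeatureSet
setClass("GraspFeatureSet", contains = "SummarizedExperiment")

setValidity("GraspFeatureSet", function(object) {
  need <- c("grasp", "position", "subject", "trial", "window")
  missing <- setdiff(need, colnames(colData(object)))
  if (length(missing)) {
    return(paste("colData lacks label column(s):", paste(missing, collapse = ", ")))
  }
  if (is.null(rownames(object))) return("feature rows must be named")
  TRUE
})

#' @describeIn GraspFeatureSet compact display
#' @param object a `GraspFeatureSet`
#' @export
setMethod("show", "GraspFeatureSet", function(object) {
  cat(sprintf("GraspFeatureSet: %d windows x %d features\n",
              ncol(object), nrow(object)))
  cat("  grasps:", paste(levels(factor(colData(object)$grasp)), collapse = ", "), "\n")
  cat("  positions:", paste(levels(factor(colData(object)$position)), collapse = ", "), "\n")
  cat("  subjects:", paste(unique(colData(object)$subject), collapse = ", "), "\n")
})

#' Min-max feature normalizer
#'
#' Per-feature training minimum and maximum defining the affine map
#' x -> 2 (x - min) / (max - min) - 1 onto \[-1, 1\] (training data attains the
#' bounds; test data may fall outside, no clipping). Constant features
#' (max == min) map to 0.
#'
#' @slot min,max named numeric vectors of per-feature training extrema.
#'
#' @exportClass FeatureNormalizer
setClass("FeatureNormalizer",
  representation(min = "numeric", max = "numeric")
)

setValidity("FeatureNormalizer", function(object) {
  if (length(object@min) != length(object@max)) return("min and max lengths differ")
  if (any(object@max < object@min)) return("max must be >= min per feature")
  TRUE
})

#' Fitted PCA projector
#'
#' Linear projection onto the k eigenvectors of the training covariance with
#' the largest eigenvalues; data are centered with the training feature mean
#' before projection.
#'
#' @slot rotation m x k matrix of orthonormal eigenvector columns.
#' @slot center training feature mean (length m).
#' @slot eigenvalues all m covariance eigenvalues, descending.
#' @slot k output dimension.
#'
#' @exportClass PcaProjector
setClass("PcaProjector",
  representation(rotation = "matrix", center = "numeric",
                 eigenvalues = "numeric", k = "integer")
)

setValidity("PcaProjector", function(object) {
  G <- crossprod(object@rotation)
  if (max(abs(G - diag(ncol(object@rotation)))) > 1e-6) {
    return("rotation columns must be orthonormal")
  }
  ev <- object@eigenvalues
  if (any(ev < -1e-8 * max(abs(ev), 1))) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE)) return("eigenvalues must be sorted descending")
  TRUE
})

#' Fitted LDA projector
#'
#' Fisher discriminant projection: columns of `rotation` are the eigenvectors
#' of solve(Sw) %*% Sb with the k largest eigenvalues (k <= c - 1 for c
#' classes). Scatter matrices follow the unnormalized sum-of-outer-products
#' definition.
#'
#' @slot rotation m x k projection matrix (unit-norm columns).
#' @slot Sw,Sb within- and between-class scatter matrices (m x m).
#' @slot classMeans c x m matrix of class means.
#' @slot grandMean overall feature mean.
#' @slot counts per-class row counts.
#' @slot k output dimension.
#'
#' @exportClass LdaProjector
setClass("LdaProjector",
  representation(rotation = "matrix", Sw = "matrix", Sb = "matrix",
                 classMeans = "matrix", grandMean = "numeric",
                 counts = "integer", k = "integer")
)

setValidity("LdaProjector", function(object) {
  if (max(abs(object@Sw - t(object@Sw))) > 1e-6) return("Sw must be symmetric")
  if (max(abs(object@Sb - t(object@Sb))) > 1e-6) return("Sb must be symmetric")
  if (object@k > nrow(object@classMeans) - 1L) return("k must be <= number of classes - 1")
  TRUE
})

#' Fitted SRELM projector
#'
#' Spectral-regression extreme learning machine: a random single-hidden-layer
#' feature map h(x) = g(a_i . x + b_i), i = 1..L with g(d) = 1 / (1 + e^d),
#' followed by output weights U solving the ridge least-squares problem
#' H U ~ Z, where Z holds c - 1 orthonormalized class-indicator response
#' columns. The hidden parameters drawn at fit time are persisted and reused
#' verbatim when transforming new data.
#'
#' @slot a m x L matrix of hidden-node input weights.
#' @slot b length-L hidden-node biases.
#' @slot U L x (c - 1) output-weight matrix.
#' @slot Z n x (c - 1) orthonormal response matrix (training only).
#' @slot L hidden-node count.
#' @slot alpha ridge parameter.
#' @slot seed RNG seed used to draw (a, b).
#' @slot classLevels grasp labels seen at fit time.
#'
#' @exportClass SrelmProjector
setClass("SrelmProjector",
  representation(a = "matrix", b = "numeric", U = "matrix", Z = "matrix",
                 L = "integer", alpha = "numeric", seed = "integer",
                 classLevels = "character")
)

setValidity("SrelmProjector", function(object) {
  if (ncol(object@a) != object@L) return("a must have L columns")
  if (length(object@b) != object@L) return("b must have L entries")
  if (nrow(object@U) != object@L) return("U must have L rows")
  if (ncol(object@U) != length(object@classLevels) - 1L) {
    return("U must have c - 1 columns")
  }
  G <- crossprod(object@Z)
  if (max(abs(G - diag(ncol(object@Z)))) > 1e-8) {
    return("Z columns must be orthonormal")
  }
  TRUE
})

#' t-SNE embedding
#'
#' Result of a (transductive) t-SNE run: low-dimensional coordinates for every
#' input row, the high-dimensional joint probabilities, per-point Gaussian
#' bandwidths calibrated to the target perplexity, and the final and initial
#' Kullback-Leibler costs. There is no out-of-sample mapping; new points
#' require a new joint embedding.
#'
#' @slot Y n x k embedded coordinates.
#' @slot P n x n symmetric joint-probability matrix (sums to 1).
#' @slot sigmas per-point Gaussian bandwidths.
#' @slot perplexity target perplexity.
#' @slot cost final KL divergence.
#' @slot costInitial KL divergence at the random initialization.
#' @slot params optimizer settings (iterations, learning rate, momentum
#'   schedule, early-exaggeration factor and duration).
#' @slot seed RNG seed for the initialization.
#'
#' @exportClass TsneEmbedding
setClass("TsneEmbedding",
  representation(Y = "matrix", P = "matrix", sigmas = "numeric",
                 perplexity = "numeric", cost = "numeric",
                 costInitial = "numeric", params = "list", seed = "integer")
)

setValidity("TsneEmbedding", function(object) {
  if (nrow(object@Y) != nrow(object@P)) return("Y and P row counts differ")
  if (abs(sum(object@P) - 1) > 1e-6) return("joint probabilities must sum to 1")
  if (object@cost < -1e-12) return("KL cost must be non-negative")
  TRUE
})

#' @describeIn TsneEmbedding compact display
#' @param object a `TsneEmbedding`
#' @export
setMethod("show", "TsneEmbedding", function(object) {
  cat(sprintf("TsneEmbedding: %d points -> %d dims | perplexity %g | KL %.4f (init %.4f)\n",
              nrow(object@Y), ncol(object@Y), object@perplexity,
              object@cost, object@costInitial))
})
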