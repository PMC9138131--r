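#' @include classification.R
NULL

.ridgeInv <- function(S) {
  k <- nrow(S)
  solve(S + diag(1e-9 * sum(diag(S)) / k + 1e-300, k))
}

.classStats <- function(x, y) {
  lv <- levels(y)
  list(
    levels = lv,
    means = t(vapply(lv, function(l) colMeans(x[y == l, , drop = FALSE]),
                     numeric(ncol(x)))),
    covs = lapply(lv, function(l) stats::cov(x[y == l, , drop = FALSE]))
  )
}

#' Separability index (SI)
#'
#' Average over classes of the minimum half modified Mahalanobis distance to
#' any other class:
#' SI = (1/c) sum_i min_{j != i} 0.5 sqrt((mu_i - mu_j)' S^-1 (mu_i - mu_j)),
#' with S = (S_i + S_j) / 2 the pairwise averaged class covariance. Larger SI
#' means better-separated grasp clusters; SI is invariant under invertible
#' affine maps of the whole feature space. Near-singular S gets a tiny ridge
#' (1e-9 trace/k) before inversion.
#'
#' @param data a `GraspFeatureSet` (typically projected features) or numeric
#'   matrix with `labels`.
#' @param labels class labels when `data` is a bare matrix.
#' @return non-negative real.
#' @export
separabilityIndex <- function(data, labels = NULL) {
  x <- .asMatrix(data)
  y <- .labelsOf(data, labels)
  if (nlevels(y) < 2) stop("SI needs at least two classes")
  st <- .classStats(x, y)
  c <- nlevels(y)
  half <- function(i, j) {
    d <- st$means[i, ] - st$means[j, ]
    S <- (st$covs[[i]] + st$covs[[j]]) / 2
    0.5 * sqrt(max(0, drop(t(d) %*% .ridgeInv(S) %*% d)))
  }
  mean(vapply(seq_len(c), function(i) {
    min(vapply(setdiff(seq_len(c), i), function(j) half(i, j), numeric(1)))
  }, numeric(1)))
}

#' Mean semi-principal axis (MSA)
#'
#' Cluster-compactness statistic: for each class, the semi-principal axes of
#' its covariance ellipsoid are the square roots of the k largest covariance
#' eigenvalues; MSA is the geometric mean of those axes, averaged over
#' classes. Smaller MSA means more compact grasp clusters; scaling all
#' features by a factor scales MSA by the same factor.
#'
#' @param data a `GraspFeatureSet` (projected features) or matrix with
#'   `labels`.
#' @param labels class labels when `data` is a bare matrix.
#' @param k number of leading eigenvalues (default: the feature dimension).
#' @return non-negative real.
#' @export
meanSemiPrincipalAxis <- function(data, labels = NULL, k = NULL) {
  x <- .asMatrix(data)
  y <- .labelsOf(data, labels)
  if (is.null(k)) k <- ncol(x)
  st <- .classStats(x, y)
  mean(vapply(seq_len(nlevels(y)), function(i) {
    ev <- sort(eigen(st$covs[[i]], symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)[seq_len(k)]
    if (any(ev < -1e-8 * max(abs(ev), 1))) stop("negative covariance eigenvalue")
    a <- sqrt(pmax(ev, 0))
    if (any(a == 0)) 0 else exp(mean(log(a)))   # geometric mean (prod a)^(1/k)
  }, numeric(1)))
}

#' Repeatability index (RI)
#'
#' Train/test consistency statistic: the half Mahalanobis distance between the
#' training and testing mean of each class under the training covariance,
#' averaged over classes:
#' RI = (1/c) sum_i 0.5 sqrt((mu_Tr,i - mu_Ts,i)' S_Tr,i^-1 (mu_Tr,i - mu_Ts,i)).
#' RI is exactly 0 when test equals train; small RI means features reproduce
#' across the train/test divide (e.g. from training positions to unseen
#' positions).
#'
#' @param train,test `GraspFeatureSet` objects (projected features) or
#'   matrices with labels.
#' @param trainLabels,testLabels class labels for bare matrices.
#' @return non-negative real.
#' @export
repeatabilityIndex <- function(train, test, trainLabels = NULL, testLabels = NULL) {
  xTr <- .asMatrix(train); yTr <- .labelsOf(train, trainLabels)
  xTs <- .asMatrix(test); yTs <- .labelsOf(test, testLabels)
  lv <- levels(yTr)
  if (!all(lv %in% levels(yTs)) || !all(levels(yTs) %in% lv)) {
    stop("train and test must contain the same classes")
  }
  mean(vapply(lv, function(l) {
    a <- xTr[yTr == l, , drop = FALSE]
    b <- xTs[yTs == l, , drop = FALSE]
    d <- colMeans(a) - colMeans(b)
    0.5 * sqrt(max(0, drop(t(d) %*% .ridgeInv(stats::cov(a)) %*% d)))
  }, numeric(1)))
}

#' Percent classification error
#'
#' @param true,predicted equal-length label vectors.
#' @return 100 * (# mismatches) / n.
#' @examples
#' classificationError(c("a", "b", "a", "a"), c("a", "b", "b", "a"))  # 25
#' @export
classificationError <- function(true, predicted) {
  if (length(true) != length(predicted)) stop("label vectors differ in length")
  100 * mean(as.character(true) != as.character(predicted))
}

#' Cluster-metrics report for a projected dataset
#'
#' Convenience wrapper computing SI and MSA on `data` and, when `test` is
#' given, RI between the two.
#'
#' @param data projected training `GraspFeatureSet`.
#' @param test optional projected testing `GraspFeatureSet`.
#' @return data.frame with columns SI, MSA and (optionally) RI.
#' @export
clusterMetricsReport <- function(data, test = NULL) {
  out <- data.frame(SI = separabilityIndex(data),
                    MSA = meanSemiPrincipalAxis(data))
  if (!is.null(test)) out$RI <- repeatabilityIndex(data, test)
  out
}

#' Scatter-plot export of the first two projected components
#'
#' Plain plotting-ready CSV: Y1, Y2, grasp, position per window, mirroring the
#' grasp-colored, position-marked scatter diagnostics of the study.
#'
#' @param fs projected `GraspFeatureSet` (at least two feature rows).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportScatterCsv <- function(fs, path) {
  x <- featureMatrix(fs)
  df <- data.frame(Y1 = x[, 1], Y2 = x[, 2],
                   grasp = as.character(graspLabels(fs)),
                   position = as.character(positionLabels(fs)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
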