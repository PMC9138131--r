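#' @include projection.R
NULL

#' Classifier specification
#'
#' The seven classifiers evaluated on projected features, with the study's
#' operating points: LDA and naive Bayes (no tunables), KNN with k = 3
#' (grid 1..7), SVM with linear (`svml`), radial-basis (`svmb`) and
#' polynomial (`svmp`) kernels at cost = 1, gamma = 1 (grid 0.5..6 by 0.5;
#' polynomial degree fixed at 3, coef0 = 0), and a 4-14-5 feed-forward neural
#' network with a tan-sigmoid hidden layer and linear outputs (hidden size
#' from grid 1..50), trained by full-batch gradient descent with momentum.
#'
#' @param kind one of "lda", "nb", "knn", "svml", "svmb", "svmp", "nn".
#' @param k KNN neighbor count.
#' @param cost,gamma,degree SVM hyperparameters.
#' @param hidden NN hidden-layer size.
#' @param epochs,lr,momentum NN training schedule (full-batch gradient
#'   descent, mean-squared error on one-hot targets).
#' @param seed seed for the NN weight initialization.
#' @return a classed list describing the classifier.
#' @export
classifierSpec <- function(kind = c("lda", "nb", "knn", "svml", "svmb", "svmp", "nn"),
                           k = 3L, cost = 1, gamma = 1, degree = 3L,
                           hidden = 14L, epochs = 500L, lr = 0.01,
                           momentum = 0.9, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), cost = cost, gamma = gamma,
                 degree = as.integer(degree), hidden = as.integer(hidden),
                 epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 seed = as.integer(seed)),
            class = "ClassifierSpec")
}

.labelsOf <- function(data, labels) {
  factor(if (is.null(labels)) graspLabels(data) else labels)
}

## Gaussian naive Bayes in log space. Projected grasp clusters can be
## extremely tight (per-feature sd of order 1e-3), where density products
## underflow; summing log densities with a variance floor stays stable.
.nbTrain <- function(x, y) {
  lv <- levels(y)
  floorVar <- 1e-12 * mean(apply(x, 2, var))
  list(levels = lv,
       prior = as.numeric(table(y)) / length(y),
       mu = t(vapply(lv, function(l) colMeans(x[y == l, , drop = FALSE]),
                     numeric(ncol(x)))),
       v = t(vapply(lv, function(l) {
         pmax(apply(x[y == l, , drop = FALSE], 2, var), floorVar, 1e-300)
       }, numeric(ncol(x)))))
}

.nbPredict <- function(fit, x) {
  ll <- vapply(seq_along(fit$levels), function(j) {
    log(fit$prior[j]) + colSums(stats::dnorm(t(x), fit$mu[j, ],
                                             sqrt(fit$v[j, ]), log = TRUE))
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x))
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

## KNN with the deterministic tie-break: majority vote among the k nearest
## neighbors; vote ties go to the candidate class with the smallest mean
## neighbor distance
.knnPredict <- function(trainX, trainY, testX, k) {
  lv <- levels(trainY)
  pred <- character(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- sqrt(colSums((t(trainX) - testX[i, ])^2))
    nn <- order(d)[seq_len(k)]
    tab <- table(trainY[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      meanD <- vapply(top, function(cl) mean(d[nn][trainY[nn] == cl]), numeric(1))
      top <- top[which.min(meanD)]
    }
    pred[i] <- top
  }
  factor(pred, levels = lv)
}

## 4-14-5 network: tanh hidden layer, linear outputs, full-batch gradient
## descent with momentum on the mean squared error against one-hot targets.
## Inputs are z-scored with training statistics so one learning rate works
## across projection methods whose output scales differ by orders of magnitude.
.nnTrain <- function(x, y, spec) {
  set.seed(spec$seed)
  lv <- levels(y)
  n <- nrow(x); p <- ncol(x); h <- spec$hidden; c <- length(lv)
  mu <- colMeans(x); sg <- apply(x, 2, sd); sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  T <- diag(c)[as.integer(y), , drop = FALSE]
  W1 <- matrix(runif(p * h, -0.5, 0.5), p, h); b1 <- runif(h, -0.5, 0.5)
  W2 <- matrix(runif(h * c, -0.5, 0.5), h, c); b2 <- runif(c, -0.5, 0.5)
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  for (e in seq_len(spec$epochs)) {
    H <- tanh(sweep(xs %*% W1, 2, b1, "+"))
    O <- sweep(H %*% W2, 2, b2, "+")
    dO <- 2 * (O - T) / n
    gW2 <- crossprod(H, dO); gb2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * (1 - H^2)
    gW1 <- crossprod(xs, dH); gb1 <- colSums(dH)
    vW2 <- spec$momentum * vW2 - spec$lr * gW2; W2 <- W2 + vW2
    vb2 <- spec$momentum * vb2 - spec$lr * gb2; b2 <- b2 + vb2
    vW1 <- spec$momentum * vW1 - spec$lr * gW1; W1 <- W1 + vW1
    vb1 <- spec$momentum * vb1 - spec$lr * gb1; b1 <- b1 + vb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sg = sg, levels = lv)
}

.nnPredict <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$mu), 2, fit$sg, "/")
  H <- tanh(sweep(xs %*% fit$W1, 2, fit$b1, "+"))
  O <- sweep(H %*% fit$W2, 2, fit$b2, "+")
  factor(fit$levels[max.col(O, ties.method = "first")], levels = fit$levels)
}

#' Train one of the seven classifiers
#'
#' @param spec a [classifierSpec()].
#' @param train a `GraspFeatureSet` (typically 4-D projected features) or a
#'   numeric matrix with `labels`.
#' @param labels class labels when `train` is a bare matrix.
#' @return an opaque fitted-classifier object for [predictClassifier()].
#' @export
trainClassifier <- function(spec, train, labels = NULL) {
  x <- .asMatrix(train)
  y <- .labelsOf(train, labels)
  if (nlevels(y) < 2) stop("training data must contain at least two classes")
  fit <- switch(spec$kind,
    lda = MASS::lda(x, grouping = y),
    nb = .nbTrain(x, y),
    knn = list(x = x, y = y, k = spec$k),
    svml = e1071::svm(x, y, kernel = "linear", cost = spec$cost, scale = TRUE),
    svmb = e1071::svm(x, y, kernel = "radial", cost = spec$cost,
                      gamma = spec$gamma, scale = TRUE),
    svmp = e1071::svm(x, y, kernel = "polynomial", cost = spec$cost,
                      gamma = spec$gamma, degree = spec$degree, coef0 = 0,
                      scale = TRUE),
    nn = {
      if (ncol(x) != 4L) stop("the neural network expects 4-D projected inputs")
      .nnTrain(x, y, spec)
    })
  structure(list(kind = spec$kind, fit = fit, levels = levels(y)),
            class = "GraspClassifier")
}

#' Predict grasp labels with a trained classifier
#'
#' @param model object from [trainClassifier()].
#' @param test a `GraspFeatureSet` or numeric matrix.
#' @return factor of predicted grasp labels.
#' @export
predictClassifier <- function(model, test) {
  x <- .asMatrix(test)
  pred <- switch(model$kind,
    lda = predict(model$fit, x)$class,
    nb = .nbPredict(model$fit, x),
    knn = .knnPredict(model$fit$x, model$fit$y, x, model$fit$k),
    svml = , svmb = , svmp = predict(model$fit, x),
    nn = .nnPredict(model$fit, x))
  factor(as.character(pred), levels = model$levels)
}

#' Seeded five-fold partition
#'
#' Randomly partitions `n` rows into `nFolds` folds whose sizes differ by at
#' most one. Within one subject, rows from all positions are pooled and
#' shuffled before splitting.
#'
#' @param n row count (or a `GraspFeatureSet`).
#' @param nFolds fold count.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..nFolds.
#' @export
makeFolds <- function(n, nFolds = 5L, seed = 1L) {
  if (methods::is(n, "GraspFeatureSet")) n <- ncol(n)
  n <- as.integer(n)
  if (n < nFolds) stop("need at least one row per fold")
  set.seed(as.integer(seed))
  ids <- rep_len(seq_len(nFolds), n)
  ids[order(runif(n))]
}

#' Cross-validated classification error
#'
#' For each fold: fit the min-max normalizer on the training rows, normalize
#' both portions, fit the projection on the (normalized) training rows,
#' project both, train the classifier, and score the held-out rows. The fold
#' errors (percent misclassified) are averaged. t-SNE is the exception by
#' design: it has no out-of-sample mapping, so the whole dataset is normalized
#' and embedded once (labels withheld) and folds only control which rows train
#' the classifier.
#'
#' @param spec a [classifierSpec()].
#' @param data an unnormalized `GraspFeatureSet` over the 66-D feature space
#'   (or any feature space when `projection = "none"`).
#' @param folds integer fold ids from [makeFolds()].
#' @param projection "none", "pca", "lda", "srelm" or "tsne".
#' @param k projected dimension.
#' @param projParams parameter list forwarded to the projection fit.
#' @return list with `error` (mean percent error), `foldErrors`, and
#'   `confusion` (summed over folds).
#' @export
crossValidate <- function(spec, data, folds, projection = "none", k = 4L,
                          projParams = list()) {
  stopifnot(length(folds) == ncol(data))
  y <- graspLabels(data)
  lv <- levels(y)
  confusion <- matrix(0L, length(lv), length(lv), dimnames = list(true = lv, pred = lv))

  if (projection == "tsne") {
    normAll <- applyNormalizer(fitNormalizer(data), data)
    args <- modifyList(list(data = normAll, k = k), projParams)
    emb <- do.call(tsneEmbed, args)
    projAll <- setFeatureMatrix(data, `colnames<-`(emb@Y, paste0("Y", seq_len(ncol(emb@Y)))))
  }

  foldErrors <- vapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f); ts <- which(folds == f)
    if (projection == "none") {
      trY <- subsetWindows(data, tr); tsY <- subsetWindows(data, ts)
    } else if (projection == "tsne") {
      trY <- subsetWindows(projAll, tr); tsY <- subsetWindows(projAll, ts)
    } else {
      norm <- fitNormalizer(subsetWindows(data, tr))
      trN <- applyNormalizer(norm, subsetWindows(data, tr))
      tsN <- applyNormalizer(norm, subsetWindows(data, ts))
      pr <- projectFeatures(projection, trN, tsN,
                            k = if (is.null(k)) 4L else k, params = projParams)
      trY <- pr$train; tsY <- pr$test
    }
    model <- trainClassifier(spec, trY)
    pred <- predictClassifier(model, tsY)
    truth <- factor(as.character(graspLabels(tsY)), levels = lv)
    confusion <<- confusion + unclass(table(truth, pred))
    classificationError(truth, pred)
  }, numeric(1))
  list(error = mean(foldErrors), foldErrors = foldErrors, confusion = confusion)
}

#' Exhaustive classifier grid search
#'
#' Evaluates each candidate spec by [crossValidate()] and returns the first
#' argmin in the supplied grid order (the documented deterministic tie-break).
#'
#' @param specs list of [classifierSpec()] candidates, in grid order.
#' @param data an unnormalized `GraspFeatureSet`.
#' @param folds fold ids from [makeFolds()].
#' @param projection,k,projParams forwarded to [crossValidate()].
#' @return list with the winning `spec`, its `error`, and all `errors`.
#' @export
gridSearchClassifier <- function(specs, data, folds, projection = "none",
                                 k = 4L, projParams = list()) {
  if (!length(specs)) stop("empty classifier grid")
  errors <- vapply(specs, function(s) {
    crossValidate(s, data, folds, projection, k, projParams)$error
  }, numeric(1))
  best <- which.min(errors)   # which.min returns the first minimum
  list(spec = specs[[best]], error = errors[best], errors = errors)
}
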