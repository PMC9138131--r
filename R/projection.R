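#' @include features.R
NULL

.asMatrix <- function(data) {
  if (methods::is(data, "GraspFeatureSet")) featureMatrix(data) else as.matrix(data)
}

## wrap a projected matrix back into the carrier type of `data`
.wrapProjected <- function(data, y) {
  colnames(y) <- paste0("Y", seq_len(ncol(y)))
  if (methods::is(data, "GraspFeatureSet")) setFeatureMatrix(data, y) else y
}

## deterministic eigenvector signs: largest-|.| element positive
.fixSigns <- function(v) {
  apply(v, 2, function(col) {
    j <- which.max(abs(col))
    if (col[j] < 0) -col else col
  })
}

#' Fit a PCA projector
#'
#' Eigen-decomposes the training covariance matrix and keeps the k
#' eigenvectors with the largest eigenvalues; projection is
#' Y = (X - mean) U_k.
#'
#' @param train a `GraspFeatureSet` or numeric matrix (rows = windows).
#' @param k output dimension (4 in the grasp study: classes minus one).
#' @return a [PcaProjector-class].
#' @export
fitPca <- function(train, k = 4L) {
  x <- .asMatrix(train)
  if (k > ncol(x)) stop("k exceeds the feature dimension")
  if (nrow(x) <= k) stop("need more rows than projected dimensions")
  ctr <- colMeans(x)
  e <- eigen(stats::cov(x), symmetric = TRUE)
  methods::new("PcaProjector",
    rotation = .fixSigns(e$vectors[, seq_len(k), drop = FALSE]),
    center = ctr, eigenvalues = pmax(e$values, 0), k = as.integer(k))
}

#' @describeIn fitPca project data with a fitted PCA model
#' @param model a fitted `PcaProjector`.
#' @param data data in the training feature space.
#' @export
setMethod("projectData", "PcaProjector", function(model, data) {
  x <- .asMatrix(data)
  y <- sweep(x, 2, model@center) %*% model@rotation
  .wrapProjected(data, y)
})

#' Fit a Fisher LDA projector
#'
#' Builds the within-class scatter Sw = sum_j sum_i (x - mu_j)(x - mu_j)^T and
#' between-class scatter Sb = sum_j n_j (mu_j - mu)(mu_j - mu)^T, then keeps
#' the k eigenvectors of solve(Sw) Sb with the largest eigenvalues
#' (k <= classes - 1). Sw gets a tiny ridge (1e-9 trace(Sw)/m) so degenerate
#' inputs stay invertible. Projection is Y = X V_k.
#'
#' @param train a `GraspFeatureSet`, or numeric matrix with `labels`.
#' @param k output dimension.
#' @param labels class labels when `train` is a bare matrix.
#' @return an [LdaProjector-class].
#' @export
fitLdaProjection <- function(train, k = 4L, labels = NULL) {
  x <- .asMatrix(train)
  y <- factor(if (is.null(labels)) graspLabels(train) else labels)
  c <- nlevels(y)
  if (c < 2) stop("LDA projection needs at least two classes")
  if (k > c - 1) stop("k must be at most classes - 1")
  m <- ncol(x)
  mu <- colMeans(x)
  Sw <- matrix(0, m, m); Sb <- matrix(0, m, m)
  counts <- integer(c)
  classMeans <- matrix(0, c, m, dimnames = list(levels(y), colnames(x)))
  for (j in seq_len(c)) {
    xj <- x[y == levels(y)[j], , drop = FALSE]
    counts[j] <- nrow(xj)
    muj <- colMeans(xj)
    classMeans[j, ] <- muj
    d <- sweep(xj, 2, muj)
    Sw <- Sw + crossprod(d)
    Sb <- Sb + counts[j] * tcrossprod(muj - mu)
  }
  SwR <- Sw + diag(1e-9 * sum(diag(Sw)) / m, m)
  e <- eigen(solve(SwR, Sb))
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(k)]
  v <- Re(e$vectors[, ord, drop = FALSE])
  v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
  methods::new("LdaProjector",
    rotation = .fixSigns(v), Sw = (Sw + t(Sw)) / 2, Sb = (Sb + t(Sb)) / 2,
    classMeans = classMeans, grandMean = mu, counts = counts,
    k = as.integer(k))
}

#' @describeIn fitLdaProjection project data with a fitted LDA model
#' @param model a fitted `LdaProjector`.
#' @param data data in the training feature space.
#' @export
setMethod("projectData", "LdaProjector", function(model, data) {
  x <- .asMatrix(data)
  .wrapProjected(data, x %*% model@rotation)
})

.srelmHidden <- function(x, a, b) {
  d <- sweep(x %*% a, 2, b, "+")
  1 / (1 + exp(d))
}

## c - 1 orthonormal response columns: orthogonalize the class indicators
## against the all-ones vector and drop the constant direction (spectral
## regression response construction)
.srelmResponses <- function(y) {
  c <- nlevels(y)
  ind <- stats::model.matrix(~ y - 1)
  q <- qr.Q(qr(cbind(1, ind[, seq_len(c - 1), drop = FALSE])))
  z <- q[, 2:c, drop = FALSE]
  colnames(z) <- NULL
  z
}

#' Fit an SRELM projector
#'
#' Spectral-regression extreme learning machine. Hidden-node parameters
#' (a_i, b_i), i = 1..L are drawn once from uniform(-1, 1) under `seed`;
#' hidden activations use the sigmoid g(d) = 1 / (1 + e^d). The response
#' matrix Z holds c - 1 orthonormal columns built from the class indicators
#' (deflating the constant direction), and the output weights solve the ridge
#' problem U = solve(H'H + alpha I, H'Z). Transforming reuses the persisted
#' (a_i, b_i); Y = H U has c - 1 columns.
#'
#' @param train a `GraspFeatureSet`, or numeric matrix with `labels`.
#' @param L hidden-node count (study operating point: 1000).
#' @param alpha ridge parameter (study operating point: 1).
#' @param seed RNG seed for the hidden-node draw.
#' @param labels class labels when `train` is a bare matrix.
#' @return an [SrelmProjector-class].
#' @export
fitSrelm <- function(train, L = 1000L, alpha = 1, seed = 1L, labels = NULL) {
  x <- .asMatrix(train)
  y <- factor(if (is.null(labels)) graspLabels(train) else labels)
  c <- nlevels(y)
  if (c < 2) stop("SRELM needs at least two classes")
  if (L < c) stop("hidden-node count L must be at least the class count")
  if (alpha <= 0) stop("alpha must be positive")
  set.seed(as.integer(seed))
  m <- ncol(x)
  a <- matrix(runif(m * L, -1, 1), m, L)
  b <- runif(L, -1, 1)
  H <- .srelmHidden(x, a, b)
  Z <- .srelmResponses(y)
  U <- solve(crossprod(H) + diag(alpha, L), crossprod(H, Z))
  methods::new("SrelmProjector",
    a = a, b = b, U = U, Z = Z, L = as.integer(L), alpha = alpha,
    seed = as.integer(seed), classLevels = levels(y))
}

#' @describeIn fitSrelm project data with a fitted SRELM model
#' @param model a fitted `SrelmProjector`.
#' @param data data in the training feature space.
#' @export
setMethod("projectData", "SrelmProjector", function(model, data) {
  x <- .asMatrix(data)
  if (ncol(x) != nrow(model@a)) stop("feature dimension mismatch")
  .wrapProjected(data, .srelmHidden(x, model@a, model@b) %*% model@U)
})

#' Exhaustive SRELM hyperparameter grid search
#'
#' Evaluates every (alpha, L) combination by five-fold cross-validated
#' classification error (projection refitted inside each training fold) and
#' returns the argmin. Ties are broken toward the smaller L, then the smaller
#' alpha.
#'
#' @param data an unnormalized `GraspFeatureSet`.
#' @param alphas ridge-parameter grid (study grid: 1..10).
#' @param Ls hidden-node grid (study grid: seq(50, 1500, by = 50)).
#' @param classifier a [classifierSpec()] used to score each candidate.
#' @param nFolds,seed cross-validation folds and seed.
#' @return list with `alpha`, `L`, `error` of the winner and the full `grid`
#'   data frame (alpha, L, error).
#' @export
srelmGridSearch <- function(data, alphas = 1:10, Ls = seq(50L, 1500L, by = 50L),
                            classifier = classifierSpec("knn"),
                            nFolds = 5L, seed = 1L) {
  if (!length(alphas) || !length(Ls)) stop("empty hyperparameter grid")
  folds <- makeFolds(ncol(data), nFolds = nFolds, seed = seed)
  grid <- expand.grid(alpha = alphas, L = sort(Ls))
  grid <- grid[order(grid$L, grid$alpha), , drop = FALSE]
  grid$error <- vapply(seq_len(nrow(grid)), function(i) {
    crossValidate(classifier, data, folds, projection = "srelm", k = NULL,
                  projParams = list(L = grid$L[i], alpha = grid$alpha[i],
                                    seed = seed))$error
  }, numeric(1))
  best <- grid[which.min(grid$error), ]
  list(alpha = best$alpha, L = best$L, error = best$error, grid = grid)
}

## per-point Gaussian bandwidth calibration: bisection on beta = 1/(2 sigma^2)
## so that the conditional distribution's perplexity matches the target
.tsneCondP <- function(D2, perplexity, tol = 1e-5, maxTries = 50L) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  sigmas <- numeric(n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    for (tr in seq_len(maxTries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; Pi <- w }
      else {
        Pi <- w / sw
        # Shannon entropy of the conditional distribution (nats)
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { betaMin <- beta; beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2 }
      else { betaMax <- beta; beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2 }
    }
    P[i, -i] <- Pi
    sigmas[i] <- sqrt(1 / (2 * beta))
  }
  list(P = P, sigmas = sigmas)
}

.tsneCost <- function(P, Y) {
  eps <- 1e-12
  num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
  diag(num) <- 0
  Q <- num / sum(num)
  sum(P * log(pmax(P, eps) / pmax(Q, eps)))
}

#' t-SNE embedding of a feature dataset
#'
#' From-first-principles t-distributed stochastic neighbor embedding:
#' per-point Gaussian bandwidths are calibrated by bisection (tolerance 1e-5,
#' at most 50 iterations) so each conditional distribution has the target
#' perplexity; the joint probabilities are p_ij = (p_{j|i} + p_{i|j}) / (2n);
#' low-dimensional similarities are Student-t with one degree of freedom; and
#' the Kullback-Leibler cost is minimized by gradient descent with momentum
#' 0.5 (0.8 after iteration 250), adaptive per-coordinate gains, learning rate
#' 200, early exaggeration x4 for the first 100 iterations and 1000 iterations
#' in total, from a seeded N(0, 1e-4) initialization. These optimizer settings
#' follow the original t-SNE publication's defaults. Purely unsupervised:
#' labels are never consulted.
#'
#' @param data a `GraspFeatureSet` or numeric matrix (rows = points).
#' @param k embedding dimension.
#' @param perplexity target perplexity; requires n > 3 * perplexity.
#' @param maxIter,eta,exaggeration,exaggerationIter optimizer settings.
#' @param seed RNG seed for the initialization.
#' @return a [TsneEmbedding-class].
#' @export
tsneEmbed <- function(data, k = 4L, perplexity = 30, maxIter = 1000L,
                      eta = 200, exaggeration = 4, exaggerationIter = 100L,
                      seed = 1L) {
  x <- .asMatrix(data)
  n <- nrow(x)
  if (n <= 3 * perplexity) stop("perplexity infeasible: need n > 3 * perplexity")
  D2 <- as.matrix(stats::dist(x))^2
  cal <- .tsneCondP(D2, perplexity)
  P <- (cal$P + t(cal$P)) / (2 * n)
  eps <- 1e-12

  set.seed(as.integer(seed))
  Y <- matrix(rnorm(n * k, sd = 1e-2), n, k)
  costInitial <- .tsneCost(P, Y)
  inc <- matrix(0, n, k)
  gains <- matrix(1, n, k)
  Pex <- P * exaggeration
  for (it in seq_len(maxIter)) {
    Puse <- if (it <= exaggerationIter) Pex else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- num / sum(num)
    G <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(G)) %*% Y - G %*% Y)
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- pmax(0.01,
      ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8))
    inc <- mom * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  methods::new("TsneEmbedding",
    Y = Y, P = P, sigmas = cal$sigmas, perplexity = perplexity,
    cost = .tsneCost(P, Y), costInitial = costInitial,
    params = list(maxIter = maxIter, eta = eta, exaggeration = exaggeration,
                  exaggerationIter = exaggerationIter,
                  momentum = c(0.5, 0.8), momentumSwitch = 250L),
    seed = as.integer(seed))
}

#' Project a train/test split with any of the four techniques
#'
#' One fit/transform contract over the four projection methods. PCA, LDA and
#' SRELM fit on the training rows only and transform both sets. t-SNE has no
#' out-of-sample mapping, so train and test rows are embedded jointly
#' (transductively) with labels withheld and split back by row index.
#'
#' @param method one of "pca", "lda", "srelm", "tsne".
#' @param train,test `GraspFeatureSet` objects over the same feature space.
#' @param k projected dimension (4: grasp classes minus one).
#' @param params method-specific parameter list (e.g. `L`, `alpha`, `seed`
#'   for SRELM; `perplexity`, `seed`, `maxIter` for t-SNE).
#' @return list with projected `train`, `test` (4-column feature sets) and the
#'   fitted `model` (`NULL` for t-SNE beyond the embedding object).
#' @export
projectFeatures <- function(method = c("pca", "lda", "srelm", "tsne"),
                            train, test, k = 4L, params = list()) {
  method <- match.arg(method)
  if (!identical(rownames(train), rownames(test))) {
    stop("train and test must share one feature space")
  }
  if (method == "tsne") {
    both <- bindWindows(train, test)
    args <- modifyList(list(data = both, k = k), params)
    emb <- do.call(tsneEmbed, args)
    nTr <- ncol(train)
    yTr <- emb@Y[seq_len(nTr), , drop = FALSE]
    yTs <- emb@Y[-seq_len(nTr), , drop = FALSE]
    return(list(train = setFeatureMatrix(train, `colnames<-`(yTr, paste0("Y", 1:k))),
                test = setFeatureMatrix(test, `colnames<-`(yTs, paste0("Y", 1:k))),
                model = emb))
  }
  model <- switch(method,
    pca = do.call(fitPca, modifyList(list(train = train, k = k), params)),
    lda = do.call(fitLdaProjection, modifyList(list(train = train, k = k), params)),
    srelm = do.call(fitSrelm, modifyList(list(train = train), params)))
  list(train = projectData(model, train),
       test = projectData(model, test),
       model = model)
}
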