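test_that("PCA finds the stretched axis and is exactly invertible at full rank", {
  set.seed(1)
  x <- cbind(rnorm(500, sd = 10), rnorm(500, sd = 1))
  fs <- GraspFeatureSet(x, grasp = "a", position = "P1", subject = "S01")
  m <- fitPca(fs, k = 1)
  angle <- acos(min(1, abs(m@rotation[1, 1]))) * 180 / pi
  expect_lt(angle, 2)

  m2 <- fitPca(fs, k = 2)
  y <- featureMatrix(projectData(m2, fs))
  back <- y %*% t(m2@rotation) + matrix(m2@center, 500, 2, byrow = TRUE)
  expect_lt(max(abs(back - x)), 1e-8)

  set.seed(2)
  iso <- matrix(rnorm(4000 * 3), 4000, 3)
  mIso <- fitPca(iso, k = 3)
  expect_lt(max(mIso@eigenvalues) / min(mIso@eigenvalues), 1.2)
  expect_error(fitPca(iso, k = 5), "exceeds")
})

test_that("LDA projection maximizes the Fisher ratio (random-direction oracle)", {
  set.seed(3)
  d <- 10
  mu2 <- c(1, rep(0, d - 1))
  x <- rbind(matrix(rnorm(200 * d), 200, d),
             sweep(matrix(rnorm(200 * d), 200, d), 2, mu2, "+"))
  y <- rep(c("a", "b"), each = 200)
  m <- fitLdaProjection(x, k = 1, labels = y)
  zProj <- drop(x %*% m@rotation[, 1])
  rProj <- fisherRatio(zProj, y)
  set.seed(4)
  rRandom <- max(vapply(1:1000, function(i) {
    v <- rnorm(d); v <- v / sqrt(sum(v^2))
    fisherRatio(drop(x %*% v), y)
  }, numeric(1)))
  expect_gte(rProj, rRandom * 0.99)

  # permutation oracle: shuffled labels collapse the between-class structure
  topEig <- function(m) {
    e <- eigen(solve(m@Sw + diag(1e-9 * sum(diag(m@Sw)) / d, d), m@Sb))
    max(Re(e$values))
  }
  set.seed(5)
  shufRatios <- vapply(1:5, function(i) {
    topEig(fitLdaProjection(x, k = 1, labels = sample(y))) / topEig(m)
  }, numeric(1))
  expect_lt(mean(shufRatios), 0.12)

  # k is capped at classes - 1
  fs5 <- clusterFeatureSet(diag(5)[, 1:5] * 4, nPerClass = 12, seed = 6)
  expect_error(fitLdaProjection(fs5, k = 5), "at most")
  expect_equal(ncol(fitLdaProjection(fs5, k = 4)@rotation), 4L)
})

test_that("LDA separates linearly separable classes with a simple threshold", {
  set.seed(7)
  fs <- clusterFeatureSet(rbind(rep(0, 6), rep(4, 6)), nPerClass = 40,
                          sd = 0.5, seed = 7)
  m <- fitLdaProjection(fs, k = 1)
  z <- featureMatrix(projectData(m, fs))[, 1]
  y <- graspLabels(fs)
  # brute-force threshold search oracle
  thresholds <- sort(z)
  errs <- vapply(thresholds, function(t) {
    min(mean((z <= t) != (y == levels(y)[1])),
        mean((z > t) != (y == levels(y)[1])))
  }, numeric(1))
  expect_equal(min(errs), 0)
})

test_that("SRELM solves the ridge regression problem (numerical-optimizer oracle)", {
  set.seed(10)
  n <- 30; m <- 5; L <- 10
  x <- matrix(rnorm(n * m), n, m)
  y <- factor(rep(c("a", "b", "c"), each = 10))
  fit <- fitSrelm(x, L = L, alpha = 1, seed = 2, labels = y)

  expect_equal(dim(fit@U), c(L, 2L))
  expect_lt(max(abs(crossprod(fit@Z) - diag(2))), 1e-10)

  # independent oracle: generic numerical minimization of the ridge objective
  H <- 1 / (1 + exp(sweep(x %*% fit@a, 2, fit@b, "+")))
  for (j in 1:2) {
    z <- fit@Z[, j]
    obj <- function(u) sum((H %*% u - z)^2) + 1 * sum(u^2)
    grad <- function(u) drop(2 * crossprod(H, H %*% u - z) + 2 * u)
    opt <- optim(rep(0, L), obj, grad, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    expect_lt(max(abs(opt$par - fit@U[, j])), 1e-5)
  }
})

test_that("SRELM transforms deterministically with persisted hidden nodes", {
  fs <- clusterFeatureSet(rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0),
                                c(0, 0, 5), c(3, 3, 3)), nPerClass = 15, seed = 3)
  fit <- fitSrelm(fs, L = 40, alpha = 1, seed = 9)
  expect_equal(ncol(fit@U), 4L)    # five classes -> four output columns
  y1 <- featureMatrix(projectData(fit, fs))
  y2 <- featureMatrix(projectData(fit, fs))
  expect_identical(y1, y2)
  # fit-stage responses are reproduced by the transform path on training data
  H <- 1 / (1 + exp(sweep(featureMatrix(fs) %*% fit@a, 2, fit@b, "+")))
  expect_equal(unname(y1), unname(H %*% fit@U))
  expect_error(fitSrelm(fs, L = 3, alpha = 1), "at least the class count")
  expect_error(projectData(fit, matrix(0, 2, 7)), "mismatch")
})

test_that("ridge strength shrinks SRELM output weights monotonically", {
  fs <- clusterFeatureSet(rbind(c(0, 0), c(3, 3)), nPerClass = 25, seed = 4)
  norms <- vapply(c(1, 10, 100, 1000), function(a) {
    sqrt(sum(fitSrelm(fs, L = 20, alpha = a, seed = 5)@U^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("SRELM separates supervised structure better than PCA (SI comparison)", {
  fs <- cached("srelmVsPca", function() {
    clusterFeatureSet(rbind(c(0, 0, 0, 0, 0), c(4, 0, 0, 0, 0), c(0, 4, 0, 0, 0),
                            c(0, 0, 4, 0, 0), c(0, 0, 0, 4, 0)),
                      nPerClass = 30, seed = 12)
  })
  norm <- applyNormalizer(fitNormalizer(fs), fs)
  prS <- projectFeatures("srelm", norm, norm, params = list(L = 100L, alpha = 1, seed = 1))
  prP <- projectFeatures("pca", norm, norm, k = 4)
  expect_gt(separabilityIndex(prS$train), separabilityIndex(prP$train))
})

test_that("t-SNE probabilities are correctly normalized and the KL cost decreases", {
  set.seed(20)
  x <- rbind(matrix(rnorm(40 * 6), 40, 6),
             matrix(rnorm(40 * 6, mean = 6), 40, 6))
  cal <- emgrasp:::.tsneCondP(as.matrix(dist(x))^2, perplexity = 10)
  expect_true(all(abs(rowSums(cal$P) - 1) < 1e-6))
  emb <- tsneEmbed(x, k = 2, perplexity = 10, maxIter = 300, seed = 1)
  expect_lt(abs(sum(emb@P) - 1), 1e-6)
  expect_lt(emb@cost, emb@costInitial)
  expect_gte(emb@cost, 0)
  expect_error(tsneEmbed(x, perplexity = 40), "infeasible")
})

test_that("t-SNE recovers well-separated clusters (k-means agreement oracle)", {
  set.seed(21)
  centers <- rbind(rep(0, 66), c(rep(8, 33), rep(0, 33)), rep(-8, 66))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(100 * 66), 100, 66), 2, centers[i, ], "+")
  }))
  truth <- rep(1:3, each = 100)
  emb <- tsneEmbed(x, k = 4, perplexity = 30, seed = 2)
  km <- kmeans(emb@Y, centers = 3, nstart = 10)
  expect_gte(labelAgreement(km$cluster, truth), 0.95)
})

test_that("the project() dispatcher honors one contract across all four methods", {
  fs <- sharedFeatures()
  idx <- seq_len(ncol(fs))
  # stratified thirds so every grasp class appears on both sides of the split
  tr <- subsetWindows(fs, idx[idx %% 3 != 0])
  ts <- subsetWindows(fs, idx[idx %% 3 == 0])
  norm <- fitNormalizer(tr)
  trN <- applyNormalizer(norm, tr); tsN <- applyNormalizer(norm, ts)

  for (method in c("pca", "lda", "srelm", "tsne")) {
    params <- switch(method,
      srelm = list(L = 60L, alpha = 1, seed = 1),
      tsne = list(perplexity = 15, maxIter = 250L, seed = 1),
      list())
    pr <- projectFeatures(method, trN, tsN, k = 4, params = params)
    expect_equal(ncol(featureMatrix(pr$train)), 4L, info = method)
    expect_equal(ncol(featureMatrix(pr$test)), 4L, info = method)
    expect_equal(ncol(pr$train), ncol(trN), info = method)
    expect_equal(ncol(pr$test), ncol(tsN), info = method)
  }

  # PCA path equals the fit + transform composition
  pr <- projectFeatures("pca", trN, tsN, k = 4)
  direct <- projectData(fitPca(trN, k = 4), tsN)
  expect_equal(featureMatrix(pr$test), featureMatrix(direct))

  # t-SNE train rows do not depend on how the joint embedding is split back
  prT <- projectFeatures("tsne", trN, tsN, k = 2,
                         params = list(perplexity = 15, maxIter = 250L, seed = 3))
  joint <- tsneEmbed(bindWindows(trN, tsN), k = 2, perplexity = 15,
                     maxIter = 250L, seed = 3)
  expect_equal(unname(featureMatrix(prT$train)),
               unname(joint@Y[seq_len(ncol(trN)), ]))
  expect_error(projectFeatures("sammon", trN, tsN), "arg")
})
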