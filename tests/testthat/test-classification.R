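test_that("seeded folds partition the rows into near-equal fifths", {
  f <- makeFolds(100, seed = 1)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  expect_identical(f, makeFolds(100, seed = 1))
  expect_false(identical(f, makeFolds(100, seed = 2)))
  f2 <- makeFolds(103, seed = 3)
  expect_lte(diff(range(table(f2))), 1)
  expect_setequal(unique(f2), 1:5)
  expect_error(makeFolds(3, nFolds = 5), "at least one row")
})

test_that("every classifier kind solves trivially separable problems", {
  centers <- rbind(c(0, 0, 0, 0), c(20, 0, 0, 0), c(0, 20, 0, 0),
                   c(0, 0, 20, 0), c(0, 0, 0, 20))
  tr <- clusterFeatureSet(centers, nPerClass = 20, sd = 0.5, seed = 1)
  ts <- clusterFeatureSet(centers, nPerClass = 10, sd = 0.5, seed = 2)
  for (kind in c("lda", "nb", "knn", "svml", "svmb", "svmp", "nn")) {
    model <- trainClassifier(classifierSpec(kind, seed = 1), tr)
    err <- classificationError(graspLabels(ts), predictClassifier(model, ts))
    expect_equal(err, 0, info = kind)
  }
})

test_that("KNN with k = 1 reproduces its own training labels", {
  fs <- clusterFeatureSet(rbind(c(0, 0), c(1.5, 0)), nPerClass = 30, seed = 4)
  model <- trainClassifier(classifierSpec("knn", k = 1), fs)
  expect_equal(classificationError(graspLabels(fs),
                                   predictClassifier(model, fs)), 0)
})

test_that("the neural network rejects inputs that are not 4-D", {
  fs <- clusterFeatureSet(rbind(rep(0, 3), rep(5, 3)), nPerClass = 10, seed = 5)
  expect_error(trainClassifier(classifierSpec("nn"), fs), "4-D")
})

test_that("cross-validated error sits at chance for label-independent features", {
  errs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(250 * 4), 250, 4)
    fs <- GraspFeatureSet(x, grasp = sample(rep(letters[1:5], 50)),
                          position = "P1", subject = "S01")
    folds <- makeFolds(250, seed = s)
    crossValidate(classifierSpec("knn"), fs, folds)$error
  }, numeric(1))
  expect_lt(abs(mean(errs) - 80), 3)
})

test_that("cross-validation averages fold errors and is invariant to row order", {
  fs <- sharedFeatures()
  keep <- seq_len(300)
  sub <- subsetWindows(fs, keep)
  folds <- makeFolds(300, seed = 2)
  cv <- crossValidate(classifierSpec("knn"), sub, folds, projection = "pca")
  expect_equal(cv$error, mean(cv$foldErrors))
  expect_length(cv$foldErrors, 5L)
  expect_equal(sum(cv$confusion), 300)

  # permute rows and folds together: identical mean error
  set.seed(9)
  perm <- sample(300)
  cvP <- crossValidate(classifierSpec("knn"), subsetWindows(sub, perm),
                       folds[perm], projection = "pca")
  expect_equal(sort(cvP$foldErrors), sort(cv$foldErrors))
  expect_equal(cvP$error, cv$error)
})

test_that("perfectly separable data yields zero cross-validated error", {
  fs <- clusterFeatureSet(rbind(rep(0, 5), rep(30, 5)), nPerClass = 40,
                          sd = 0.5, seed = 6)
  folds <- makeFolds(80, seed = 1)
  expect_equal(crossValidate(classifierSpec("knn"), fs, folds)$error, 0)
})

test_that("classifier grid search returns the first argmin in grid order", {
  fs <- clusterFeatureSet(rbind(c(0, 0, 0, 0), c(25, 0, 0, 0)),
                          nPerClass = 25, sd = 0.5, seed = 7)
  folds <- makeFolds(50, seed = 1)
  specs <- lapply(1:7, function(k) classifierSpec("knn", k = k))
  gs <- gridSearchClassifier(specs, fs, folds)
  expect_equal(gs$spec$k, 1L)               # all tie at 0; first wins
  expect_true(all(gs$error <= gs$errors))
  one <- gridSearchClassifier(specs[3], fs, folds)
  expect_equal(one$spec$k, 3L)
  expect_error(gridSearchClassifier(list(), fs, folds), "empty")
})

test_that("SRELM hyperparameter search scans the grid with the documented tie-break", {
  fs <- clusterFeatureSet(rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)),
                          nPerClass = 15, sd = 0.5, seed = 8)
  gs <- srelmGridSearch(fs, alphas = c(1, 2), Ls = c(10L, 20L),
                        classifier = classifierSpec("knn"), seed = 1)
  expect_equal(nrow(gs$grid), 4L)
  expect_true(all(gs$error <= gs$grid$error))
  # grid rows ordered by (L, alpha): ties resolve to smaller L, then alpha
  firstMin <- gs$grid[which.min(gs$grid$error), ]
  expect_equal(gs$L, firstMin$L)
  expect_equal(gs$alpha, firstMin$alpha)
  expect_error(srelmGridSearch(fs, alphas = numeric(0)), "empty")
})
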