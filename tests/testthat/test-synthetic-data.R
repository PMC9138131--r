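test_that("the default design yields 5 x 9 x reps trials per subject with valid labels", {
  recs <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 4))
  expect_length(recs, 45L)
  grasp <- vapply(recs, function(r) r@grasp, character(1))
  pos <- vapply(recs, function(r) r@position, character(1))
  expect_setequal(unique(grasp), c("sphere", "cylinder", "keycard", "eraser", "pen"))
  expect_setequal(unique(pos), paste0("P", 1:9))
  expect_equal(as.vector(table(grasp, pos)), rep(1L, 45))
  r <- recs[[1]]
  expect_equal(dim(r@emg), c(6L, 2048L))
  expect_equal(dim(r@imu), c(6L, 120L))
})

test_that("generation is deterministic in the seed and order-independent", {
  a <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 7))
  b <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 7))
  expect_identical(a[[10]]@emg, b[[10]]@emg)
  expect_identical(a[[31]]@imu, b[[31]]@imu)
  c <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 8))
  expect_false(identical(a[[10]]@emg, c[[10]]@emg))
})

test_that("invalid generator configurations are rejected", {
  expect_error(graspGeneratorConfig(nSubjects = 0), "positive")
  expect_error(graspGeneratorConfig(nReps = -1), "positive")
  expect_error(graspGeneratorConfig(emgRate = 0), "strictly positive")
  expect_error(graspGeneratorConfig(noiseSd = -0.1), "non-negative")
})

test_that("zero class separation and position effect equalize channel variances", {
  # brute-force oracle: pooled per-trial sample variances, compared across
  # grasp and position groups
  cfg <- graspGeneratorConfig(nReps = 2L, seed = 11,
                              classSeparation = 0, positionEffect = 0)
  recs <- generateGraspDataset(cfg)
  v <- vapply(recs, function(r) var(r@emg[1, ]), numeric(1))
  grasp <- vapply(recs, function(r) r@grasp, character(1))
  pos <- vapply(recs, function(r) r@position, character(1))
  byGrasp <- tapply(v, grasp, mean)
  byPos <- tapply(v, pos, mean)
  expect_lt(max(byGrasp) / min(byGrasp), 1.15)
  expect_lt(max(byPos) / min(byPos), 1.25)
  # and the position effect reappears when switched on
  cfg2 <- graspGeneratorConfig(nReps = 2L, seed = 11, classSeparation = 0)
  v2 <- vapply(generateGraspDataset(cfg2), function(r) var(r@emg[1, ]), numeric(1))
  byPos2 <- tapply(v2, pos, mean)
  expect_gt(max(byPos2) / min(byPos2), 1.5)
})

test_that("class separation monotonically increases raw MAV separability", {
  grid <- c(0.4, 1, 2)
  siAt <- function(cs) {
    mean(vapply(1:5, function(s) {
      cfg <- graspGeneratorConfig(nReps = 1L, seed = 100 + s, classSeparation = cs)
      fs <- featuresFromRecordings(generateGraspDataset(cfg), windowStride = 13L)
      x <- featureMatrix(fs)
      separabilityIndex(x[, grepl("_MAV$", colnames(x))], labels = graspLabels(fs))
    }, numeric(1)))
  }
  si <- vapply(grid, siAt, numeric(1))
  expect_true(all(diff(si) > 0))
})

test_that("position effect shifts per-position class means in MAV space", {
  shiftSize <- function(pe, seed = 21) {
    cfg <- graspGeneratorConfig(nReps = 2L, seed = seed, positionEffect = pe)
    fs <- featuresFromRecordings(generateGraspDataset(cfg), windowStride = 13L)
    x <- featureMatrix(fs)[, grepl("_MAV$", colnames(featureMatrix(fs)))]
    g <- graspLabels(fs); p <- positionLabels(fs)
    # mean over (grasp, position) cells of the distance between the cell mean
    # and that grasp's overall mean
    mean(unlist(lapply(levels(g), function(gl) {
      mu <- colMeans(x[g == gl, , drop = FALSE])
      vapply(levels(p), function(pl) {
        sel <- g == gl & p == pl
        sqrt(sum((colMeans(x[sel, , drop = FALSE]) - mu)^2))
      }, numeric(1))
    })))
  }
  withEffect <- shiftSize(0.35)
  without <- shiftSize(0)
  expect_gt(withEffect, 3 * without)
})

test_that("accelerometer Y means separate the three azimuth groups", {
  recs <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 5))
  accy <- vapply(recs, function(r) mean(r@imu["ACCY", ]), numeric(1))
  pos <- vapply(recs, function(r) r@position, character(1))
  groupOf <- function(p) (as.integer(sub("P", "", p)) - 1L) %/% 3L
  gm <- tapply(accy, groupOf(pos), mean)
  expect_lt(gm["0"], gm["1"])   # azimuth -45 < 0
  expect_lt(gm["1"], gm["2"])   # azimuth 0 < +45
})

test_that("datasets round-trip through the delimited-text layout", {
  recs <- generateGraspDataset(graspGeneratorConfig(nReps = 1L, seed = 9))[1:4]
  dir <- withr::local_tempdir()
  writeGraspDataset(recs, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- readGraspDataset(dir)
  expect_length(back, 4L)
  expect_equal(back[[2]]@emg, recs[[2]]@emg, tolerance = 1e-8)
  expect_equal(back[[2]]@imu, recs[[2]]@imu, tolerance = 1e-8)
  expect_identical(back[[2]]@grasp, recs[[2]]@grasp)
  expect_identical(back[[2]]@position, recs[[2]]@position)
  expect_error(readGraspDataset(file.path(dir, "nowhere")), "manifest")
})
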