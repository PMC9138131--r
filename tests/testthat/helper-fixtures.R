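# Shared fixtures, built in code and cached for the duration of the run.
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, builder(), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Small end-to-end dataset at the generator's default study conditions:
# 1 subject x 5 grasps x 9 positions x 2 reps, windows thinned 8-fold
# (5 windows per 2 s trial) to keep the suite fast.
sharedFeatures <- function(seed = 1L) {
  cached(paste0("fs", seed), function() {
    cfg <- graspGeneratorConfig(nReps = 2L, seed = seed)
    featuresFromRecordings(generateGraspDataset(cfg), windowStride = 8L)
  })
}

# Gaussian-cluster feature set: one isotropic cluster per row of `centers`.
clusterFeatureSet <- function(centers, nPerClass = 50L, sd = 1, seed = 1L,
                              labels = NULL) {
  set.seed(seed)
  centers <- as.matrix(centers)
  if (is.null(labels)) labels <- paste0("class", seq_len(nrow(centers)))
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    sweep(matrix(rnorm(nPerClass * ncol(centers), sd = sd),
                 nPerClass, ncol(centers)), 2, centers[i, ], "+")
  }))
  GraspFeatureSet(x, grasp = rep(labels, each = nPerClass),
                  position = "P1", subject = "S01",
                  trial = 1L, window = seq_len(nrow(x)))
}

# A raw recording fabricated directly (for segmentation edge cases).
makeRecording <- function(emgRate = 1024, imuRate = 60, duration = 2,
                          emgFill = NULL, seed = 1L) {
  set.seed(seed)
  nE <- round(emgRate * duration); nI <- round(imuRate * duration)
  emg <- if (is.null(emgFill)) matrix(rnorm(6 * nE), 6, nE)
         else matrix(emgFill, 6, nE)
  methods::new("GraspRecording",
    emg = emg, imu = matrix(rnorm(6 * nI), 6, nI),
    emgRate = emgRate, imuRate = imuRate,
    subject = "S01", grasp = "sphere", position = "P1",
    rep = 1L, trialId = 1L)
}

# Fisher ratio of 1-D projected two-class data (independent of the LDA path).
fisherRatio <- function(z, y) {
  lv <- levels(factor(y))
  z1 <- z[y == lv[1]]; z2 <- z[y == lv[2]]
  n1 <- length(z1); n2 <- length(z2)
  sb <- n1 * (mean(z1) - mean(z))^2 + n2 * (mean(z2) - mean(z))^2
  sw <- sum((z1 - mean(z1))^2) + sum((z2 - mean(z2))^2)
  sb / sw
}

# Best label agreement between a clustering and reference labels over all
# permutations of the cluster ids.
labelAgreement <- function(cluster, truth) {
  cluster <- as.integer(factor(cluster)); truth <- as.integer(factor(truth))
  k <- max(truth)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  max(vapply(perms(seq_len(k)), function(p) {
    mean(p[cluster] == truth)
  }, numeric(1)))
}
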