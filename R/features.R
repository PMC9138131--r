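#' @include preprocess.R
NULL

#' Time-domain EMG features
#'
#' The classical per-channel time-domain set computed on one 150 ms session
#' window `u` of N samples:
#' * `mav(u)`: mean absolute value, (1/N) sum |u_i|.
#' * `zc(u)`: zero crossings, the number of i with u_i * u_{i+1} < 0
#'   (strict; products equal to 0 do not count, no amplitude deadband).
#' * `wl(u)`: waveform length, sum |u_{i+1} - u_i|.
#' * `ssc(u)`: slope sign changes, the number of interior i with
#'   (u_i - u_{i+1}) * (u_i - u_{i-1}) > 0 (strict).
#' * `arCoeffs(u, order)`: coefficients a_1..a_P of the autoregressive model
#'   u_i = sum_p a_p u_{i-p} + e_i, estimated by Burg's method (stable on
#'   154-sample windows); order 6 here.
#'
#' @param u numeric vector, one windowed EMG channel.
#' @param order AR model order.
#' @return `mav`, `wl` a real; `zc`, `ssc` a non-negative integer count;
#'   `arCoeffs` a length-`order` numeric vector (all zeros, with attribute
#'   `degenerate = TRUE`, for a constant window).
#' @examples
#' mav(c(1, -1, 2))  # 4/3
#' zc(c(1, -1, 2))   # 2
#' wl(c(1, -1, 2))   # 5
#' ssc(c(1, -1, 2))  # 1
#' @export
mav <- function(u) {
  if (length(u) < 1) stop("mav needs at least one sample")
  mean(abs(u))
}

#' @rdname mav
#' @export
zc <- function(u) {
  n <- length(u)
  if (n < 2) stop("zc needs at least two samples")
  sum(u[-n] * u[-1] < 0)
}

#' @rdname mav
#' @export
wl <- function(u) {
  if (length(u) < 2) stop("wl needs at least two samples")
  sum(abs(diff(u)))
}

#' @rdname mav
#' @export
ssc <- function(u) {
  n <- length(u)
  if (n < 3) stop("ssc needs at least three samples")
  i <- 2:(n - 1)
  sum((u[i] - u[i + 1]) * (u[i] - u[i - 1]) > 0)
}

#' @rdname mav
#' @export
arCoeffs <- function(u, order = 6L) {
  if (length(u) <= 2L * order) stop("window too short for AR(", order, ") estimation")
  if (var(u) < .Machine$double.eps) {
    return(structure(rep(0, order), degenerate = TRUE))
  }
  fit <- stats::ar.burg(u, aic = FALSE, order.max = order, demean = TRUE)
  a <- as.numeric(fit$ar)
  if (length(a) < order) a <- c(a, rep(0, order - length(a)))
  a
}

#' Root-mean-square of an IMU window
#'
#' sqrt((1/M) sum v_i^2) over one windowed IMU channel.
#'
#' @param v numeric vector, one windowed IMU channel.
#' @return non-negative real.
#' @examples
#' rmsValue(c(3, 4))  # sqrt(12.5)
#' @export
rmsValue <- function(v) {
  if (length(v) < 1) stop("rmsValue needs at least one sample")
  sqrt(mean(v^2))
}

#' Names of the 66 features, in canonical order
#'
#' Per EMG channel ch = 1..6: MAV, ZC, WL, SSC, AR1..AR6 (10 features,
#' 60 total), then the six IMU RMS values RMS_ACCX..RMS_GYRZ. This order is a
#' stable part of the interface.
#'
#' @return character vector of length 66.
#' @export
featureNames66 <- function() {
  emg <- as.vector(vapply(1:6, function(ch) {
    paste0("EMG", ch, "_", c("MAV", "ZC", "WL", "SSC", paste0("AR", 1:6)))
  }, character(10)))
  c(emg, paste0("RMS_", c("ACCX", "ACCY", "ACCZ", "GYRX", "GYRY", "GYRZ")))
}

.windowFeatures <- function(w) {
  emgF <- numeric(60)
  degenerate <- FALSE
  for (ch in 1:6) {
    u <- w$emg[ch, ]
    a <- arCoeffs(u)
    if (isTRUE(attr(a, "degenerate"))) degenerate <- TRUE
    emgF[(ch - 1L) * 10L + 1:10] <- c(mav(u), zc(u), wl(u), ssc(u), a)
  }
  imuF <- apply(w$imu, 1, rmsValue)
  structure(c(emgF, imuF), degenerate = degenerate)
}

#' Extract the 66-D feature dataset from session windows
#'
#' One feature vector per window, in the [featureNames66()] order, labels
#' carried through. Windows whose EMG is constant (zero variance) get zero AR
#' coefficients and are listed in `metadata(fs)$degenerateWindows`.
#'
#' @param windows list of session windows from [segmentRecording()], possibly
#'   concatenated over trials.
#' @return a [GraspFeatureSet-class] with 66 feature rows.
#' @export
extractFeatures <- function(windows) {
  if (length(windows) == 0) stop("no windows to extract features from")
  vals <- lapply(windows, .windowFeatures)
  x <- do.call(rbind, vals)
  colnames(x) <- featureNames66()
  fs <- GraspFeatureSet(x,
    grasp = vapply(windows, `[[`, character(1), "grasp"),
    position = vapply(windows, `[[`, character(1), "position"),
    subject = vapply(windows, `[[`, character(1), "subject"),
    trial = vapply(windows, `[[`, integer(1), "trialId"),
    window = vapply(windows, `[[`, integer(1), "windowIndex"))
  deg <- which(vapply(vals, function(v) isTRUE(attr(v, "degenerate")), logical(1)))
  if (length(deg)) metadata(fs)$degenerateWindows <- deg
  fs
}

#' Segment, window and featurize a set of recordings
#'
#' Convenience wrapper: filter each recording ([preprocessRecording()]),
#' segment it ([segmentRecording()]), keep every `windowStride`-th window
#' (stride 1 keeps all 38 windows of a 2 s trial) and extract the 66-D
#' features.
#'
#' @param recs list of [GraspRecording-class] objects.
#' @param windowStride keep windows 1, 1 + stride, ... of each trial; larger
#'   strides thin the dataset for faster downstream experiments.
#' @param maWindow IMU moving-average length (samples).
#' @return a [GraspFeatureSet-class].
#' @export
featuresFromRecordings <- function(recs, windowStride = 1L, maWindow = 5L) {
  windows <- unlist(lapply(recs, function(r) {
    w <- segmentRecording(preprocessRecording(r, maWindow = maWindow))
    w[seq(1, length(w), by = windowStride)]
  }), recursive = FALSE)
  extractFeatures(windows)
}

#' Fit / apply the min-max normalizer
#'
#' `fitNormalizer` records each feature's training minimum and maximum;
#' `applyNormalizer` maps x to 2 (x - min) / (max - min) - 1. Training data
#' lands exactly in \[-1, 1\]; test values outside the training range are NOT
#' clipped. Constant features map to 0.
#'
#' @param train a `GraspFeatureSet` of training windows.
#' @param norm a fitted [FeatureNormalizer-class].
#' @param data a `GraspFeatureSet` to normalize.
#' @return `fitNormalizer` a `FeatureNormalizer`; `applyNormalizer` the
#'   normalized `GraspFeatureSet`.
#' @export
fitNormalizer <- function(train) {
  x <- featureMatrix(train)
  if (nrow(x) == 0) stop("cannot fit a normalizer on an empty dataset")
  methods::new("FeatureNormalizer",
    min = apply(x, 2, min), max = apply(x, 2, max))
}

#' @rdname fitNormalizer
#' @export
applyNormalizer <- function(norm, data) {
  x <- featureMatrix(data)
  stopifnot(ncol(x) == length(norm@min))
  rng <- norm@max - norm@min
  y <- sweep(sweep(x, 2, norm@min), 2, ifelse(rng == 0, 1, rng), "/") * 2 - 1
  y[, rng == 0] <- 0
  setFeatureMatrix(data, y, colnames(x))
}
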