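#' @include synthetic-data.R
NULL

#' Band-pass filter an EMG channel
#'
#' Fifth-order Butterworth band-pass, 20-450 Hz, applied forward-backward
#' (zero phase) so features stay aligned with the trial labels.
#'
#' @param x numeric vector, one EMG channel.
#' @param rate sampling rate in Hz; must exceed 900 Hz so the 450 Hz edge
#'   sits below Nyquist.
#' @return filtered series, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1024)
#' f <- bandpassEmg(sin(2 * pi * 100 * t), 1024)  # passband: nearly unchanged
#' @export
bandpassEmg <- function(x, rate) {
  if (rate <= 900) stop("EMG rate must exceed 900 Hz (20-450 Hz passband infeasible)")
  bf <- signal::butter(5, c(20, 450) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Notch-filter power-line interference from an EMG channel
#'
#' Second-order IIR notch centered at 50 Hz (quality factor 30, about 1.7 Hz
#' bandwidth), applied forward-backward. The biquad follows the standard
#' audio-EQ design: with w0 = 2*pi*50/rate and alpha = sin(w0)/(2Q),
#' b = (1, -2cos(w0), 1), a = (1+alpha, -2cos(w0), 1-alpha).
#'
#' @param x numeric vector, one EMG channel.
#' @param rate sampling rate in Hz (> 900).
#' @param freq interference frequency, Hz.
#' @param Q notch quality factor.
#' @return filtered series, same length as `x`.
#' @export
notchEmg <- function(x, rate, freq = 50, Q = 30) {
  if (rate <= 900) stop("EMG rate must exceed 900 Hz")
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  flt <- signal::Arma(b = b / a[1], a = a / a[1])
  as.numeric(signal::filtfilt(flt, as.numeric(x)))
}

#' Moving-average smoothing for IMU channels
#'
#' Centered moving average of odd length; edge samples average over the
#' shrinking window that fits inside the series.
#'
#' @param x numeric vector, one IMU channel.
#' @param windowLen odd positive window length in samples (default 5, about
#'   83 ms at 60 Hz).
#' @return smoothed series, same length as `x`.
#' @examples
#' smoothImu(c(1, 2, 3, 4, 5), 3)  # 1.5 2 3 4 4.5
#' @export
smoothImu <- function(x, windowLen = 5L) {
  if (windowLen < 1 || windowLen %% 2 == 0) {
    stop("windowLen must be an odd positive integer")
  }
  n <- length(x)
  half <- (windowLen - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Filter a recording's channels
#'
#' Applies the 20-450 Hz band-pass and the 50 Hz notch to every EMG channel
#' and the moving average to every IMU channel, once per recording (before any
#' segmentation).
#'
#' @param rec a [GraspRecording-class].
#' @param maWindow IMU moving-average length in samples.
#' @return the filtered `GraspRecording`.
#' @export
preprocessRecording <- function(rec, maWindow = 5L) {
  emg <- t(apply(rec@emg, 1, function(ch) notchEmg(bandpassEmg(ch, rec@emgRate), rec@emgRate)))
  imu <- t(apply(rec@imu, 1, smoothImu, windowLen = maWindow))
  rownames(emg) <- rownames(rec@emg)
  rownames(imu) <- rownames(rec@imu)
  methods::initialize(rec, emg = emg, imu = imu)
}

#' Segment a recording into aligned analysis windows
#'
#' Slides a 150 ms window in 50 ms steps (100 ms overlap) over both streams.
#' Window k starts at t_k = k * stepS; windows are emitted while
#' t_k + winS fits inside the recording. Per-stream sample counts come from
#' nearest-sample rounding: N = round(winS * emgRate) EMG samples and
#' M = round(winS * imuRate) IMU samples (154 and 9 at the default rates), so
#' both streams cover the same 150 ms span to within one sample.
#'
#' @param rec a (filtered) [GraspRecording-class].
#' @param winS window length in seconds.
#' @param stepS window increment in seconds.
#' @return list of session windows; each element has `emg` (6 x N), `imu`
#'   (6 x M), the trial labels and the window index.
#' @examples
#' cfg <- graspGeneratorConfig(nReps = 1, seed = 1)
#' w <- segmentRecording(generateGraspDataset(cfg)[[1]])
#' length(w)  # 38 windows per 2 s trial
#' @export
segmentRecording <- function(rec, winS = 0.150, stepS = 0.050) {
  nE <- round(winS * rec@emgRate); dE <- round(stepS * rec@emgRate)
  nI <- round(winS * rec@imuRate); dI <- round(stepS * rec@imuRate)
  kMaxE <- floor((ncol(rec@emg) - nE) / dE)
  kMaxI <- floor((ncol(rec@imu) - nI) / dI)
  kMax <- min(kMaxE, kMaxI)
  if (kMax < 0) stop("recording shorter than one analysis window")
  lapply(0:kMax, function(k) {
    list(
      emg = rec@emg[, (k * dE + 1L):(k * dE + nE), drop = FALSE],
      imu = rec@imu[, (k * dI + 1L):(k * dI + nI), drop = FALSE],
      subject = rec@subject, grasp = rec@grasp, position = rec@position,
      rep = rec@rep, trialId = rec@trialId, windowIndex = k + 1L
    )
  })
}
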