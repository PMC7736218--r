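## Synthetic multichannel EEG epochs: spatially correlated 1/f background
## plus white sensor noise and, on stop trials, a Hanning-windowed
## beta-band burst injected through a right-frontal mixing vector. The
## burst peak precedes the cancellation time by burstLeadMean +/-
## burstLeadSd ms plus independent couplingJitterSd jitter, which is what
## couples BurstTime to CancelTime in the generated cohort.

## 1/f amplitude-shaped noise, one column per series.
pinkNoise <- function(n, nSeries, fs) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f < 1, 1, 1 / sqrt(f))  # power ~ 1/f above 1 Hz
  ph <- matrix(stats::runif(n * nSeries, 0, 2 * pi), n, nSeries)
  spec <- shape * exp(1i * ph)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  x
}

## Gaussian spatial profile over the montage centered on a channel label.
mixingVector <- function(montage, centerLabel, spread) {
  ctr <- montage[montage$label == centerLabel, c("x", "y")]
  d2 <- (montage$x - ctr$x)^2 + (montage$y - ctr$y)^2
  m <- exp(-d2 / (2 * spread^2))
  m / max(m)
}

#' Synthesize multichannel EEG epochs for a session
#'
#' Generates one epoch per trial: stop trials are time-locked to the stop
#' signal, go trials to the go signal, both with window
#' \code{windowMs} (default -2000 to 1520 ms, covering the spatial-filter
#' derivation and burst-analysis windows). The background of every epoch is
#' a mixture of spatially smooth 1/f sources plus white sensor noise,
#' channel RMS about 1. With probability \code{burstProb} a stop trial
#' additionally receives a Hanning-windowed sinusoid at the subject's peak
#' beta frequency, peaking at (cancellation latency - lead + jitter) ms
#' after the stop signal, injected through the right-frontal mixing vector.
#'
#' @param trials trial table from \code{\link{runStaircaseSession}}.
#' @param eeg an \linkS4class{EegSynthParams}.
#' @param seed optional integer seed.
#' @param windowMs epoch window (ms) relative to the lock event.
#' @param nGoEpochs number of go trials to epoch (correct-go trials are
#'   sampled down to this count; EEG sessions epoch far fewer go than the
#'   task presents). Default: as many as there are stop trials.
#' @return list with \code{stop} and \code{go} (\linkS4class{EpochSet}s,
#'   \code{go} may be NULL), \code{truth} (data.frame: trial_index,
#'   true_cancel_ms, true_burst_peak_ms, burst_present, row-aligned with the
#'   stop epochs) and \code{mixing} (the true source mixing vector).
#' @examples
#' tr <- runStaircaseSession(raceParams(), nGo = 8, nStop = 4, seed = 2)
#' ep <- synthEegEpochs(tr, eegSynthParams(nChannels = 64), seed = 3)
#' dim(epochData(ep$stop))
#' @export
synthEegEpochs <- function(trials, eeg, seed = NULL,
                           windowMs = c(-2000, 1520), nGoEpochs = NULL) {
  stopifnot(is(eeg, "EegSynthParams"))
  if (!is.null(seed)) set.seed(seed)
  montage <- standardMontage64()[seq_len(eeg@nChannels), , drop = FALSE]
  fs <- eeg@fsHz
  n <- floor(diff(windowMs) * fs / 1000) + 1
  times <- windowMs[1] + (seq_len(n) - 1) * 1000 / fs
  mix <- mixingVector(montage, eeg@mixingCenter, eeg@mixingSpread)
  nCh <- nrow(montage)

  makeBackground <- function(nTrials) {
    k <- 20
    arr <- array(0, c(nTrials, nCh, n))
    for (tr in seq_len(nTrials)) {
      src <- pinkNoise(n, k, fs)                      # n x k, unit RMS
      ctrs <- montage[sample.int(nCh, k, replace = TRUE), c("x", "y")]
      sprd <- stats::runif(k, 0.2, 0.6)
      A <- exp(-((outer(montage$x, ctrs$x, "-"))^2 +
                 (outer(montage$y, ctrs$y, "-"))^2) / (2 * rep(sprd, each = nCh)^2))
      A <- A / sqrt(rowSums(A^2))
      arr[tr, , ] <- A %*% t(src) +
        0.3 * matrix(stats::rnorm(nCh * n), nCh, n)
    }
    arr
  }

  stopIdx <- which(trials$trial_type == "stop")
  goIdx <- which(trials$classification == "CorrectGo")
  if (is.null(nGoEpochs)) nGoEpochs <- length(stopIdx)
  if (length(goIdx) > nGoEpochs) goIdx <- sort(sample(goIdx, nGoEpochs))

  ## stop epochs (stop-locked) with injected bursts
  stopArr <- makeBackground(length(stopIdx))
  truth <- data.frame(trial_index = trials$trial_index[stopIdx],
                      true_cancel_ms = trials$true_cancel_latency_ms[stopIdx],
                      true_burst_peak_ms = NA_real_,
                      burst_present = FALSE)
  for (j in seq_along(stopIdx)) {
    if (stats::runif(1) < eeg@burstProb) {
      lead <- stats::rnorm(1, eeg@burstLeadMean, eeg@burstLeadSd)
      jit <- stats::rnorm(1, 0, eeg@couplingJitterSd)
      tp <- truth$true_cancel_ms[j] - lead + jit
      half <- eeg@burstWidthMs / 2
      inwin <- abs(times - tp) <= half
      hann <- numeric(n)
      hann[inwin] <- 0.5 * (1 + cos(pi * (times[inwin] - tp) / half))
      carrier <- sin(2 * pi * eeg@peakBetaHz * (times - tp) / 1000 +
                     stats::runif(1, 0, 2 * pi))
      src <- eeg@snr * hann * carrier
      stopArr[j, , ] <- stopArr[j, , ] + outer(mix, src)
      truth$true_burst_peak_ms[j] <- tp
      truth$burst_present[j] <- TRUE
    }
  }
  stopInfo <- trials[stopIdx, c("trial_index", "classification", "ssd_ms")]
  stopEp <- epochSet(stopArr, fs, montage$label, montage, windowMs,
                     "stop", stopInfo)

  goEp <- NULL
  if (length(goIdx)) {
    goArr <- makeBackground(length(goIdx))
    goInfo <- trials[goIdx, c("trial_index", "classification", "ssd_ms")]
    goEp <- epochSet(goArr, fs, montage$label, montage, windowMs,
                     "go", goInfo)
  }
  list(stop = stopEp, go = goEp, truth = truth, mixing = mix)
}
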