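## Beta-burst extraction on the projected component: thresholds from a
## pooled baseline of the analytic amplitude, burst events as maximal
## suprathreshold runs, burst probability per window, and pairing of beta
## bursts with EMG-derived CancelTimes.

#' Burst-detection thresholds from pooled baselines
#'
#' Baseline analytic-amplitude samples are taken from -1000 to -500 ms
#' relative to the stop signal on stop trials, and from (mean SSD - 1000)
#' to (mean SSD - 500) ms relative to the go signal on go trials, pooled
#' across all trial types. The burst threshold is median + 1.5 SD; the
#' width threshold is median + 1 SD.
#'
#' @param ampStop matrix of stop-trial amplitude series (trials x
#'   samples), stop-locked; may be NULL.
#' @param timesStop time axis (ms) for \code{ampStop}.
#' @param ampGo,timesGo same for go trials (go-locked); may be NULL.
#' @param meanSsdMs mean stop-signal delay (ms), shifts the go-trial
#'   baseline window.
#' @param upperSd,lowerSd threshold multipliers (1.5 and 1).
#' @param minTrials minimum pooled trial count.
#' @return a \linkS4class{BurstThresholds}.
#' @export
burstThresholds <- function(ampStop = NULL, timesStop = NULL,
                            ampGo = NULL, timesGo = NULL, meanSsdMs = 0,
                            upperSd = 1.5, lowerSd = 1, minTrials = 20) {
  pool <- numeric()
  nTr <- 0
  if (!is.null(ampStop)) {
    idx <- windowIndex(timesStop, c(-1000, -500))
    pool <- c(pool, as.numeric(ampStop[, idx]))
    nTr <- nTr + nrow(ampStop)
  }
  if (!is.null(ampGo)) {
    idx <- windowIndex(timesGo, c(meanSsdMs - 1000, meanSsdMs - 500))
    pool <- c(pool, as.numeric(ampGo[, idx]))
    nTr <- nTr + nrow(ampGo)
  }
  if (nTr < minTrials)
    stop("need at least ", minTrials, " pooled trials for thresholds")
  med <- stats::median(pool)
  s <- stats::sd(pool)
  new("BurstThresholds", baselineMedian = med, baselineSd = s,
      upper = med + upperSd * s, lower = med + lowerSd * s)
}

#' Detect beta bursts in one trial
#'
#' Bursts are maximal contiguous runs of amplitude strictly above the
#' upper threshold; each yields one event with \code{burst_time_ms} at the
#' run's amplitude maximum, \code{height} the peak amplitude, and
#' \code{width_ms} the duration between the lower-threshold crossings that
#' bracket the peak (truncated, and flagged, at the epoch edges).
#'
#' @param amp amplitude series for one trial.
#' @param times time axis (ms).
#' @param thresholds a \linkS4class{BurstThresholds}.
#' @return data.frame of events: \code{burst_time_ms}, \code{width_ms},
#'   \code{height}, \code{width_truncated}; zero rows when nothing
#'   crosses.
#' @export
detectBursts <- function(amp, times, thresholds) {
  above <- amp > thresholds@upper
  if (!any(above))
    return(data.frame(burst_time_ms = numeric(), width_ms = numeric(),
                      height = numeric(), width_truncated = logical()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  n <- length(amp)
  ev <- lapply(seq_len(nrow(runs)), function(k) {
    seg <- runs[k, 1]:runs[k, 2]
    pk <- seg[which.max(amp[seg])]
    lo <- pk
    while (lo > 1 && amp[lo - 1] > thresholds@lower) lo <- lo - 1
    hi <- pk
    while (hi < n && amp[hi + 1] > thresholds@lower) hi <- hi + 1
    trunc <- (lo == 1 && amp[lo] > thresholds@lower) ||
             (hi == n && amp[hi] > thresholds@lower)
    data.frame(burst_time_ms = times[pk], width_ms = times[hi] - times[lo],
               height = amp[pk], width_truncated = trunc)
  })
  do.call(rbind, ev)
}

#' Detect beta bursts across trials
#'
#' @param ampMat matrix, trials x samples.
#' @param times time axis (ms).
#' @param thresholds a \linkS4class{BurstThresholds}.
#' @param trialIndex optional trial identifiers (default row number).
#' @return data.frame of events with a \code{trial_index} column.
#' @export
detectBurstsTrials <- function(ampMat, times, thresholds,
                               trialIndex = seq_len(nrow(ampMat))) {
  ev <- lapply(seq_len(nrow(ampMat)), function(i) {
    e <- detectBursts(ampMat[i, ], times, thresholds)
    if (nrow(e)) cbind(trial_index = trialIndex[i], e) else NULL
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev))
    ev <- data.frame(trial_index = numeric(), burst_time_ms = numeric(),
                     width_ms = numeric(), height = numeric(),
                     width_truncated = logical())
  ev
}

#' Burst probability (burst\%) in a window
#'
#' Percentage of trials containing at least one burst whose peak falls in
#' the window.
#'
#' @param events event table from \code{\link{detectBurstsTrials}}.
#' @param nTrials number of trials scanned.
#' @param window time window (ms).
#' @return percentage in [0, 100].
#' @export
burstFraction <- function(events, nTrials, window) {
  inWin <- events$burst_time_ms >= window[1] &
           events$burst_time_ms <= window[2]
  100 * length(unique(events$trial_index[inWin])) / nTrials
}

#' Per-sample burst timecourse
#'
#' For each sample, the percentage of trials whose amplitude exceeds the
#' lower threshold at that sample (the timecourse companion of
#' \code{\link{burstFraction}}).
#'
#' @param ampMat matrix, trials x samples.
#' @param thresholds a \linkS4class{BurstThresholds}.
#' @return numeric vector, percentage per sample.
#' @export
burstTimecourse <- function(ampMat, thresholds) {
  100 * colMeans(ampMat > thresholds@lower)
}

#' Mean BurstTime in a window
#'
#' Per trial, the largest-height event inside the window is kept; the mean
#' of their peak times is returned. NA (with a reason attribute) when no
#' trial qualifies.
#'
#' @param events event table from \code{\link{detectBurstsTrials}}.
#' @param window time window (ms).
#' @return mean burst time (ms), or NA with attribute \code{reason}.
#' @export
meanBurstTime <- function(events, window) {
  ev <- events[events$burst_time_ms >= window[1] &
               events$burst_time_ms <= window[2], ]
  if (!nrow(ev))
    return(structure(NA_real_, reason = "no trial with an in-window burst"))
  keep <- unlist(lapply(split(ev, ev$trial_index), function(d)
    d$burst_time_ms[which.max(d$height)]))
  mean(keep)
}

#' Pair beta bursts with EMG cancellation, per trial
#'
#' Keeps Successful Stop trials that have both an EMG burst (with a valid
#' CancelTime) and at least one beta burst whose peak lies between the
#' stop signal and the EMG decline; with several such bursts the largest
#' height wins. Emits one (BurstTime, CancelTime) pair per retained trial.
#'
#' @param burstEvents beta-burst event table (stop-locked times) with
#'   \code{trial_index}.
#' @param emgEvents data.frame with \code{trial_index},
#'   \code{classification}, \code{burst_detected}, \code{cancel_time_ms}.
#' @return data.frame: \code{trial_index}, \code{burst_time_ms},
#'   \code{cancel_time_ms}.
#' @export
pairBurstsWithEmg <- function(burstEvents, emgEvents) {
  ss <- emgEvents[emgEvents$classification == "SuccessfulStop" &
                  emgEvents$burst_detected &
                  is.finite(emgEvents$cancel_time_ms), ]
  out <- lapply(seq_len(nrow(ss)), function(i) {
    tr <- ss$trial_index[i]
    declineRelStop <- ss$cancel_time_ms[i]
    bb <- burstEvents[burstEvents$trial_index == tr &
                      burstEvents$burst_time_ms >= 0 &
                      burstEvents$burst_time_ms <= declineRelStop, ]
    if (!nrow(bb)) return(NULL)
    best <- bb[which.max(bb$height), ]
    data.frame(trial_index = tr, burst_time_ms = best$burst_time_ms,
               cancel_time_ms = declineRelStop)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(trial_index = numeric(), burst_time_ms = numeric(),
                      cancel_time_ms = numeric())
  out
}
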