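## Single-trial EMG burst landmarking and CancelTime.
##
## The detection chain is: optional 58-62 Hz zero-phase band-stop (line
## noise), 50-ms centered RMS envelope, per-trial threshold at baseline
## mean + 8 SD (baseline = fixation-to-go period of the envelope), peak =
## global maximum of suprathreshold post-go samples, onset backtracked to
## the first >=5-ms run below 20% of the peak, decline = first run of 5
## strictly decreasing milliseconds after the peak, and CancelTime =
## decline - stop on Successful Stop trials.

#' Zero-phase line-noise band-stop for EMG
#'
#' 4th-order Butterworth band-stop at 58-62 Hz applied forward and backward
#' (zero phase).
#'
#' @param samples numeric signal.
#' @param fsHz sampling rate.
#' @return filtered signal.
#' @export
emgNotch <- function(samples, fsHz = 1000) {
  bf <- signal::butter(2, c(58, 62) / (fsHz / 2), type = "stop")
  as.numeric(signal::filtfilt(bf, samples))
}

#' Centered sliding RMS envelope
#'
#' Root-mean-square over a centered window (default 50 ms); at the edges
#' the window is truncated to the available samples.
#'
#' @param samples numeric signal.
#' @param windowMs window length in ms.
#' @param fsHz sampling rate.
#' @return RMS envelope, same length as the input.
#' @examples
#' rmsEnvelope(rep(2, 200))[100]  # 2
#' @export
rmsEnvelope <- function(samples, windowMs = 50, fsHz = 1000) {
  n <- length(samples)
  w <- round(windowMs * fsHz / 1000)
  if (w %% 2 == 0) w <- w + 1
  if (n < w) stop("trace shorter than the RMS window")
  half <- (w - 1) / 2
  cs <- cumsum(c(0, samples^2))
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  sqrt((cs[hi + 1] - cs[lo + 1]) / (hi - lo))
}

#' Detect an EMG burst on one trial
#'
#' Threshold = baseline mean + 8 baseline SD, both computed on the RMS
#' envelope between the fixation and go markers; the peak is the global
#' maximum among post-go samples strictly exceeding the threshold. Returns
#' NULL when no sample crosses. A zero baseline SD falls back to
#' \code{fallbackSd} (e.g. pooled across trials) with a message.
#'
#' @param envelope RMS envelope.
#' @param fsHz sampling rate.
#' @param fixationMs,goMs baseline window markers (ms from trace start);
#'   the baseline must span at least 100 ms.
#' @param nSd threshold multiplier (8).
#' @param fallbackSd SD used when the baseline SD is exactly zero.
#' @return NULL, or list with \code{peakIdx}, \code{peakMs} (from trace
#'   start), \code{peakAmp}, \code{threshold}.
#' @export
detectEmgBurst <- function(envelope, fsHz = 1000, fixationMs, goMs,
                           nSd = 8, fallbackSd = NULL) {
  i0 <- max(1, floor(fixationMs * fsHz / 1000) + 1)
  i1 <- floor(goMs * fsHz / 1000)
  if ((i1 - i0 + 1) * 1000 / fsHz < 100)
    stop("baseline (fixation to go) must span at least 100 ms")
  base <- envelope[i0:i1]
  bSd <- stats::sd(base)
  if (bSd == 0) {
    if (is.null(fallbackSd))
      stop("zero baseline SD and no fallbackSd supplied")
    message("zero baseline SD; falling back to pooled SD")
    bSd <- fallbackSd
  }
  thr <- mean(base) + nSd * bSd
  post <- seq.int(i1 + 1, length(envelope))
  supra <- post[envelope[post] > thr]
  if (!length(supra)) return(NULL)
  peakIdx <- supra[which.max(envelope[supra])]
  list(peakIdx = peakIdx, peakMs = (peakIdx - 1) * 1000 / fsHz,
       peakAmp = envelope[peakIdx], threshold = thr)
}

#' Backtrack to the EMG burst onset
#'
#' Walking backward from the peak, the onset is the sample adjacent (on the
#' peak side) to the first run of at least \code{runMs} consecutive
#' milliseconds below 20\% of the peak amplitude. If no such run exists
#' before the go signal the onset is clamped to the go sample and flagged.
#'
#' @param envelope RMS envelope.
#' @param peakIdx peak sample index.
#' @param goIdx first sample index of the search range (the go signal).
#' @param frac onset threshold as a fraction of the peak (0.2).
#' @param runMs required run length (ms).
#' @param fsHz sampling rate.
#' @return list with \code{idx} and \code{clamped}.
#' @export
findOnset <- function(envelope, peakIdx, goIdx, frac = 0.2, runMs = 5,
                      fsHz = 1000) {
  runN <- round(runMs * fsHz / 1000)
  thr <- frac * envelope[peakIdx]
  below <- envelope < thr
  run <- 0L
  i <- peakIdx - 1L
  while (i >= goIdx) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= runN)
      return(list(idx = i + runN, clamped = FALSE))
    i <- i - 1L
  }
  list(idx = goIdx, clamped = TRUE)
}

#' Find the EMG decline after the peak
#'
#' The first sample at or after the peak that begins a run of
#' \code{runMs} strictly decreasing consecutive milliseconds; absent
#' (flagged) if no such run occurs before the end of the trace.
#'
#' @param envelope RMS envelope.
#' @param peakIdx peak sample index.
#' @param runMs run length (ms).
#' @param fsHz sampling rate.
#' @return list with \code{idx} (NA when absent) and \code{found}.
#' @export
findDecline <- function(envelope, peakIdx, runMs = 5, fsHz = 1000) {
  runN <- round(runMs * fsHz / 1000)
  dec <- diff(envelope) < 0
  i <- peakIdx
  nmax <- length(envelope) - runN
  while (i <= nmax) {
    if (all(dec[i:(i + runN - 1)]))
      return(list(idx = i, found = TRUE))
    i <- i + 1L
  }
  list(idx = NA_integer_, found = FALSE)
}

#' CancelTime from the EMG decline
#'
#' The interval between the stop signal and the decline of EMG activity on
#' a Successful Stop trial. Negative values (decline before the stop
#' signal) are excluded and returned as NA with an exclusion flag.
#'
#' @param declineMs decline time (ms, same reference as \code{stopMs}).
#' @param stopMs stop-signal time.
#' @param classification trial classification; anything but
#'   "SuccessfulStop" is an error.
#' @return list with \code{cancel_time_ms} (NA if excluded) and
#'   \code{excluded}.
#' @examples
#' cancelTime(350, 200)$cancel_time_ms  # 150
#' @export
cancelTime <- function(declineMs, stopMs,
                       classification = "SuccessfulStop") {
  if (!identical(classification, "SuccessfulStop"))
    stop("CancelTime is defined only on Successful Stop trials")
  ct <- declineMs - stopMs
  if (!is.finite(ct) || ct < 0)
    return(list(cancel_time_ms = NA_real_, excluded = TRUE))
  list(cancel_time_ms = ct, excluded = FALSE)
}

#' Landmark the EMG burst of one trial
#'
#' Full per-trial chain: optional line-noise band-stop, RMS envelope,
#' burst detection, onset backtracking, decline search and (on Successful
#' Stop trials) CancelTime.
#'
#' @param trace an \code{EmgTrace}.
#' @param classification trial classification.
#' @param notch apply the 58-62 Hz band-stop first.
#' @param windowMs RMS window (ms).
#' @param fallbackSd pooled SD fallback for zero-variance baselines.
#' @return one-row data.frame: \code{onset_ms}, \code{peak_ms},
#'   \code{decline_ms} (all relative to the go signal), \code{peak_amp},
#'   \code{cancel_time_ms}, \code{burst_detected}, \code{onset_clamped},
#'   \code{decline_found}, \code{cancel_excluded}.
#' @examples
#' out <- simulateTrial(raceParams(), ssd = 200,
#'                      forced = list(onsetMs = 230, emdMs = 135,
#'                                    cancelLatencyMs = 150))
#' emgBurstEvents(synthEmgTrace(out), "SuccessfulStop")
#' @export
emgBurstEvents <- function(trace, classification, notch = FALSE,
                           windowMs = 50, fallbackSd = NULL) {
  x <- trace$samples
  if (notch) x <- emgNotch(x, trace$fsHz)
  env <- rmsEnvelope(x, windowMs, trace$fsHz)
  mk <- trace$markers
  na <- data.frame(onset_ms = NA_real_, peak_ms = NA_real_,
                   decline_ms = NA_real_, peak_amp = NA_real_,
                   cancel_time_ms = NA_real_, burst_detected = FALSE,
                   onset_clamped = FALSE, decline_found = FALSE,
                   cancel_excluded = FALSE)
  pk <- detectEmgBurst(env, trace$fsHz, mk$fixation_ms, mk$go_ms,
                       fallbackSd = fallbackSd)
  if (is.null(pk)) return(na)
  goIdx <- floor(mk$go_ms * trace$fsHz / 1000) + 1
  on <- findOnset(env, pk$peakIdx, goIdx, fsHz = trace$fsHz)
  de <- findDecline(env, pk$peakIdx, fsHz = trace$fsHz)
  toMs <- function(idx) (idx - 1) * 1000 / trace$fsHz - mk$go_ms
  out <- na
  out$burst_detected <- TRUE
  out$onset_ms <- toMs(on$idx)
  out$onset_clamped <- on$clamped
  out$peak_ms <- toMs(pk$peakIdx)
  out$peak_amp <- pk$peakAmp
  out$decline_found <- de$found
  if (de$found) out$decline_ms <- toMs(de$idx)
  if (identical(classification, "SuccessfulStop") && de$found &&
      is.finite(mk$stop_ms)) {
    ct <- cancelTime(toMs(de$idx), mk$stop_ms - mk$go_ms, classification)
    out$cancel_time_ms <- ct$cancel_time_ms
    out$cancel_excluded <- ct$excluded
  }
  out
}

#' Normalize EMG peak amplitudes to the go-trial mean
#'
#' Peak amplitudes expressed as a percentage of the mean go-trial peak
#' amplitude, per muscle.
#'
#' @param events data.frame with \code{peak_amp}, \code{muscle} and
#'   \code{classification} columns (detected bursts only).
#' @return \code{events} with an added \code{amp_pct_go} column.
#' @export
normalizeAmplitudes <- function(events) {
  stopifnot(all(c("peak_amp", "muscle", "classification") %in%
                  names(events)))
  events$amp_pct_go <- NA_real_
  for (m in unique(events$muscle)) {
    sel <- events$muscle == m
    ref <- events$peak_amp[sel & events$classification == "CorrectGo"]
    if (!length(ref)) stop("no go-trial reference for muscle ", m)
    refMean <- mean(ref, na.rm = TRUE)
    if (!is.finite(refMean) || refMean == 0)
      stop("degenerate go-trial reference amplitude for muscle ", m)
    events$amp_pct_go[sel] <- events$peak_amp[sel] / refMean * 100
  }
  events
}
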