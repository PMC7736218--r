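## Synthetic surface-EMG traces at 1000 Hz: band-limited baseline noise
## plus, when the race leaves (part of) a motor command, a burst of
## rectified band-limited noise under a deterministic envelope. The
## envelope rises as a sublinear power of elapsed time over
## emgBurstRiseMs (rapid initial recruitment, then slower growth);
## full bursts fall linearly over emgBurstFallMs. Partial bursts on
## Successful Stop trials are truncated at the cancellation time: the
## rise time exceeds the electromechanical delay, so a truncated burst
## is still rising when cut and therefore peaks at the cancellation
## time, after which it briefly derecruits (mirroring the rise) and
## collapses.

## Band-limited (30-300 Hz) unit-variance noise: the spectral footprint of
## the surface-EMG interference pattern.
.emgBandNoise <- function(n, fsHz, band = c(30, 300)) {
  f <- (seq_len(n) - 1) * fsHz / n
  f <- pmin(f, fsHz - f)
  H <- as.numeric(f >= band[1] & f <= min(band[2], fsHz / 2))
  ph <- stats::runif(n, 0, 2 * pi)
  x <- Re(stats::fft(H * exp(1i * ph), inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize a single-trial EMG trace
#'
#' @param outcome one trial outcome (a row of the table returned by
#'   \code{\link{runStaircaseSession}}, or the list returned by
#'   \code{\link{simulateTrial}}).
#' @param emgNoiseSd baseline noise SD (mV).
#' @param riseMs,fallMs envelope rise and fall times (ms).
#' @param peakAmp full-burst peak amplitude (mV).
#' @param fsHz sampling rate; the acquisition standard is 1000 Hz.
#' @param goMs time of the go signal within the trace (ms); the preceding
#'   fixation period is the detector's baseline.
#' @param postMs trace duration after the go signal (ms).
#' @param ampJitterSd lognormal SD of the per-trial amplitude.
#' @param riseExp exponent of the recruitment power law.
#' @return an object of class \code{EmgTrace}: list with \code{samples},
#'   \code{fsHz}, \code{markers} (fixation_ms, go_ms, stop_ms) and
#'   \code{muscle}.
#' @examples
#' out <- simulateTrial(raceParams(), ssd = 200,
#'                      forced = list(onsetMs = 230, emdMs = 135,
#'                                    cancelLatencyMs = 150))
#' tr <- synthEmgTrace(out)
#' str(tr$markers)
#' @export
synthEmgTrace <- function(outcome, emgNoiseSd = 0.1, riseMs = 150,
                          fallMs = 100, peakAmp = 1, fsHz = 1000,
                          goMs = 500, postMs = 1200, ampJitterSd = 0.15,
                          riseExp = 0.35) {
  o <- as.list(outcome)
  if (!is.null(o$trial_type)) {  # data.frame row naming
    o <- list(trialType = o$trial_type, onsetMs = o$true_onset_ms,
              emdMs = o$true_emd_ms, cancelAbsMs = o$true_cancel_abs_ms,
              ssdMs = o$ssd_ms, emgPresent = o$emg_present,
              emgTruncated = o$emg_truncated, direction = o$direction)
  }
  n <- round((goMs + postMs) * fsHz / 1000)
  t <- (seq_len(n) - 1) * 1000 / fsHz  # ms from trace start
  noise <- .emgBandNoise(n, fsHz)
  env <- numeric(n)
  ## a partial motor command shorter than ~10 ms leaves no measurable
  ## surface-EMG burst above baseline; do not synthesize one
  if (isTRUE(o$emgTruncated) &&
      (o$cancelAbsMs - o$onsetMs) < 10) o$emgPresent <- FALSE
  if (isTRUE(o$emgPresent) && is.finite(o$onsetMs)) {
    onsetAbs <- goMs + o$onsetMs
    peakAbs <- if (isTRUE(o$emgTruncated)) goMs + o$cancelAbsMs
               else onsetAbs + riseMs
    rel <- (t - onsetAbs) / riseMs
    rise <- pmin(1, pmax(0, rel))^riseExp
    peakVal <- min(1, max(0, (peakAbs - onsetAbs) / riseMs))^riseExp
    if (isTRUE(o$emgTruncated)) {
      ## cancellation halts the rising motor command: gradual derecruitment
      ## (mirroring the rise) for ~25 ms, then the burst collapses; the
      ## envelope therefore peaks at the cancellation time
      mirrorMs <- 15
      collapseMs <- 30
      x <- t - peakAbs
      dur <- peakAbs - onsetAbs
      mir <- pmin(1, pmax(0, (dur - x) / riseMs))^riseExp
      v25 <- max(0, (dur - mirrorMs) / riseMs)^riseExp
      fall <- ifelse(x <= mirrorMs, mir,
                     pmax(0, v25 * (1 - (x - mirrorMs) / collapseMs)))
    } else {
      fall <- pmax(0, peakVal - (t - peakAbs) / fallMs)
    }
    env <- ifelse(t <= peakAbs, rise, pmin(fall, peakVal))
    amp <- peakAmp * exp(stats::rnorm(1, 0, ampJitterSd))
    env <- env * amp
  }
  ## rectified band-limited carrier with its short-time RMS normalized to
  ## 1: the interference pattern of many motor units is band-limited
  ## (roughly 30-300 Hz at the surface) with a stable local RMS, so the
  ## programmed envelope is what the RMS detector should see
  carrier <- abs(.emgBandNoise(n, fsHz))
  w <- 51
  cs <- cumsum(c(0, carrier^2))
  lo <- pmax(0, seq_len(n) - (w - 1) / 2 - 1)
  hi <- pmin(n, seq_len(n) + (w - 1) / 2)
  localRms <- sqrt((cs[hi + 1] - cs[lo + 1]) / (hi - lo))
  samples <- emgNoiseSd * noise + env * carrier / localRms
  markers <- list(fixation_ms = 0, go_ms = goMs,
                  stop_ms = if (o$trialType == "stop") goMs + o$ssdMs
                            else NA_real_)
  muscle <- if (identical(o$direction, "right")) "ADM" else "FDI"
  structure(list(samples = samples, fsHz = fsHz, markers = markers,
                 muscle = muscle), class = "EmgTrace")
}

#' @export
print.EmgTrace <- function(x, ...) {
  cat("EmgTrace:", length(x$samples), "samples @", x$fsHz, "Hz, muscle",
      x$muscle, "; go at", x$markers$go_ms, "ms",
      if (is.finite(x$markers$stop_ms))
        paste(", stop at", x$markers$stop_ms, "ms"), "\n")
  invisible(x)
}
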