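#' @import methods
#' @importFrom stats median sd cor fft rnorm runif rexp rbinom quantile pt pf
#'   integrate approx mvfft aggregate complete.cases setNames
#' @importFrom utils write.table read.table head tail
NULL

## Central containers are S4 with validity; tabular records (trial tables,
## burst events, paired latencies) are plain data.frames written/read as TSV.

#' Race-model parameters for the synthetic stop-signal task
#'
#' Parameters of the horse race between a go process (ex-Gaussian EMG-onset
#' latency plus an electromechanical delay to the key press) and a stop
#' process (cancellation latency after the stop signal), together with the
#' 1-up/1-down staircase that tracks the stop-signal delay (SSD).
#'
#' @slot muOn,sigmaOn,tauOn ex-Gaussian parameters (ms) of the EMG-onset
#'   latency measured from the go signal.
#' @slot emdMean,emdSd electromechanical delay EMG onset to key press (ms).
#' @slot cancelMean,cancelSd,cancelMin cancellation latency after the stop
#'   signal (ms); draws are truncated below at \code{cancelMin}.
#' @slot pGoOmission probability of a go omission.
#' @slot ssdStart,ssdStep,ssdFloor staircase start, step and floor (ms).
#' @export
setClass("RaceParams", representation(
  muOn = "numeric", sigmaOn = "numeric", tauOn = "numeric",
  emdMean = "numeric", emdSd = "numeric",
  cancelMean = "numeric", cancelSd = "numeric", cancelMin = "numeric",
  pGoOmission = "numeric",
  ssdStart = "numeric", ssdStep = "numeric", ssdFloor = "numeric"))

setValidity("RaceParams", function(object) {
  msg <- character()
  lat <- c(object@muOn, object@sigmaOn, object@tauOn, object@emdMean,
           object@emdSd, object@cancelMean, object@cancelSd)
  if (any(!is.finite(lat)) || any(lat <= 0))
    msg <- c(msg, "all latency parameters must be finite and > 0")
  if (object@cancelMin >= object@cancelMean)
    msg <- c(msg, "cancelMin must be < cancelMean")
  if (object@ssdStep <= 0) msg <- c(msg, "ssdStep must be > 0")
  if (object@pGoOmission < 0 || object@pGoOmission > 1)
    msg <- c(msg, "pGoOmission must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct race-model parameters
#'
#' Defaults are calibrated so that cohort means approximate the group means
#' reported for the task (EMG onset about 256 ms, go RT about 393 ms,
#' cancellation latency about 160 ms): onset ex-Gaussian (200, 30, 60) ms,
#' electromechanical delay 135 +/- 10 ms, cancellation 160 +/- 30 ms
#' truncated at 80 ms, 50-ms staircase starting at 200 ms with floor 0 ms.
#'
#' @param muOn,sigmaOn,tauOn ex-Gaussian onset-latency parameters (ms).
#' @param emdMean,emdSd electromechanical delay (ms).
#' @param cancelMean,cancelSd,cancelMin cancellation latency (ms).
#' @param pGoOmission go-omission probability.
#' @param ssdStart,ssdStep,ssdFloor staircase parameters (ms).
#' @return A \linkS4class{RaceParams} object.
#' @examples
#' raceParams()
#' @export
raceParams <- function(muOn = 200, sigmaOn = 30, tauOn = 60,
                       emdMean = 135, emdSd = 10,
                       cancelMean = 160, cancelSd = 30, cancelMin = 80,
                       pGoOmission = 0.01,
                       ssdStart = 200, ssdStep = 50, ssdFloor = 0) {
  new("RaceParams", muOn = muOn, sigmaOn = sigmaOn, tauOn = tauOn,
      emdMean = emdMean, emdSd = emdSd, cancelMean = cancelMean,
      cancelSd = cancelSd, cancelMin = cancelMin,
      pGoOmission = pGoOmission, ssdStart = ssdStart, ssdStep = ssdStep,
      ssdFloor = ssdFloor)
}

#' Synthetic-EEG parameters
#'
#' Parameters of the multichannel EEG generator: spatially correlated 1/f
#' background plus, on stop trials, a Hanning-windowed beta-band burst
#' injected through a right-frontal mixing vector, whose peak precedes and
#' covaries with the cancellation time.
#'
#' @slot nChannels channel count (64-channel 10/20 montage).
#' @slot fsHz sampling rate of the synthesized epochs.
#' @slot peakBetaHz subject carrier frequency (integer, within 13-25 Hz).
#' @slot burstWidthMs full width of the Hanning burst envelope (ms).
#' @slot burstProb probability that a stop trial carries a burst.
#' @slot burstLeadMean,burstLeadSd lead of the burst peak before the
#'   cancellation time (ms).
#' @slot couplingJitterSd independent per-trial jitter of the peak (ms).
#' @slot snr burst amplitude over background RMS at the source.
#' @slot mixingCenter montage label at the center of the source projection.
#' @slot mixingSpread Gaussian spatial spread of the projection (montage
#'   coordinate units).
#' @export
setClass("EegSynthParams", representation(
  nChannels = "numeric", fsHz = "numeric", peakBetaHz = "numeric",
  burstWidthMs = "numeric", burstProb = "numeric",
  burstLeadMean = "numeric", burstLeadSd = "numeric",
  couplingJitterSd = "numeric", snr = "numeric",
  mixingCenter = "character", mixingSpread = "numeric"))

setValidity("EegSynthParams", function(object) {
  msg <- character()
  if (object@burstProb < 0 || object@burstProb > 1)
    msg <- c(msg, "burstProb must lie in [0, 1]")
  if (object@peakBetaHz < 13 || object@peakBetaHz > 25)
    msg <- c(msg, "peakBetaHz must lie within the 13-25 Hz analysis band")
  if (!object@mixingCenter %in% standardMontage64()$label)
    msg <- c(msg, "mixingCenter must be a montage channel label")
  if (object@fsHz <= 2 * object@peakBetaHz)
    msg <- c(msg, "fsHz must exceed twice the carrier frequency")
  if (length(msg)) msg else TRUE
})

#' Construct synthetic-EEG parameters
#'
#' Defaults: 64 channels at 512 Hz, 18-Hz carrier, 200-ms Hanning envelope,
#' burst probability 0.5, burst peak leading the cancellation time by
#' 30 +/- 10 ms with 25-ms independent jitter, source SNR 2, mixing centered
#' on F6.
#'
#' @param nChannels,fsHz,peakBetaHz,burstWidthMs,burstProb,burstLeadMean
#'   see \linkS4class{EegSynthParams}.
#' @param burstLeadSd,couplingJitterSd,snr,mixingCenter,mixingSpread
#'   see \linkS4class{EegSynthParams}.
#' @return An \linkS4class{EegSynthParams} object.
#' @examples
#' eegSynthParams(peakBetaHz = 20)
#' @export
eegSynthParams <- function(nChannels = 64, fsHz = 512, peakBetaHz = 18,
                           burstWidthMs = 200, burstProb = 0.5,
                           burstLeadMean = 30, burstLeadSd = 10,
                           couplingJitterSd = 25, snr = 2,
                           mixingCenter = "F6", mixingSpread = 0.25) {
  new("EegSynthParams", nChannels = nChannels, fsHz = fsHz,
      peakBetaHz = peakBetaHz, burstWidthMs = burstWidthMs,
      burstProb = burstProb, burstLeadMean = burstLeadMean,
      burstLeadSd = burstLeadSd, couplingJitterSd = couplingJitterSd,
      snr = snr, mixingCenter = mixingCenter, mixingSpread = mixingSpread)
}

#' TMS-effect parameters for the synthetic cohort
#'
#' Generative stand-in for the effect of a single TMS pulse over right
#' prefrontal cortex: a Gaussian-in-time elongation of the cancellation
#' latency, maximal when the pulse coincides with the subject's beta-burst
#' center, plus a nonspecific onset slowing on all pulse trials (both coils).
#' The temporal-tuning model is an invented stand-in, not an empirical claim.
#'
#' @slot tmsTimeMs pulse latency after the stop signal (ms).
#' @slot deltaMs maximal cancellation elongation (ms).
#' @slot tuningSdMs temporal width of the elongation effect (ms).
#' @slot distractionMs onset slowing applied on all pulse trials (ms).
#' @export
setClass("TmsEffectParams", representation(
  tmsTimeMs = "numeric", deltaMs = "numeric", tuningSdMs = "numeric",
  distractionMs = "numeric"))

setValidity("TmsEffectParams", function(object) {
  msg <- character()
  if (object@deltaMs < 0) msg <- c(msg, "deltaMs must be >= 0")
  if (object@tuningSdMs <= 0) msg <- c(msg, "tuningSdMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct TMS-effect parameters
#'
#' Defaults: pulse 80 ms after the stop signal, maximal elongation 20 ms,
#' 40-ms temporal tuning, 12-ms nonspecific onset slowing.
#'
#' @param tmsTimeMs,deltaMs,tuningSdMs,distractionMs see
#'   \linkS4class{TmsEffectParams}.
#' @return A \linkS4class{TmsEffectParams} object.
#' @examples
#' tmsEffectParams()
#' @export
tmsEffectParams <- function(tmsTimeMs = 80, deltaMs = 20, tuningSdMs = 40,
                            distractionMs = 12) {
  new("TmsEffectParams", tmsTimeMs = tmsTimeMs, deltaMs = deltaMs,
      tuningSdMs = tuningSdMs, distractionMs = distractionMs)
}

#' Synthetic-cohort configuration
#'
#' Full parameterization of the synthetic cohort: counts, seed, race model,
#' EEG source model, optional TMS condition, EMG synthesis parameters and
#' between-subject dispersion. An identical configuration and seed yield a
#' bit-identical cohort.
#'
#' @slot nSubjects,nGoTrials,nStopTrials counts (per subject and session).
#' @slot seed integer RNG seed.
#' @slot race a \linkS4class{RaceParams}.
#' @slot eeg an \linkS4class{EegSynthParams}.
#' @slot tms a \linkS4class{TmsEffectParams}, or NULL for no TMS condition.
#' @slot emgNoiseSd baseline EMG noise SD (mV).
#' @slot emgBurstRiseMs,emgBurstFallMs burst envelope rise/fall times (ms).
#' @slot emgPeakAmp full-burst peak amplitude (mV).
#' @slot betweenSdMuOn,betweenSdCancel between-subject SD of the onset mu
#'   and of the cancellation mean (ms).
#' @export
setClass("CohortConfig", representation(
  nSubjects = "numeric", nGoTrials = "numeric", nStopTrials = "numeric",
  seed = "numeric", race = "RaceParams", eeg = "EegSynthParams",
  tms = "ANY", emgNoiseSd = "numeric", emgBurstRiseMs = "numeric",
  emgBurstFallMs = "numeric", emgPeakAmp = "numeric",
  betweenSdMuOn = "numeric", betweenSdCancel = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (any(c(object@nSubjects, object@nGoTrials, object@nStopTrials) <= 0))
    msg <- c(msg, "counts must be > 0")
  if (!is.null(object@tms) && !is(object@tms, "TmsEffectParams"))
    msg <- c(msg, "tms must be NULL or a TmsEffectParams")
  if (length(object@seed) != 1 || !is.finite(object@seed))
    msg <- c(msg, "seed must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a cohort configuration
#'
#' @param nSubjects,nGoTrials,nStopTrials counts; defaults mirror a single
#'   long EEG session (1440 go / 480 stop trials, i.e. 25\% stop trials).
#' @param seed integer RNG seed.
#' @param race,eeg,tms component parameter objects (\code{tms = NULL}
#'   disables the TMS condition).
#' @param emgNoiseSd,emgBurstRiseMs,emgBurstFallMs,emgPeakAmp EMG synthesis
#'   parameters; the 150-ms square-root rise exceeds the maximal
#'   electromechanical delay so partial bursts are still rising when
#'   truncated and therefore peak at the cancellation time.
#' @param betweenSdMuOn,betweenSdCancel between-subject dispersion (ms).
#' @return A \linkS4class{CohortConfig} object.
#' @examples
#' cohortConfig(nSubjects = 2, nGoTrials = 90, nStopTrials = 30)
#' @export
cohortConfig <- function(nSubjects = 10, nGoTrials = 1440, nStopTrials = 480,
                         seed = 1, race = raceParams(),
                         eeg = eegSynthParams(), tms = NULL,
                         emgNoiseSd = 0.1, emgBurstRiseMs = 150,
                         emgBurstFallMs = 100, emgPeakAmp = 1,
                         betweenSdMuOn = 20, betweenSdCancel = 15) {
  new("CohortConfig", nSubjects = nSubjects, nGoTrials = nGoTrials,
      nStopTrials = nStopTrials, seed = seed, race = race, eeg = eeg,
      tms = tms, emgNoiseSd = emgNoiseSd, emgBurstRiseMs = emgBurstRiseMs,
      emgBurstFallMs = emgBurstFallMs, emgPeakAmp = emgPeakAmp,
      betweenSdMuOn = betweenSdMuOn, betweenSdCancel = betweenSdCancel)
}

#' Epoched multichannel EEG
#'
#' Trials x channels x samples array with montage, epoch window and
#' per-trial labels. Epochs are time-locked to the stop signal on stop
#' trials and to the go signal on go trials.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot fsHz sampling rate (Hz).
#' @slot channelNames channel labels (length = dim(data)[2]).
#' @slot montage data.frame with columns label, x, y (2-D coordinates).
#' @slot windowMs numeric length-2, epoch window relative to the lock event.
#' @slot lockEvent "go" or "stop".
#' @slot trialInfo data.frame with one row per trial (classification,
#'   ssd_ms, ... as available).
#' @export
setClass("EpochSet", representation(
  data = "array", fsHz = "numeric", channelNames = "character",
  montage = "data.frame", windowMs = "numeric", lockEvent = "character",
  trialInfo = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be trials x channels x samples")
  if (length(d) == 3 && length(object@channelNames) != d[2])
    msg <- c(msg, "channelNames length must equal channel dimension")
  if (length(object@windowMs) != 2 || diff(object@windowMs) <= 0)
    msg <- c(msg, "windowMs must be an increasing length-2 window")
  if (!object@lockEvent %in% c("go", "stop"))
    msg <- c(msg, "lockEvent must be 'go' or 'stop'")
  if (length(d) == 3 && nrow(object@trialInfo) &&
      nrow(object@trialInfo) != d[1])
    msg <- c(msg, "trialInfo rows must equal trial dimension")
  if (!all(object@channelNames %in% object@montage$label))
    msg <- c(msg, "montage must cover all channels")
  if (length(msg)) msg else TRUE
})

#' @describeIn EpochSet construct an EpochSet
#' @param data,fsHz,channelNames,montage,windowMs,lockEvent,trialInfo slots.
#' @export
epochSet <- function(data, fsHz, channelNames,
                     montage = standardMontage64(),
                     windowMs, lockEvent = "stop",
                     trialInfo = data.frame()) {
  new("EpochSet", data = data, fsHz = fsHz, channelNames = channelNames,
      montage = montage, windowMs = windowMs, lockEvent = lockEvent,
      trialInfo = trialInfo)
}

#' Right-frontal spatial filter
#'
#' A channel weighting derived by generalized eigendecomposition together
#' with its activation pattern (topography), the narrowband frequency it was
#' derived at, its generalized eigenvalue and rank, the right-frontal
#' concentration score, and the validation beta-power gain.
#'
#' @slot weights unit-norm channel weight vector.
#' @slot topography activation pattern (signal covariance times weights),
#'   sign-fixed so its largest-magnitude entry is positive.
#' @slot channelNames channel labels.
#' @slot freqHz narrowband center frequency the filter was derived at.
#' @slot eigenvalue generalized eigenvalue.
#' @slot rank position in descending-eigenvalue order (1 = first).
#' @slot rfScore right-frontal concentration score.
#' @slot betaGainDb validation power increase (dB), stop-to-SSRT window
#'   versus pre-go baseline.
#' @export
setClass("SpatialFilter", representation(
  weights = "numeric", topography = "numeric", channelNames = "character",
  freqHz = "numeric", eigenvalue = "numeric", rank = "numeric",
  rfScore = "numeric", betaGainDb = "numeric"))

setValidity("SpatialFilter", function(object) {
  msg <- character()
  if (any(!is.finite(object@weights))) msg <- c(msg, "weights must be finite")
  if (abs(sqrt(sum(object@weights^2)) - 1) > 1e-6)
    msg <- c(msg, "weights must have unit norm")
  if (length(object@weights) != length(object@topography))
    msg <- c(msg, "weights and topography lengths differ")
  if (object@rank < 1) msg <- c(msg, "rank must be >= 1")
  mx <- which.max(abs(object@topography))
  if (length(mx) && object@topography[mx] < 0)
    msg <- c(msg, "topography sign must make the maximal entry positive")
  if (length(msg)) msg else TRUE
})

#' Beta-burst detection thresholds
#'
#' Baseline-amplitude statistics pooled across all trial types, and the
#' derived burst thresholds: upper = median + 1.5 SD (burst definition),
#' lower = median + 1 SD (width measurement).
#'
#' @slot baselineMedian,baselineSd pooled baseline amplitude statistics.
#' @slot upper,lower derived thresholds.
#' @export
setClass("BurstThresholds", representation(
  baselineMedian = "numeric", baselineSd = "numeric",
  upper = "numeric", lower = "numeric"))

setValidity("BurstThresholds", function(object) {
  msg <- character()
  if (object@lower > object@upper) msg <- c(msg, "lower must be <= upper")
  if (object@upper < object@baselineMedian ||
      object@lower < object@baselineMedian)
    msg <- c(msg, "thresholds must be >= baselineMedian")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "RaceParams", function(object) {
  cat("RaceParams: onset exGauss(", object@muOn, ",", object@sigmaOn, ",",
      object@tauOn, ") ms; EMD", object@emdMean, "+/-", object@emdSd,
      "ms; cancel", object@cancelMean, "+/-", object@cancelSd,
      "ms (min", object@cancelMin, "); SSD start/step/floor",
      object@ssdStart, "/", object@ssdStep, "/", object@ssdFloor, "ms\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nSubjects, "subjects x (",
      object@nGoTrials, "go +", object@nStopTrials, "stop ) trials; seed",
      object@seed, if (is.null(object@tms)) "; no TMS condition\n"
      else "; TMS condition enabled\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", object@fsHz, "Hz; window [", object@windowMs[1], ",",
      object@windowMs[2], "] ms locked to", object@lockEvent, "\n")
})

setMethod("show", "SpatialFilter", function(object) {
  cat("SpatialFilter @", object@freqHz, "Hz: eigenvalue",
      signif(object@eigenvalue, 4), ", rank", object@rank,
      ", rf score", signif(object@rfScore, 3), ", beta gain",
      signif(object@betaGainDb, 3), "dB\n")
})

setMethod("show", "BurstThresholds", function(object) {
  cat("BurstThresholds: median", signif(object@baselineMedian, 4), "SD",
      signif(object@baselineSd, 4), "-> upper", signif(object@upper, 4),
      ", lower", signif(object@lower, 4), "\n")
})

## ---- accessors ----

#' Epoch data array
#' @param x an EpochSet
#' @return the trials x channels x samples array
#' @export
epochData <- function(x) x@data

#' Channel labels
#' @param x an EpochSet or SpatialFilter
#' @return character vector of channel labels
#' @export
channelNames <- function(x) x@channelNames

#' Sampling rate in Hz
#' @param x an EpochSet
#' @return sampling rate (Hz)
#' @export
samplingRate <- function(x) x@fsHz

#' Epoch sample times
#' @param x an EpochSet
#' @return numeric vector of sample times (ms, relative to the lock event)
#' @export
epochTimes <- function(x) {
  n <- dim(x@data)[3]
  x@windowMs[1] + (seq_len(n) - 1) * 1000 / x@fsHz
}

#' Per-trial metadata
#' @param x an EpochSet
#' @return data.frame of per-trial metadata
#' @export
trialInfo <- function(x) x@trialInfo

#' Spatial-filter weights
#' @param x a SpatialFilter
#' @return numeric weight vector (unit norm)
#' @export
filterWeights <- function(x) x@weights

#' Spatial-filter topography (activation pattern)
#' @param x a SpatialFilter
#' @return numeric topography vector
#' @export
filterTopography <- function(x) x@topography
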