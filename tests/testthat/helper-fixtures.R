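## Shared fixtures, generated once per test run and memoized.

.fx <- new.env(parent = emptyenv())

## One synthetic subject with EEG epochs: 30 go / 40 stop trials, fixed
## seeds. Used by the spatial-filter and beta-burst suites.
eegSubjectFixture <- function() {
  if (is.null(.fx$eegSubject)) {
    trials <- runStaircaseSession(raceParams(), nGo = 30, nStop = 40,
                                  seed = 301)
    eeg <- synthEegEpochs(trials, eegSynthParams(peakBetaHz = 18),
                          seed = 302)
    beh <- summarizeBehavior(trials)
    .fx$eegSubject <- list(trials = trials, eeg = eeg, beh = beh)
  }
  .fx$eegSubject
}

## Preprocessed Successful Stop epochs plus the selected spatial filter.
selectedFilterFixture <- function() {
  if (is.null(.fx$filter)) {
    sub <- eegSubjectFixture()
    pp <- preprocessEpochs(sub$eeg$stop, fsTarget = sub$eeg$stop@fsHz)
    info <- trialInfo(pp)
    ssIdx <- which(info$classification == "SuccessfulStop")
    ssEp <- epochSet(epochData(pp)[ssIdx, , , drop = FALSE], pp@fsHz,
                     channelNames(pp), pp@montage, pp@windowMs, "stop",
                     info[ssIdx, ])
    filt <- selectSpatialFilter(ssEp, ssrtMs = sub$beh$ssrt)
    .fx$filter <- list(pp = pp, ssEp = ssEp, filt = filt, ssIdx = ssIdx)
  }
  .fx$filter
}

## Collect CancelTime recovery pairs (true, detected) from the default
## generator at a fixed SSD.
cancelRecoveryPairs <- function(nTrials, seed, ssd = 170) {
  set.seed(seed)
  tru <- numeric(); det <- numeric(); i <- 0
  while (length(tru) < nTrials && i < 30 * nTrials) {
    i <- i + 1
    out <- simulateTrial(raceParams(), ssd = ssd)
    if (out$classification == "SuccessfulStop" && out$emgPresent) {
      ev <- emgBurstEvents(synthEmgTrace(out), "SuccessfulStop")
      if (ev$burst_detected && is.finite(ev$cancel_time_ms)) {
        tru <- c(tru, out$cancelLatencyMs)
        det <- c(det, ev$cancel_time_ms)
      }
    }
  }
  data.frame(true = tru, detected = det)
}
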