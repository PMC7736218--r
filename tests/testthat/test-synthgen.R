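test_that("race classification follows the relative finish times", {
  race <- raceParams()
  ## cancellation beats the motor command entirely: no EMG
  a <- simulateTrial(race, ssd = 0,
                     forced = list(onsetMs = 300, cancelLatencyMs = 250,
                                   emdMs = 135))
  expect_equal(a$classification, "SuccessfulStop")
  expect_false(a$emgPresent)
  ## cancellation lands between EMG onset and key press: partial burst
  b <- simulateTrial(race, ssd = 0,
                     forced = list(onsetMs = 200, emdMs = 135,
                                   cancelLatencyMs = 250))
  expect_equal(b$classification, "SuccessfulStop")
  expect_true(b$emgPresent && b$emgTruncated)
  expect_equal(b$cancelAbsMs, 250)
  ## cancellation arrives after the key press: failed stop
  cc <- simulateTrial(race, ssd = 0,
                      forced = list(onsetMs = 100, emdMs = 135,
                                    cancelLatencyMs = 300))
  expect_equal(cc$classification, "FailedStop")
  expect_equal(cc$keypressMs, 235)
  ## go trials: key press unless omitted
  g <- simulateTrial(race, forced = list(onsetMs = 250, emdMs = 135,
                                         omitted = FALSE))
  expect_equal(g$classification, "CorrectGo")
  expect_equal(g$keypressMs, 385)
  om <- simulateTrial(race, forced = list(omitted = TRUE))
  expect_equal(om$classification, "GoOmission")
  expect_true(is.na(om$keypressMs))
})

test_that("staircase steps 50 ms up after success, down after failure, with floor", {
  ## a race the stop process always wins: every stop trial succeeds
  alwaysStop <- raceParams(muOn = 3000, cancelMean = 100, cancelSd = 1,
                           cancelMin = 50)
  tr <- runStaircaseSession(alwaysStop, nGo = 4, nStop = 12, seed = 21)
  st <- tr[tr$trial_type == "stop", ]
  for (d in c("left", "right")) {
    s <- st[st$direction == d, ]
    if (nrow(s) >= 2)
      expect_equal(diff(s$ssd_ms), rep(50, nrow(s) - 1))
  }
  expect_equal(st$ssd_ms[1], 200)
  ## a race the go process always wins: SSD clamps at the floor
  alwaysGo <- raceParams(muOn = 60, sigmaOn = 1, tauOn = 1, emdMean = 50,
                         emdSd = 1, cancelMean = 2000, cancelSd = 1,
                         cancelMin = 1000)
  tr2 <- runStaircaseSession(alwaysGo, nGo = 4, nStop = 16, seed = 22)
  st2 <- tr2[tr2$trial_type == "stop", ]
  expect_true(all(st2$ssd_ms >= 0))
  expect_true(any(st2$ssd_ms == 0))
  expect_true(all(st2$classification == "FailedStop"))
})

test_that("the 1-up/1-down staircase converges to 50% stopping", {
  tr <- runStaircaseSession(raceParams(), nGo = 1500, nStop = 500,
                            seed = 23)
  st <- tr[tr$trial_type == "stop", ]
  expect_gt(100 * mean(st$classification == "SuccessfulStop"), 46)
  expect_lt(100 * mean(st$classification == "SuccessfulStop"), 54)
})

test_that("failed-stop RTs are faster than go RTs (race truncation)", {
  tr <- runStaircaseSession(raceParams(), nGo = 600, nStop = 200,
                            seed = 24)
  fs <- tr$rt_ms[tr$classification == "FailedStop"]
  go <- tr$rt_ms[tr$classification == "CorrectGo"]
  expect_gt(length(fs), 50)
  expect_lt(mean(fs), mean(go))
})

test_that("identical config and seed give a bit-identical cohort", {
  cfg <- cohortConfig(nSubjects = 1, nGoTrials = 20, nStopTrials = 8,
                      seed = 99)
  a <- simulateSubject(cfg, 1, eegEpochs = FALSE)
  b <- simulateSubject(cfg, 1, eegEpochs = FALSE)
  expect_identical(a$conditions$none$trials, b$conditions$none$trials)
  expect_identical(a$conditions$none$emg[[3]]$samples,
                   b$conditions$none$emg[[3]]$samples)
})

test_that("signal-free EMG traces stay below the 8-SD threshold as often as a noise oracle", {
  ## detector on EMG-free successful stops
  set.seed(25)
  nTr <- 150
  hits <- replicate(nTr, {
    out <- simulateTrial(raceParams(), ssd = 300,
                         forced = list(onsetMs = 500, emdMs = 135,
                                       cancelLatencyMs = 90))
    ev <- emgBurstEvents(synthEmgTrace(out), "SuccessfulStop")
    ev$burst_detected
  })
  ## brute-force oracle: same noise model, independent RMS/threshold code
  oracleHits <- replicate(nTr, {
    x <- 0.1 * stopBeta:::.emgBandNoise(1700, 1000)
    env <- sapply(seq_along(x), function(i) {
      w <- max(1, i - 25):min(length(x), i + 25)
      sqrt(mean(x[w]^2))
    })
    thr <- mean(env[1:500]) + 8 * sd(env[1:500])
    any(env[501:length(env)] > thr)
  })
  ## binomial tolerance around the oracle rate
  pOracle <- mean(oracleHits)
  tol <- 3 * sqrt(max(pOracle, 1 / nTr) * (1 - pOracle) / nTr) + 2 / nTr
  expect_lt(abs(mean(hits) - pOracle), tol + 0.02)
})

test_that("noiseless full bursts are landmarked close to the programmed onset", {
  set.seed(26)
  out <- simulateTrial(raceParams(),
                       forced = list(onsetMs = 250, emdMs = 135,
                                     omitted = FALSE))
  errs <- replicate(10, {
    tr <- synthEmgTrace(out, emgNoiseSd = 0)
    ev <- suppressMessages(
      emgBurstEvents(tr, "CorrectGo", fallbackSd = 1e-8))
    ev$onset_ms - 250
  })
  ## centered 50-ms RMS window displaces the 20%-of-peak crossing by at
  ## most ~half the window for a smooth recruitment envelope
  expect_true(all(abs(errs) <= 20))
})

test_that("EEG ground truth is row-aligned and burst injection follows burstProb", {
  sub <- eegSubjectFixture()
  truth <- sub$eeg$truth
  stopInfo <- trialInfo(sub$eeg$stop)
  expect_equal(truth$trial_index, stopInfo$trial_index)
  expect_equal(nrow(truth), dim(epochData(sub$eeg$stop))[1])
  ## no bursts when burstProb = 0
  tr <- runStaircaseSession(raceParams(), nGo = 6, nStop = 6, seed = 27)
  ep0 <- synthEegEpochs(tr, eegSynthParams(burstProb = 0), seed = 28)
  expect_true(all(!ep0$truth$burst_present))
})

test_that("injected burst peaks track the cancellation time by construction", {
  ## default lead/jitter: positive rank correlation in every subject
  for (s in 1:4) {
    tr <- runStaircaseSession(raceParams(), nGo = 10, nStop = 60,
                              seed = 400 + s)
    ep <- synthEegEpochs(tr, eegSynthParams(), seed = 500 + s,
                         nGoEpochs = 0)
    tru <- ep$truth[ep$truth$burst_present, ]
    expect_gt(nrow(tru), 10)
    expect_gt(cor(tru$true_burst_peak_ms, tru$true_cancel_ms,
                  method = "spearman"), 0)
  }
})

test_that("high-SNR jitter-free injected bursts are recovered at the injected peak", {
  tr <- runStaircaseSession(raceParams(), nGo = 10, nStop = 30, seed = 29)
  eegp <- eegSynthParams(snr = 40, couplingJitterSd = 0,
                         burstLeadSd = 0, burstProb = 1, peakBetaHz = 20)
  ep <- synthEegEpochs(tr, eegp, seed = 30, nGoEpochs = 0)
  ## project onto the true mixing and detect bursts
  comp <- projectEpochs(ep$stop, ep$mixing / sqrt(sum(ep$mixing^2)))
  times <- epochTimes(ep$stop)
  amp <- t(analyticAmplitude(gaussianBandpass(t(comp), 512, 20)))
  thr <- burstThresholds(amp, times, minTrials = 20)
  ev <- detectBurstsTrials(amp, times, thr,
                           trialInfo(ep$stop)$trial_index)
  truth <- ep$truth
  errs <- vapply(seq_len(nrow(truth)), function(j) {
    e <- ev[ev$trial_index == truth$trial_index[j], ]
    if (!nrow(e)) return(NA_real_)
    min(abs(e$burst_time_ms - truth$true_burst_peak_ms[j]))
  }, 0)
  expect_gt(mean(!is.na(errs)), 0.95)
  ## within one carrier period (50 ms at 20 Hz)
  expect_lt(median(errs, na.rm = TRUE), 50)
})

test_that("the TMS effect model is exact at the tuning center and null at delta 0", {
  race <- raceParams()
  out <- simulateTrial(race, ssd = 200,
                       forced = list(onsetMs = 240, emdMs = 135,
                                     cancelLatencyMs = 150))
  ## pulse exactly at the burst center: elongation equals deltaMs
  tms <- tmsEffectParams(tmsTimeMs = 80, deltaMs = 25, distractionMs = 0)
  mod <- applyTmsEffect(out, tms, "real", burstCenterMs = 80, race = race)
  expect_equal(mod$cancelLatencyMs, 175)
  ## delta 0, no distraction: latents unchanged for both coils
  tms0 <- tmsEffectParams(deltaMs = 0, distractionMs = 0)
  for (coil in c("real", "sham")) {
    same <- applyTmsEffect(out, tms0, coil, burstCenterMs = 80,
                           race = race)
    expect_equal(same$cancelLatencyMs, out$cancelLatencyMs)
    expect_equal(same$onsetMs, out$onsetMs)
    expect_equal(same$classification, out$classification)
  }
  ## sham never elongates; distraction shifts onset for both coils
  tms2 <- tmsEffectParams(deltaMs = 25, distractionMs = 10)
  sham <- applyTmsEffect(out, tms2, "sham", burstCenterMs = 80,
                         race = race)
  expect_equal(sham$cancelLatencyMs, out$cancelLatencyMs)
  expect_equal(sham$onsetMs, out$onsetMs + 10)
})
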