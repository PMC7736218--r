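rayAmp <- function(nTr, n, sigma = 1, seed = 71) {
  set.seed(seed)
  matrix(sigma * sqrt(rexp(nTr * n, 1 / 2)), nTr, n)  # Rayleigh(sigma)
}

test_that("burst thresholds pool the stated baseline windows", {
  times <- seq(-1500, 1500, by = 2)
  n <- length(times)
  ## constant amplitude: median c, SD 0, both thresholds c
  thr <- burstThresholds(matrix(3, 25, n), times, minTrials = 20)
  expect_equal(thr@baselineMedian, 3)
  expect_equal(thr@baselineSd, 0)
  expect_equal(thr@upper, 3)
  expect_equal(thr@lower, 3)
  ## matches an independently-indexed median/SD computation
  amp <- rayAmp(30, n)
  ampGo <- rayAmp(20, n, seed = 72)
  meanSsd <- 180
  got <- burstThresholds(amp, times, ampGo, times, meanSsd)
  oracle <- c(amp[, times >= -1000 & times <= -500],
              ampGo[, times >= meanSsd - 1000 & times <= meanSsd - 500])
  expect_equal(got@baselineMedian, median(oracle))
  expect_equal(got@upper, median(oracle) + 1.5 * sd(oracle))
  expect_equal(got@lower, median(oracle) + 1 * sd(oracle))
  ## scale equivariance
  got2 <- burstThresholds(2 * amp, times, 2 * ampGo, times, meanSsd)
  expect_equal(got2@baselineMedian, 2 * got@baselineMedian)
  expect_equal(got2@upper, 2 * got@upper)
  ## Monte-Carlo oracle of the same distribution within 2%
  bigRay <- sqrt(rexp(2e5, 1 / 2))
  expect_lt(abs(got@baselineMedian / (median(bigRay)) - 1), 0.02)
  expect_error(burstThresholds(amp[1:5, ], times), "pooled trials")
  expect_error(burstThresholds(amp, times - 5000), "outside")
})

test_that("bursts are maximal suprathreshold runs with bracketed widths", {
  times <- 0:999
  thr <- new("BurstThresholds", baselineMedian = 1, baselineSd = 1,
             upper = 2.5, lower = 2)
  amp <- rep(1, 1000)
  ## single Hanning-like burst well above threshold
  amp[300:400] <- 1 + 4 * sin(pi * (0:100) / 100)
  ev <- detectBursts(amp, times, thr)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$burst_time_ms - 350), 2)
  expect_equal(ev$height, max(amp))
  ## width between the lower-threshold crossings around the peak
  expect_equal(ev$width_ms,
               times[max(which(amp > 2))] - times[min(which(amp > 2))])
  expect_false(ev$width_truncated)
  ## two bursts separated by a sub-lower gap
  amp2 <- rep(1, 1000)
  amp2[200:250] <- 4
  amp2[400:450] <- 5
  ev2 <- detectBursts(amp2, times, thr)
  expect_equal(nrow(ev2), 2)
  ## everything below the upper threshold: empty
  expect_equal(nrow(detectBursts(rep(2.2, 1000), times, thr)), 0)
  ## epoch-edge truncation flagged
  amp3 <- c(rep(4, 100), rep(1, 900))
  ev3 <- detectBursts(amp3, times, thr)
  expect_true(ev3$width_truncated[1])
})

test_that("burst detection is idempotent, order-independent and threshold-monotone", {
  times <- seq(-1500, 1500, by = 2)
  amp <- rayAmp(40, length(times), seed = 73)
  thr <- burstThresholds(amp, times)
  ev1 <- detectBurstsTrials(amp, times, thr)
  ev2 <- detectBurstsTrials(amp, times, thr)
  expect_identical(ev1, ev2)
  perm <- sample(nrow(amp))
  evP <- detectBurstsTrials(amp[perm, ], times, thr,
                            trialIndex = perm)
  evPs <- evP[order(evP$trial_index, evP$burst_time_ms), ]
  ev1s <- ev1[order(ev1$trial_index, ev1$burst_time_ms), ]
  rownames(evPs) <- rownames(ev1s) <- NULL
  expect_equal(evPs, ev1s)
  ## events never overlap within a trial
  for (tr in unique(ev1$trial_index)) {
    e <- ev1[ev1$trial_index == tr, ]
    if (nrow(e) > 1) {
      e <- e[order(e$burst_time_ms), ]
      expect_true(all(diff(e$burst_time_ms) > 0))
    }
  }
  ## raising the upper threshold never increases the event count
  thrHi <- new("BurstThresholds", baselineMedian = thr@baselineMedian,
               baselineSd = thr@baselineSd, upper = thr@upper * 1.3,
               lower = thr@lower)
  expect_lte(nrow(detectBurstsTrials(amp, times, thrHi)), nrow(ev1))
})

test_that("burst fraction and mean BurstTime follow the window rules", {
  ev <- data.frame(trial_index = c(1, 1, 2, 3),
                   burst_time_ms = c(50, 400, 120, -600),
                   width_ms = 100, height = c(3, 5, 4, 2),
                   width_truncated = FALSE)
  expect_equal(burstFraction(ev, 4, c(0, 200)), 50)
  expect_equal(burstFraction(ev, 4, c(-2000, 2000)), 75)
  expect_equal(burstFraction(ev[0, ], 4, c(0, 200)), 0)
  ## per-trial largest height wins; mean over trials
  ev2 <- data.frame(trial_index = c(1, 2, 3),
                    burst_time_ms = c(100, 120, 140), width_ms = 80,
                    height = c(1, 2, 3), width_truncated = FALSE)
  expect_equal(meanBurstTime(ev2, c(0, 300)), 120)
  expect_equal(meanBurstTime(ev2[2, ], c(0, 300)), 120)
  ev3 <- rbind(ev2, data.frame(trial_index = 1, burst_time_ms = 200,
                               width_ms = 80, height = 9,
                               width_truncated = FALSE))
  ## trial 1 now contributes its taller 200-ms burst
  expect_equal(meanBurstTime(ev3, c(0, 300)), mean(c(200, 120, 140)))
  out <- meanBurstTime(ev2, c(400, 500))
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "no trial")
})

test_that("beta bursts pair with EMG cancellation on the same trial", {
  emg <- data.frame(trial_index = 1:4,
                    classification = c("SuccessfulStop", "SuccessfulStop",
                                       "FailedStop", "SuccessfulStop"),
                    burst_detected = c(TRUE, TRUE, TRUE, FALSE),
                    cancel_time_ms = c(150, 140, NA, 160))
  bb <- data.frame(trial_index = c(1, 1, 2, 3),
                   burst_time_ms = c(110, 60, 200, 100),
                   width_ms = 80, height = c(5, 7, 3, 2),
                   width_truncated = FALSE)
  pr <- pairBurstsWithEmg(bb, emg)
  ## trial 1: two in-window bursts, the taller (60 ms) wins
  expect_equal(pr$burst_time_ms[pr$trial_index == 1], 60)
  expect_equal(pr$cancel_time_ms[pr$trial_index == 1], 150)
  ## trial 2: burst after the EMG decline only -> excluded
  expect_false(2 %in% pr$trial_index)
  ## failed stop and no-EMG trials excluded
  expect_false(any(c(3, 4) %in% pr$trial_index))
})

test_that("burst recovery at default SNR and monotone SNR response", {
  sub <- eegSubjectFixture()
  fx <- selectedFilterFixture()
  times <- epochTimes(fx$pp)
  comp <- projectEpochs(fx$pp, fx$filt)
  amp <- t(analyticAmplitude(gaussianBandpass(t(comp), 512, 18)))
  thr <- burstThresholds(amp, times, meanSsdMs = sub$beh$mean_ssd)
  ev <- detectBurstsTrials(amp, times, thr,
                           trialInfo(fx$pp)$trial_index)
  truth <- sub$eeg$truth[sub$eeg$truth$burst_present, ]
  errs <- vapply(seq_len(nrow(truth)), function(j) {
    e <- ev[ev$trial_index == truth$trial_index[j] &
            abs(ev$burst_time_ms - truth$true_burst_peak_ms[j]) < 150, ]
    if (!nrow(e)) return(NA_real_)
    min(abs(e$burst_time_ms - truth$true_burst_peak_ms[j]))
  }, 0)
  expect_gte(mean(!is.na(errs)), 0.9)
  expect_lt(median(errs, na.rm = TRUE), 25)
  ## lowering SNR monotonically lowers the detection rate
  rates <- vapply(c(2, 0.8, 0.3), function(s) {
    tr <- runStaircaseSession(raceParams(), nGo = 6, nStop = 30,
                              seed = 74)
    ep <- synthEegEpochs(tr, eegSynthParams(snr = s, burstProb = 1,
                                            peakBetaHz = 18),
                         seed = 75, nGoEpochs = 0)
    tms <- epochTimes(ep$stop)
    cp <- projectEpochs(ep$stop, ep$mixing / sqrt(sum(ep$mixing^2)))
    am <- t(analyticAmplitude(gaussianBandpass(t(cp), 512, 18)))
    th <- burstThresholds(am, tms, minTrials = 20)
    e <- detectBurstsTrials(am, tms, th, trialInfo(ep$stop)$trial_index)
    tu <- ep$truth[ep$truth$burst_present, ]
    mean(vapply(seq_len(nrow(tu)), function(j) {
      any(e$trial_index == tu$trial_index[j] &
            abs(e$burst_time_ms - tu$true_burst_peak_ms[j]) < 100)
    }, TRUE))
  }, 0)
  expect_true(all(diff(rates) <= 0))
})

test_that("the burst timecourse is the per-sample suprathreshold fraction", {
  times <- 0:99
  thr <- new("BurstThresholds", baselineMedian = 1, baselineSd = 1,
             upper = 2.5, lower = 2)
  amp <- rbind(rep(1, 100), rep(3, 100))
  expect_equal(burstTimecourse(amp, thr), rep(50, 100))
})
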