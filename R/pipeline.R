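## Orchestration: per-subject EMG and EEG analysis chains, the cohort-level
## run, report tables and the fixture generator.

## Polynomial rolling hash of a string, for the run manifest.
.configHash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Analyze one subject's EMG
#'
#' Runs the burst-landmarking chain on every trial and merges the detected
#' events with the trial table; amplitudes are normalized to the go-trial
#' mean per muscle.
#'
#' @param trials trial table.
#' @param emg list of \code{EmgTrace}, row-aligned with \code{trials}.
#' @param notch apply the line-noise band-stop.
#' @return data.frame: trial columns plus the \code{\link{emgBurstEvents}}
#'   columns, \code{muscle} and \code{amp_pct_go}.
#' @export
analyzeSubjectEmg <- function(trials, emg, notch = FALSE) {
  ev <- do.call(rbind, lapply(seq_along(emg), function(i)
    emgBurstEvents(emg[[i]], trials$classification[i], notch = notch)))
  ev$muscle <- vapply(emg, function(tr) tr$muscle, "")
  out <- cbind(trials, ev)
  out$amp_pct_go <- NA_real_
  det <- out$burst_detected & is.finite(out$peak_amp)
  if (any(det & out$classification == "CorrectGo"))
    out[det, ] <- normalizeAmplitudes(out[det, ])
  out
}

#' Analyze one subject's EEG
#'
#' Preprocessing, GED spatial-filter selection on Successful Stop epochs,
#' projection, Morlet peak-beta selection in the stop-to-SSRT window,
#' narrowband analytic amplitude at the peak frequency, pooled burst
#' thresholds, burst detection, burst probabilities per window and trial
#' type, and mean BurstTime.
#'
#' @param eegResult \code{\link{synthEegEpochs}} output (or a list with
#'   \code{stop} and \code{go} EpochSets).
#' @param ssrtMs the session's integration-method SSRT.
#' @param meanSsdMs mean stop-signal delay.
#' @param preprocess run \code{\link{preprocessEpochs}} first.
#' @return list: \code{filter} (NULL when no right-frontal component),
#'   \code{peakFreqHz}, \code{thresholds}, \code{events} (stop-locked
#'   beta-burst events over stop trials), \code{eventsGo},
#'   \code{burstPct} (data.frame per trial type and window),
#'   \code{meanBurstTimeMs}, \code{ampStop}, \code{timesStop}.
#' @export
analyzeSubjectEeg <- function(eegResult, ssrtMs, meanSsdMs,
                              preprocess = TRUE) {
  stopEp <- eegResult$stop
  goEp <- eegResult$go
  if (preprocess) {
    stopEp <- preprocessEpochs(stopEp, fsTarget = stopEp@fsHz)
    if (!is.null(goEp)) goEp <- preprocessEpochs(goEp, fsTarget = goEp@fsHz)
  }
  info <- trialInfo(stopEp)
  ssIdx <- which(info$classification == "SuccessfulStop")
  ssEp <- epochSet(stopEp@data[ssIdx, , , drop = FALSE], stopEp@fsHz,
                   stopEp@channelNames, stopEp@montage, stopEp@windowMs,
                   "stop", info[ssIdx, ])
  filt <- selectSpatialFilter(ssEp, ssrtMs)
  if (is.null(filt))
    return(list(filter = NULL, reason = "no right-frontal component"))
  times <- epochTimes(stopEp)
  compStop <- projectEpochs(stopEp, filt)
  tfr <- morletTfr(compStop[ssIdx, , drop = FALSE], stopEp@fsHz, times,
                   baselineWin = c(-meanSsdMs - 500, -meanSsdMs - 200))
  fPeak <- peakBetaFrequency(tfr, c(0, max(ssrtMs, 100)))
  ampStop <- t(analyticAmplitude(
    gaussianBandpass(t(compStop), stopEp@fsHz, as.numeric(fPeak))))
  ampGo <- NULL; timesGo <- NULL
  if (!is.null(goEp)) {
    compGo <- projectEpochs(goEp, filt)
    ampGo <- t(analyticAmplitude(
      gaussianBandpass(t(compGo), goEp@fsHz, as.numeric(fPeak))))
    timesGo <- epochTimes(goEp)
  }
  thr <- burstThresholds(ampStop, times, ampGo, timesGo, meanSsdMs)
  events <- detectBurstsTrials(ampStop, times, thr, info$trial_index)
  stopWin <- c(0, max(ssrtMs, 100))
  baseWin <- c(-meanSsdMs, 0)
  cls <- info$classification
  pct <- list()
  for (lab in c("SuccessfulStop", "FailedStop")) {
    sel <- info$trial_index[cls == lab]
    ev <- events[events$trial_index %in% sel, ]
    pct[[length(pct) + 1]] <- data.frame(
      trial_type = lab,
      stop_win_pct = burstFraction(ev, length(sel), stopWin),
      base_win_pct = burstFraction(ev, length(sel), baseWin))
  }
  eventsGo <- NULL
  if (!is.null(ampGo)) {
    infoGo <- trialInfo(goEp)
    eventsGo <- detectBurstsTrials(ampGo, timesGo, thr,
                                   infoGo$trial_index)
    pct[[length(pct) + 1]] <- data.frame(
      trial_type = "CorrectGo",
      stop_win_pct = burstFraction(eventsGo, nrow(infoGo),
                                   stopWin + meanSsdMs),
      base_win_pct = burstFraction(eventsGo, nrow(infoGo),
                                   c(0, meanSsdMs)))
  }
  list(filter = filt, peakFreqHz = as.numeric(fPeak), thresholds = thr,
       events = events, eventsGo = eventsGo,
       burstPct = do.call(rbind, pct),
       meanBurstTimeMs = meanBurstTime(
         events[events$trial_index %in%
                  info$trial_index[cls == "SuccessfulStop"], ], stopWin),
       ampStop = ampStop, timesStop = times)
}

#' Run the full analysis on a synthetic cohort
#'
#' Generates (or re-analyzes) each subject, runs behavior, EMG, EEG and
#' (when configured) the TMS contrast, and assembles the report tables.
#' Deterministic given the configuration seed. When \code{outDir} is
#' given, all tables plus a manifest (configuration hash, seed, package
#' version) are written as TSV/JSON.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param outDir optional output directory.
#' @param eeg analyze EEG (non-TMS configurations only).
#' @param verbose print per-subject progress.
#' @return list with \code{subjects} (per-subject summary data.frame),
#'   \code{pairs} (pooled BurstTime/CancelTime pairs), \code{rmcorr},
#'   \code{groupStats} (data.frame of group-level tests), and, for TMS
#'   configurations, \code{tms} (per-subject contrast table).
#' @export
runAll <- function(config, outDir = NULL, eeg = is.null(config@tms),
                   verbose = FALSE) {
  subjects <- list(); pairsAll <- list(); tmsRows <- list()
  for (s in seq_len(config@nSubjects)) {
    if (verbose) message("subject ", s)
    sub <- simulateSubject(config, s, eegEpochs = eeg)
    conds <- names(sub$conditions)
    condRes <- list()
    for (cond in conds) {
      res <- sub$conditions[[cond]]
      beh <- summarizeBehavior(res$trials)
      emgTab <- analyzeSubjectEmg(res$trials, res$emg)
      ss <- emgTab$classification == "SuccessfulStop"
      go <- emgTab$classification == "CorrectGo"
      row <- data.frame(
        subject = s, condition = cond,
        go_rt_mean = beh$go_rt_mean,
        failed_stop_rt_mean = beh$failed_stop_rt_mean,
        correct_stop_pct = beh$correct_stop_pct,
        mean_ssd = beh$mean_ssd, ssrt = beh$ssrt,
        correct_go_pct = beh$correct_go_pct,
        go_emg_onset_mean = mean(emgTab$onset_ms[go &
                                   emgTab$burst_detected], na.rm = TRUE),
        ss_emg_pct = 100 * mean(emgTab$burst_detected[ss]),
        cancel_time_mean = mean(emgTab$cancel_time_ms[ss], na.rm = TRUE),
        ss_amp_pct_go = mean(emgTab$amp_pct_go[ss], na.rm = TRUE),
        mean_burst_time = NA_real_, peak_beta_hz = NA_real_,
        burst_pct_ss_stopwin = NA_real_, burst_pct_ss_basewin = NA_real_)
      if (eeg && cond == "none" && !is.null(res$eeg)) {
        ea <- analyzeSubjectEeg(res$eeg, beh$ssrt, beh$mean_ssd)
        if (!is.null(ea$filter)) {
          row$mean_burst_time <- as.numeric(ea$meanBurstTimeMs)
          row$peak_beta_hz <- ea$peakFreqHz
          pss <- ea$burstPct[ea$burstPct$trial_type == "SuccessfulStop", ]
          row$burst_pct_ss_stopwin <- pss$stop_win_pct
          row$burst_pct_ss_basewin <- pss$base_win_pct
          emgStop <- emgTab[emgTab$trial_type == "stop", ]
          pr <- pairBurstsWithEmg(ea$events, emgStop)
          if (nrow(pr)) pairsAll[[length(pairsAll) + 1]] <-
              cbind(subject = s, pr)
        }
      }
      condRes[[cond]] <- list(trials = res$trials, emgTab = emgTab,
                              beh = beh, row = row)
      subjects[[length(subjects) + 1]] <- row
    }
    if (all(c("real", "sham") %in% conds)) {
      ctReal <- condRes$real$row$cancel_time_mean
      ctSham <- condRes$sham$row$cancel_time_mean
      proxy <- failedStopLatencyProxy(condRes$real$trials,
                                      condRes$sham$trials)
      tmsRows[[length(tmsRows) + 1]] <- data.frame(
        subject = s, cancel_real = ctReal, cancel_sham = ctSham,
        pct_change_cancel = percentChange(ctReal, ctSham),
        relative_tms_time = relativeTmsTime(config@tms@tmsTimeMs, ctSham),
        proxy_real = proxy$a$value, proxy_sham = proxy$b$value,
        ssrt_real = condRes$real$row$ssrt,
        ssrt_sham = condRes$sham$row$ssrt)
    }
  }
  subjects <- do.call(rbind, subjects)
  pairs <- if (length(pairsAll)) do.call(rbind, pairsAll) else NULL
  out <- list(subjects = subjects, pairs = pairs)
  gs <- list()
  if (!is.null(pairs) && length(unique(pairs$subject)) >= 2) {
    rc <- rmCorr(pairs$subject, pairs$burst_time_ms, pairs$cancel_time_ms)
    out$rmcorr <- rc
    gs[[length(gs) + 1]] <- data.frame(
      measure = "rmcorr_burst_cancel", statistic = rc$r_m, df = rc$df,
      p = rc$p_value, effect_size = rc$r_m, bf10 = NA_real_)
  }
  ok <- stats::complete.cases(subjects[, c("mean_burst_time",
                                           "cancel_time_mean")])
  if (sum(ok & subjects$condition == "none") >= 3) {
    sel <- subjects[ok & subjects$condition == "none", ]
    tt <- pairedT(sel$mean_burst_time, sel$cancel_time_mean)
    gs[[length(gs) + 1]] <- data.frame(
      measure = "burst_time_vs_cancel_time", statistic = tt$statistic,
      df = tt$df, p = tt$p_value, effect_size = tt$effect_size,
      bf10 = tt$bf10)
    pr <- pearsonTest(sel$mean_burst_time, sel$cancel_time_mean)
    gs[[length(gs) + 1]] <- data.frame(
      measure = "pearson_burst_cancel_between", statistic = pr$statistic,
      df = pr$df, p = pr$p_value, effect_size = pr$effect_size,
      bf10 = NA_real_)
    bt <- pairedT(sel$burst_pct_ss_stopwin, sel$burst_pct_ss_basewin)
    gs[[length(gs) + 1]] <- data.frame(
      measure = "burst_pct_stopwin_vs_basewin", statistic = bt$statistic,
      df = bt$df, p = bt$p_value, effect_size = bt$effect_size,
      bf10 = bt$bf10)
  }
  tms <- if (length(tmsRows)) do.call(rbind, tmsRows) else NULL
  if (!is.null(tms) && nrow(tms) >= 3) {
    tt <- pairedT(tms$cancel_real, tms$cancel_sham)
    gs[[length(gs) + 1]] <- data.frame(
      measure = "cancel_real_vs_sham", statistic = tt$statistic,
      df = tt$df, p = tt$p_value, effect_size = tt$effect_size,
      bf10 = tt$bf10)
    pr <- pearsonTest(tms$relative_tms_time, tms$pct_change_cancel)
    gs[[length(gs) + 1]] <- data.frame(
      measure = "pct_change_vs_relative_tms_time",
      statistic = pr$statistic, df = pr$df, p = pr$p_value,
      effect_size = pr$effect_size, bf10 = NA_real_)
  }
  out$tms <- tms
  out$groupStats <- if (length(gs)) do.call(rbind, gs) else NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTsv(subjects, file.path(outDir, "behavior_summary.tsv"))
    if (!is.null(pairs)) writeTsv(pairs, file.path(outDir, "pairs.tsv"))
    if (!is.null(out$groupStats))
      writeTsv(out$groupStats, file.path(outDir, "group_stats.tsv"))
    if (!is.null(tms)) writeTsv(tms, file.path(outDir, "tms_contrast.tsv"))
    cfgStr <- paste(deparse(list(
      nSubjects = config@nSubjects, nGoTrials = config@nGoTrials,
      nStopTrials = config@nStopTrials, seed = config@seed,
      tms = !is.null(config@tms))), collapse = "")
    jsonlite::write_json(
      list(config_hash = .configHash(cfgStr), seed = config@seed,
           version = as.character(utils::packageVersion("stopBeta"))),
      file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  }
  out
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the
#' \code{\link{cohortConfig}} arguments (nested \code{race}, \code{eeg}
#' and \code{tms} blocks mirror \code{\link{raceParams}},
#' \code{\link{eegSynthParams}} and \code{\link{tmsEffectParams}}).
#'
#' @param path YAML file path.
#' @return a \linkS4class{CohortConfig}.
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("race", "eeg", "tms"))]
  if (!is.null(y$race)) args$race <- do.call(raceParams, y$race)
  if (!is.null(y$eeg)) args$eeg <- do.call(eegSynthParams, y$eeg)
  if (!is.null(y$tms)) args$tms <- do.call(tmsEffectParams, y$tms)
  do.call(cohortConfig, args)
}

#' Build a small packaged test cohort
#'
#' "tiny": 3 subjects x 120 trials (90 go / 30 stop, the 25\% stop-trial
#' rate); "default": 10 subjects x 320 trials (240 go / 80 stop, one
#' short EEG session each).
#'
#' @param size "tiny" or "default".
#' @param seed RNG seed.
#' @param eegEpochs synthesize EEG epochs.
#' @return list of per-subject results (see \code{\link{simulateSubject}}).
#' @export
makeFixtures <- function(size = c("tiny", "default"), seed = 1,
                         eegEpochs = FALSE) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = cohortConfig(nSubjects = 3, nGoTrials = 90, nStopTrials = 30,
                        seed = seed),
    default = cohortConfig(nSubjects = 10, nGoTrials = 240,
                           nStopTrials = 80, seed = seed))
  simulateCohort(cfg, eegEpochs = eegEpochs)
}
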