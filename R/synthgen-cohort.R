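## Cohort assembly: subject-level parameter draws, sessions, EMG traces and
## (optionally) EEG epochs, plus the float32 + JSON-sidecar on-disk layout.

#' Draw subject-level parameters
#'
#' Subjects differ in their mean onset latency and mean cancellation
#' latency (Gaussian between-subject dispersion) and in their peak beta
#' frequency (uniform over the 13-25 Hz analysis band). The subject's
#' expected beta-burst center (used by the TMS effect model) is the
#' subject cancellation mean minus the burst lead.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param subject subject index (used only for the derived seed).
#' @return list with \code{race} (subject-level \linkS4class{RaceParams}),
#'   \code{eeg} (subject-level \linkS4class{EegSynthParams}),
#'   \code{burstCenterMs} and \code{subject}.
#' @export
drawSubjectParams <- function(config, subject) {
  set.seed(childSeed(config@seed, 1L, subject))
  race <- config@race
  race@muOn <- max(50, race@muOn + stats::rnorm(1, 0, config@betweenSdMuOn))
  race@cancelMean <- max(race@cancelMin + 20,
                         race@cancelMean +
                           stats::rnorm(1, 0, config@betweenSdCancel))
  eeg <- config@eeg
  eeg@peakBetaHz <- sample(13:25, 1)
  list(race = race, eeg = eeg,
       burstCenterMs = race@cancelMean - eeg@burstLeadMean,
       subject = subject)
}

#' Simulate one subject of the synthetic cohort
#'
#' Runs the staircased session(s) (one session without TMS; real and sham
#' sessions when the configuration carries a TMS condition), synthesizes
#' the per-trial EMG traces, and optionally the EEG epochs (non-TMS
#' configurations only, mirroring acquisition where EEG is not recorded
#' during stimulation).
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param subject subject index.
#' @param eegEpochs logical; synthesize EEG epochs.
#' @return list with \code{params}, and per condition ("none" or
#'   "real"/"sham") a list with \code{trials}, \code{emg} (list of
#'   \code{EmgTrace}) and, if requested, \code{eeg} (the
#'   \code{\link{synthEegEpochs}} result including the ground-truth table).
#' @examples
#' cfg <- cohortConfig(nSubjects = 1, nGoTrials = 12, nStopTrials = 4)
#' sub <- simulateSubject(cfg, 1, eegEpochs = FALSE)
#' nrow(sub$conditions$none$trials)
#' @export
simulateSubject <- function(config, subject, eegEpochs = TRUE) {
  p <- drawSubjectParams(config, subject)
  conds <- if (is.null(config@tms)) "none" else c("real", "sham")
  out <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    trials <- runStaircaseSession(
      p$race, config@nGoTrials, config@nStopTrials,
      tms = config@tms,
      coil = if (cond == "none") "none" else cond,
      burstCenterMs = p$burstCenterMs,
      seed = childSeed(config@seed, 2L + ci, subject))
    set.seed(childSeed(config@seed, 10L + ci, subject))
    emg <- lapply(seq_len(nrow(trials)), function(i)
      synthEmgTrace(trials[i, ], emgNoiseSd = config@emgNoiseSd,
                    riseMs = config@emgBurstRiseMs,
                    fallMs = config@emgBurstFallMs,
                    peakAmp = config@emgPeakAmp))
    res <- list(trials = trials, emg = emg)
    if (eegEpochs && cond == "none") {
      res$eeg <- synthEegEpochs(trials, p$eeg,
                                seed = childSeed(config@seed, 20L, subject))
    }
    out[[cond]] <- res
  }
  list(params = p, conditions = out)
}

#' Simulate a full cohort in memory
#'
#' Convenience wrapper over \code{\link{simulateSubject}} for small
#' configurations (fixtures, examples). Large cohorts are better processed
#' subject by subject.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param eegEpochs logical; synthesize EEG epochs.
#' @return list of per-subject results.
#' @export
simulateCohort <- function(config, eegEpochs = TRUE) {
  lapply(seq_len(config@nSubjects), function(s)
    simulateSubject(config, s, eegEpochs = eegEpochs))
}

## ---- on-disk layout ----

#' Write an EMG trace as float32 + JSON sidecar
#' @param trace an \code{EmgTrace}.
#' @param pathPrefix path without extension; writes .dat and .json.
#' @return invisibly, the .dat path.
#' @export
writeEmgTrace <- function(trace, pathPrefix) {
  dat <- paste0(pathPrefix, ".dat")
  con <- file(dat, "wb")
  writeBin(as.numeric(trace$samples), con, size = 4)
  close(con)
  jsonlite::write_json(
    list(fs_hz = trace$fsHz, muscle = trace$muscle,
         markers = trace$markers, n_samples = length(trace$samples)),
    paste0(pathPrefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dat)
}

#' Read an EMG trace written by \code{writeEmgTrace}
#' @param pathPrefix path without extension.
#' @return an \code{EmgTrace}.
#' @export
readEmgTrace <- function(pathPrefix) {
  meta <- jsonlite::read_json(paste0(pathPrefix, ".json"),
                              simplifyVector = TRUE)
  con <- file(paste0(pathPrefix, ".dat"), "rb")
  x <- readBin(con, "numeric", n = meta$n_samples, size = 4)
  close(con)
  mk <- as.list(meta$markers)
  mk$stop_ms <- if (is.null(mk$stop_ms)) NA_real_ else mk$stop_ms
  structure(list(samples = x, fsHz = meta$fs_hz, markers = mk,
                 muscle = meta$muscle), class = "EmgTrace")
}

#' Write an EpochSet as float32 + JSON sidecar
#' @param x an \linkS4class{EpochSet}.
#' @param pathPrefix path without extension; writes .dat, .json and a
#'   _trials.tsv metadata table.
#' @return invisibly, the .dat path.
#' @export
writeEpochSet <- function(x, pathPrefix) {
  dat <- paste0(pathPrefix, ".dat")
  con <- file(dat, "wb")
  writeBin(as.numeric(x@data), con, size = 4)
  close(con)
  jsonlite::write_json(
    list(fs_hz = x@fsHz, channel_names = x@channelNames,
         window_ms = x@windowMs, lock_event = x@lockEvent,
         dim = dim(x@data)),
    paste0(pathPrefix, ".json"), auto_unbox = TRUE, digits = NA)
  if (nrow(x@trialInfo))
    writeTsv(x@trialInfo, paste0(pathPrefix, "_trials.tsv"))
  invisible(dat)
}

#' Read an EpochSet written by \code{writeEpochSet}
#' @param pathPrefix path without extension.
#' @return an \linkS4class{EpochSet}.
#' @export
readEpochSet <- function(pathPrefix) {
  meta <- jsonlite::read_json(paste0(pathPrefix, ".json"),
                              simplifyVector = TRUE)
  con <- file(paste0(pathPrefix, ".dat"), "rb")
  x <- readBin(con, "numeric", n = prod(meta$dim), size = 4)
  close(con)
  ti <- paste0(pathPrefix, "_trials.tsv")
  info <- if (file.exists(ti)) readTsv(ti) else data.frame()
  epochSet(array(x, meta$dim), meta$fs_hz, meta$channel_names,
           windowMs = meta$window_ms, lockEvent = meta$lock_event,
           trialInfo = info)
}

#' Write a subject's synthetic data in the pipeline layout
#'
#' Per-subject directory with \code{trials_<cond>.tsv},
#' \code{ground_truth.tsv} (trial_index, true_cancel_ms,
#' true_burst_peak_ms, burst_present), EMG traces under \code{emg/} and
#' EEG epochs under \code{eeg/}.
#'
#' @param sub a \code{\link{simulateSubject}} result.
#' @param dir target directory (created).
#' @return invisibly, \code{dir}.
#' @export
writeSubject <- function(sub, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(sub$conditions)) {
    res <- sub$conditions[[cond]]
    writeTsv(res$trials, file.path(dir, paste0("trials_", cond, ".tsv")))
    emgDir <- file.path(dir, "emg", cond)
    dir.create(emgDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(res$emg))
      writeEmgTrace(res$emg[[i]],
                    file.path(emgDir, sprintf("trial_%04d", i)))
    if (!is.null(res$eeg)) {
      eegDir <- file.path(dir, "eeg")
      dir.create(eegDir, recursive = TRUE, showWarnings = FALSE)
      writeEpochSet(res$eeg$stop, file.path(eegDir, "epochs_stop"))
      if (!is.null(res$eeg$go))
        writeEpochSet(res$eeg$go, file.path(eegDir, "epochs_go"))
      writeTsv(res$eeg$truth, file.path(dir, "ground_truth.tsv"))
    }
  }
  invisible(dir)
}
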