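## Race-model simulation: a go process (ex-Gaussian EMG-onset latency plus
## electromechanical delay to the key press) races a stop process
## (cancellation latency after the stop signal). The relative finish times
## determine the trial class and whether a partial EMG burst survives.

#' Simulate one stop-signal trial
#'
#' Samples the latent finish times and classifies the trial. With
#' \code{t_on} the EMG-onset latency from the go signal, \code{EMD} the
#' electromechanical delay and \code{t_c = ssd + cancellation latency}:
#' \code{t_c <= t_on} gives a Successful Stop without EMG;
#' \code{t_on < t_c < t_on + EMD} a Successful Stop with a partial EMG burst
#' truncated at \code{t_c}; \code{t_c >= t_on + EMD} a Failed Stop with a
#' key press at \code{t_on + EMD}. Go trials always produce a key press
#' unless the go process is omitted.
#'
#' @param race a \linkS4class{RaceParams}.
#' @param ssd stop-signal delay (ms) for stop trials, NULL for go trials.
#' @param forced optional list overriding sampled latents (\code{onsetMs},
#'   \code{emdMs}, \code{cancelLatencyMs}, \code{omitted}) for deterministic
#'   construction.
#' @return list with \code{trialType}, \code{classification},
#'   \code{onsetMs} (EMG onset from go; Inf if omitted),
#'   \code{emdMs}, \code{cancelLatencyMs} (stop trials),
#'   \code{cancelAbsMs} (from go), \code{keypressMs} (from go, NA if none),
#'   \code{emgPresent}, \code{emgTruncated}, \code{ssdMs}.
#' @examples
#' simulateTrial(raceParams(), ssd = 250,
#'               forced = list(onsetMs = 200, emdMs = 135,
#'                             cancelLatencyMs = 50))
#' @export
simulateTrial <- function(race, ssd = NULL, forced = list()) {
  stopifnot(is(race, "RaceParams"))
  omitted <- if (!is.null(forced$omitted)) forced$omitted
             else stats::runif(1) < race@pGoOmission
  onset <- if (!is.null(forced$onsetMs)) forced$onsetMs
           else rexGauss(1, race@muOn, race@sigmaOn, race@tauOn)
  emd <- if (!is.null(forced$emdMs)) forced$emdMs
         else stats::rnorm(1, race@emdMean, race@emdSd)
  if (omitted) onset <- Inf
  out <- list(trialType = if (is.null(ssd)) "go" else "stop",
              onsetMs = onset, emdMs = emd, ssdMs = ssd,
              cancelLatencyMs = NA_real_, cancelAbsMs = NA_real_)
  if (is.null(ssd)) {
    out$classification <- if (omitted) "GoOmission" else "CorrectGo"
    out$keypressMs <- if (omitted) NA_real_ else onset + emd
    out$emgPresent <- !omitted
    out$emgTruncated <- FALSE
    return(out)
  }
  cancel <- if (!is.null(forced$cancelLatencyMs)) forced$cancelLatencyMs
            else max(race@cancelMin,
                     stats::rnorm(1, race@cancelMean, race@cancelSd))
  out$cancelLatencyMs <- cancel
  tc <- ssd + cancel
  out$cancelAbsMs <- tc
  if (tc <= onset) {
    out$classification <- "SuccessfulStop"
    out$keypressMs <- NA_real_
    out$emgPresent <- FALSE
    out$emgTruncated <- FALSE
  } else if (tc < onset + emd) {
    out$classification <- "SuccessfulStop"
    out$keypressMs <- NA_real_
    out$emgPresent <- TRUE
    out$emgTruncated <- TRUE
  } else {
    out$classification <- "FailedStop"
    out$keypressMs <- onset + emd
    out$emgPresent <- TRUE
    out$emgTruncated <- FALSE
  }
  out
}

#' Apply the synthetic TMS effect to a simulated trial
#'
#' Generative stand-in for single-pulse TMS over right prefrontal cortex:
#' on pulse trials both coils slow the EMG onset by \code{distractionMs};
#' the real coil additionally elongates the cancellation latency by
#' \code{deltaMs * exp(-(tTms - burstCenter)^2 / (2 * tuningSdMs^2))},
#' maximal when the pulse coincides with the subject's typical beta-burst
#' time. The trial is then re-classified from the modified latents.
#'
#' @param outcome a trial outcome from \code{\link{simulateTrial}}.
#' @param tms a \linkS4class{TmsEffectParams}.
#' @param coil "real" or "sham".
#' @param burstCenterMs subject-level beta-burst center, ms after the stop
#'   signal.
#' @param race the \linkS4class{RaceParams} used for re-classification.
#' @return the modified trial outcome (same shape as
#'   \code{\link{simulateTrial}}).
#' @export
applyTmsEffect <- function(outcome, tms, coil = c("real", "sham"),
                           burstCenterMs, race) {
  coil <- match.arg(coil)
  stopifnot(is(tms, "TmsEffectParams"))
  forced <- list(onsetMs = outcome$onsetMs + tms@distractionMs,
                 emdMs = outcome$emdMs,
                 omitted = !is.finite(outcome$onsetMs))
  if (outcome$trialType == "stop") {
    cancel <- outcome$cancelLatencyMs
    if (coil == "real") {
      tune <- exp(-(tms@tmsTimeMs - burstCenterMs)^2 / (2 * tms@tuningSdMs^2))
      cancel <- cancel + tms@deltaMs * tune
    }
    forced$cancelLatencyMs <- cancel
  }
  res <- simulateTrial(race, ssd = outcome$ssdMs, forced = forced)
  res
}

#' Simulate a staircased stop-signal session
#'
#' Runs a full session of interleaved go and stop trials (stop trials 25\%
#' of the total when counts follow the defaults), with two independent
#' 1-up/1-down staircases (one per response direction) stepping the SSD up
#' by \code{ssdStep} after each Successful Stop and down after each Failed
#' Stop, clamped at \code{ssdFloor}.
#'
#' @param race a \linkS4class{RaceParams}.
#' @param nGo,nStop trial counts.
#' @param tms optional \linkS4class{TmsEffectParams}; when supplied, every
#'   stop trial and a random half of go trials carry a pulse at
#'   \code{tmsTimeMs} after the (most recent) stop signal.
#' @param coil coil for the TMS condition ("none", "real" or "sham").
#' @param burstCenterMs subject beta-burst center (ms after stop), required
#'   when \code{tms} is supplied.
#' @param seed optional integer seed (set for reproducibility).
#' @return data.frame of trial records: \code{trial_index},
#'   \code{trial_type}, \code{direction}, \code{ssd_ms}, \code{rt_ms},
#'   \code{classification}, \code{tms}, \code{tms_time_ms} plus ground-truth
#'   columns \code{true_onset_ms}, \code{true_emd_ms},
#'   \code{true_cancel_latency_ms}, \code{true_cancel_abs_ms},
#'   \code{emg_present}, \code{emg_truncated}.
#' @examples
#' tr <- runStaircaseSession(raceParams(), nGo = 30, nStop = 10, seed = 1)
#' table(tr$classification)
#' @export
runStaircaseSession <- function(race, nGo, nStop, tms = NULL,
                                coil = "none", burstCenterMs = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(tms) && coil == "none")
    stop("coil must be 'real' or 'sham' when a TMS condition is supplied")
  n <- nGo + nStop
  isStop <- sample(rep(c(TRUE, FALSE), c(nStop, nGo)))
  direction <- sample(c("left", "right"), n, replace = TRUE)
  ssdNow <- c(left = race@ssdStart, right = race@ssdStart)
  lastSsd <- race@ssdStart
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    d <- direction[i]
    if (isStop[i]) {
      ssd <- ssdNow[[d]]
      out <- simulateTrial(race, ssd = ssd)
      pulse <- !is.null(tms)
      tmsTime <- if (pulse) tms@tmsTimeMs else NA_real_
      if (pulse) {
        out <- applyTmsEffect(out, tms, coil, burstCenterMs, race)
        lastSsd <- ssd
      }
      step <- if (out$classification == "SuccessfulStop") race@ssdStep
              else -race@ssdStep
      ssdNow[[d]] <- max(race@ssdFloor, ssd + step)
      if (is.null(tms)) lastSsd <- ssd
    } else {
      out <- simulateTrial(race)
      pulse <- !is.null(tms) && stats::runif(1) < 0.5
      ## go-trial pulses mirror the pulse time of the most recent stop trial
      tmsTime <- if (pulse) tms@tmsTimeMs else NA_real_
      if (pulse) out <- applyTmsEffect(out, tms, coil, burstCenterMs, race)
    }
    rec[[i]] <- data.frame(
      trial_index = i, trial_type = out$trialType, direction = d,
      ssd_ms = if (is.null(out$ssdMs)) NA_real_ else out$ssdMs,
      rt_ms = out$keypressMs,
      classification = out$classification,
      tms = if (is.null(tms)) "none" else if (pulse) coil else "no_pulse",
      tms_time_ms = tmsTime,
      true_onset_ms = out$onsetMs, true_emd_ms = out$emdMs,
      true_cancel_latency_ms = out$cancelLatencyMs,
      true_cancel_abs_ms = out$cancelAbsMs,
      emg_present = out$emgPresent, emg_truncated = out$emgTruncated,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rec)
}
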