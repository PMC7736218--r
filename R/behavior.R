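## Behavioral stop-signal measures: session summary, integration-method
## SSRT, the failed-stop latency proxy and the TMS contrast arithmetic.

#' Summarize stop-signal behavior
#'
#' Means over the defined trial subsets. An empty subset yields NA for the
#' corresponding field (flagged absent), never zero.
#'
#' @param trials trial table with \code{trial_type}, \code{classification},
#'   \code{rt_ms}, \code{ssd_ms}.
#' @return list with \code{go_rt_mean}, \code{failed_stop_rt_mean},
#'   \code{correct_stop_pct}, \code{mean_ssd}, \code{correct_go_pct},
#'   \code{n_go}, \code{n_stop} and \code{ssrt} (integration method; NA if
#'   the stop rate is degenerate).
#' @examples
#' tr <- runStaircaseSession(raceParams(), nGo = 120, nStop = 40, seed = 4)
#' summarizeBehavior(tr)
#' @export
summarizeBehavior <- function(trials) {
  go <- trials[trials$trial_type == "go", ]
  st <- trials[trials$trial_type == "stop", ]
  if (!nrow(go) || !nrow(st))
    stop("need at least one go and one stop trial")
  meanOr <- function(x) if (length(x)) mean(x) else NA_real_
  goRts <- go$rt_ms[go$classification == "CorrectGo"]
  fsRts <- st$rt_ms[st$classification == "FailedStop"]
  pRespond <- mean(st$classification == "FailedStop")
  out <- list(
    go_rt_mean = meanOr(goRts),
    failed_stop_rt_mean = meanOr(fsRts),
    correct_stop_pct = 100 * mean(st$classification == "SuccessfulStop"),
    mean_ssd = mean(st$ssd_ms),
    correct_go_pct = 100 * mean(go$classification == "CorrectGo"),
    n_go = nrow(go), n_stop = nrow(st))
  out$ssrt <- if (pRespond > 0 && pRespond < 1 && length(goRts) >= 20)
    ssrtIntegration(ifelse(go$classification == "CorrectGo", go$rt_ms,
                           NA_real_),
                    pRespond, out$mean_ssd)
  else NA_real_
  out
}

#' Integration-method SSRT
#'
#' Go RTs are sorted ascending with go omissions (NA) replaced by the
#' maximum observed RT; the p-th quantile is taken as the
#' ceiling(p * n)-th order statistic, and SSRT is that value minus the mean
#' SSD, with p the probability of responding given a stop signal.
#'
#' @param goRts numeric go RTs; NA marks a go omission.
#' @param pRespond probability of responding on stop trials, in (0, 1).
#' @param meanSsd mean stop-signal delay (ms).
#' @return SSRT in ms.
#' @examples
#' ssrtIntegration(seq(201, 300), 0.5, 100)  # 150
#' @export
ssrtIntegration <- function(goRts, pRespond, meanSsd) {
  if (!is.finite(pRespond) || pRespond <= 0 || pRespond >= 1)
    stop("pRespond must lie strictly inside (0, 1): degenerate staircase")
  if (length(goRts) < 20)
    stop("need at least 20 go RTs")
  goRts[is.na(goRts)] <- max(goRts, na.rm = TRUE)
  srt <- sort(goRts)
  idx <- ceiling(pRespond * length(srt))
  srt[idx] - meanSsd
}

#' Failed-stop latency proxy
#'
#' Per SSD level, the median Failed Stop RT minus the SSD, aggregated
#' across SSD levels by a trial-count-weighted mean. SSD levels are
#' retained only if both conditions have at least \code{minPerSsd}
#' observations after filtering; when a TMS condition is analyzed, pulse
#' trials are retained only if the pulse occurred at least
#' \code{minPulseLeadMs} before the response.
#'
#' @param trialsA,trialsB trial tables for the two conditions (e.g. real
#'   and sham); \code{trialsB} may be NULL for a single condition (then
#'   only the count filter applies, against itself).
#' @param minPerSsd minimum Failed Stop observations per SSD level in both
#'   conditions.
#' @param minPulseLeadMs minimum pulse-to-response lead (ms) for retaining
#'   a pulse trial.
#' @return list with one element per condition: \code{value} (ms, NA when
#'   no SSD survives) and \code{reason} (character, why absent), plus
#'   \code{ssd_levels} retained.
#' @export
failedStopLatencyProxy <- function(trialsA, trialsB = NULL, minPerSsd = 3,
                                   minPulseLeadMs = 60) {
  fsSubset <- function(tr) {
    fs <- tr[tr$trial_type == "stop" & tr$classification == "FailedStop", ]
    pulse <- fs$tms %in% c("real", "sham") & is.finite(fs$tms_time_ms)
    keep <- !pulse |
      (fs$rt_ms - (fs$ssd_ms + fs$tms_time_ms)) >= minPulseLeadMs
    fs[keep, ]
  }
  a <- fsSubset(trialsA)
  b <- if (is.null(trialsB)) a else fsSubset(trialsB)
  lv <- intersect(unique(a$ssd_ms), unique(b$ssd_ms))
  cnt <- function(d, s) sum(d$ssd_ms == s)
  keepLv <- lv[vapply(lv, function(s)
    cnt(a, s) >= minPerSsd && cnt(b, s) >= minPerSsd, TRUE)]
  agg <- function(d) {
    if (!length(keepLv))
      return(list(value = NA_real_, reason = "no SSD level survives filters"))
    med <- vapply(keepLv, function(s)
      stats::median(d$rt_ms[d$ssd_ms == s]) - s, 0)
    w <- vapply(keepLv, function(s) cnt(d, s), 0)
    list(value = sum(med * w) / sum(w), reason = NA_character_)
  }
  out <- list(a = agg(a), ssd_levels = keepLv)
  if (!is.null(trialsB)) out$b <- agg(b)
  out
}

#' Percent change of a measure between conditions
#'
#' \code{((real - sham) / sham) * 100}.
#'
#' @param valueReal,valueSham condition values; \code{valueSham} must be
#'   nonzero.
#' @return percent change.
#' @examples
#' percentChange(170, 160)  # 6.25
#' @export
percentChange <- function(valueReal, valueSham) {
  if (any(valueSham == 0)) stop("sham value must be nonzero")
  (valueReal - valueSham) / valueSham * 100
}

#' Relative TMS time
#'
#' The pulse latency after the stop signal expressed as a percentage of the
#' sham-condition CancelTime.
#'
#' @param tmsTimeMs pulse latency after the stop signal (ms).
#' @param cancelTimeShamMs sham CancelTime (ms), must be positive.
#' @return percentage.
#' @examples
#' relativeTmsTime(80, 160)  # 50
#' @export
relativeTmsTime <- function(tmsTimeMs, cancelTimeShamMs) {
  if (any(cancelTimeShamMs <= 0)) stop("cancel time must be positive")
  tmsTimeMs / cancelTimeShamMs * 100
}
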