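## Right-frontal spatial filter by generalized eigendecomposition (GED):
## for each narrowband frequency, contrast the channel covariance of a
## post-stop window against a pre-go baseline window on Successful Stop
## epochs, solve S w = lambda R w, and keep high-ranked components whose
## activation pattern is right-frontal (or, failing that, frontal). The
## surviving candidate with the highest validation beta-power gain
## (stop-to-SSRT vs baseline) is selected.

#' Window covariance matrices for GED
#'
#' Per-trial channel covariances averaged across trials, for a signal
#' window (default 0-250 ms after the stop signal) and a baseline window
#' (default -1500 to -1000 ms).
#'
#' @param epochs an \linkS4class{EpochSet} of (narrowband) Successful Stop
#'   epochs, stop-locked.
#' @param stopWin,baseWin windows (ms) on the epoch time axis.
#' @return list with \code{S} and \code{R} (channels x channels).
#' @export
windowCovariances <- function(epochs, stopWin = c(0, 250),
                              baseWin = c(-1500, -1000)) {
  times <- epochTimes(epochs)
  d <- dim(epochs@data)
  winCov <- function(win) {
    idx <- windowIndex(times, win)
    if (d[1] * length(idx) <= d[2])
      stop("fewer samples than channels + 1 in window")
    acc <- matrix(0, d[2], d[2])
    for (tr in seq_len(d[1])) {
      X <- epochs@data[tr, , idx]
      X <- X - rowMeans(X)
      acc <- acc + tcrossprod(X) / (length(idx) - 1)
    }
    acc / d[1]
  }
  list(S = winCov(stopWin), R = winCov(baseWin))
}

#' Generalized eigendecomposition with shrinkage regularization
#'
#' Solves \code{S w = lambda R_reg w} with
#' \code{R_reg = (1 - gamma) R + gamma * (trace(R)/n) I}, via symmetric
#' whitening. Eigenpairs are returned sorted by descending eigenvalue with
#' unit-norm eigenvectors.
#'
#' @param S,R symmetric positive semidefinite matrices of equal dimension.
#' @param gamma shrinkage weight (0.01).
#' @return list with \code{values} and \code{vectors} (columns).
#' @examples
#' S <- diag(c(4, 1)); R <- diag(2)
#' gedEigen(S, R, gamma = 0)$values
#' @export
gedEigen <- function(S, R, gamma = 0.01) {
  if (!isSymmetric(unname(S), tol = 1e-8) ||
      !isSymmetric(unname(R), tol = 1e-8))
    stop("covariance inputs must be symmetric")
  n <- nrow(R)
  Rreg <- (1 - gamma) * R + gamma * (sum(diag(R)) / n) * diag(n)
  er <- eigen((Rreg + t(Rreg)) / 2, symmetric = TRUE)
  d <- pmax(er$values, max(er$values) * 1e-12)
  W <- er$vectors %*% (t(er$vectors) / sqrt(d))
  M <- W %*% ((S + t(S)) / 2) %*% t(W)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- t(W) %*% em$vectors
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  list(values = em$values, vectors = V)
}

#' Right-frontal concentration score of a topography
#'
#' Mean absolute topography over the region-of-interest channels divided
#' by the mean absolute topography over all channels; 1 for a spatially
#' uniform pattern, \code{n_channels / n_roi} for a pattern entirely on a
#' single ROI channel.
#'
#' @param topography numeric pattern, one entry per channel.
#' @param channelNames channel labels aligned with \code{topography}.
#' @param roi ROI labels (default the right-frontal set).
#' @return nonnegative score.
#' @examples
#' m <- standardMontage64()
#' topo <- as.numeric(m$label == "F6")
#' rightFrontalScore(topo, m$label)  # 64 / 7
#' @export
rightFrontalScore <- function(topography, channelNames,
                              roi = montageRoi("right_frontal")) {
  missing <- setdiff(roi, channelNames)
  if (length(missing))
    stop("ROI channels missing from montage: ",
         paste(missing, collapse = ", "))
  a <- abs(topography)
  mean(a[channelNames %in% roi]) / mean(a)
}

#' Project epochs onto a spatial filter
#'
#' Weighted channel sum per sample, per trial.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param weights channel weight vector (or a
#'   \linkS4class{SpatialFilter}).
#' @return matrix, trials x samples.
#' @export
projectEpochs <- function(epochs, weights) {
  if (is(weights, "SpatialFilter")) weights <- weights@weights
  d <- dim(epochs@data)
  if (length(weights) != d[2])
    stop("weight length does not match channel count")
  out <- matrix(0, d[1], d[3])
  for (tr in seq_len(d[1]))
    out[tr, ] <- as.numeric(weights %*% epochs@data[tr, , ])
  out
}

#' Derive and select the right-frontal spatial filter
#'
#' For each integer frequency in \code{band}: narrowband-filter the
#' Successful Stop epochs (frequency-domain Gaussian, FWHM
#' \code{fwhmHz}), compute stop-vs-baseline window covariances, run GED,
#' and keep the top \code{nTop} components by eigenvalue whose activation
#' pattern (S times weights, sign-fixed) is right-frontal
#' (\code{rfScore >= rfThreshold}); if no frequency yields a right-frontal
#' candidate, frontal topographies are admitted as a fallback. Every
#' candidate is validated by projecting the (broadband) epochs onto its
#' weights and requiring a positive beta-power gain (dB) between the
#' stop-to-SSRT window and the baseline window at its frequency; the
#' candidate with the highest gain wins.
#'
#' @param epochs preprocessed Successful Stop \linkS4class{EpochSet},
#'   stop-locked.
#' @param ssrtMs the session's integration-method SSRT (ms), upper edge of
#'   the validation window.
#' @param band integer frequencies to scan (Hz).
#' @param fwhmHz narrowband FWHM (Hz).
#' @param stopWin,baseWin covariance windows (ms).
#' @param rfThreshold minimum concentration score.
#' @param gamma GED shrinkage.
#' @param nTop admissible component rank (top 6).
#' @return a \linkS4class{SpatialFilter}, or NULL when no candidate passes
#'   (the "no right-frontal component" outcome).
#' @export
selectSpatialFilter <- function(epochs, ssrtMs, band = 10:25, fwhmHz = 5,
                                stopWin = c(0, 250),
                                baseWin = c(-1500, -1000),
                                rfThreshold = 1.2, gamma = 0.01,
                                nTop = 6) {
  d <- dim(epochs@data)
  times <- epochTimes(epochs)
  fs <- epochs@fsHz
  valWin <- c(0, max(ssrtMs, 100))
  ## work on a slice covering all analysis windows plus a 250-ms guard for
  ## the (circular) frequency-domain filtering
  keep <- which(times >= baseWin[1] - 250 &
                times <= max(stopWin[2], valWin[2]) + 250)
  ## extend the slice to an FFT-friendly (5-smooth) length
  n2 <- min(d[3], stats::nextn(length(keep), c(2, 3, 5)))
  end2 <- min(d[3], keep[1] + n2 - 1)
  keep <- seq.int(max(1, end2 - n2 + 1), end2)
  times <- times[keep]
  n <- length(keep)
  mat <- matrix(aperm(epochs@data[, , keep, drop = FALSE],
                      c(3, 1, 2)), n, d[1] * d[2])
  spec <- stats::mvfft(mat)
  f2 <- fftFreqs(n, fs)
  valIdx <- windowIndex(times, valWin)
  baseIdx <- windowIndex(times, baseWin)
  stopIdx <- windowIndex(times, stopWin)
  covWin <- function(nb, idx) {
    acc <- matrix(0, d[2], d[2])
    for (tr in seq_len(d[1])) {
      X <- nb[idx, tr + d[1] * (seq_len(d[2]) - 1)]
      X <- sweep(X, 2, colMeans(X))
      acc <- acc + crossprod(X) / (length(idx) - 1)
    }
    acc / d[1]
  }

  cand <- list()
  for (fr in band) {
    H <- exp(-4 * log(2) * (f2 - fr)^2 / fwhmHz^2)
    nb <- Re(stats::mvfft(spec * H, inverse = TRUE)) / n
    S <- covWin(nb, stopIdx)
    R <- covWin(nb, baseIdx)
    g <- gedEigen(S, R, gamma)
    nr <- min(nTop, ncol(g$vectors))
    ## batch validation: project the narrowband slice onto all admissible
    ## components at once and take analytic amplitudes in one pass
    W <- g$vectors[, seq_len(nr), drop = FALSE]
    comp <- matrix(nb, n * d[1], d[2]) %*% W      # (n*trials) x nr
    env <- analyticAmplitude(matrix(comp, n, d[1] * nr))
    dim(env) <- c(n, d[1], nr)
    for (r in seq_len(nr)) {
      w <- W[, r]
      ## activation pattern of the stop-specific covariance excess
      topo <- as.numeric((S - R) %*% w)
      if (topo[which.max(abs(topo))] < 0) { topo <- -topo; w <- -w }
      e2 <- env[, , r]^2
      cand[[length(cand) + 1]] <- list(
        w = w, topo = topo, freq = fr, lambda = g$values[r], rank = r,
        gain = 10 * log10(mean(e2[valIdx, ]) / mean(e2[baseIdx, ])),
        rf = rightFrontalScore(topo, epochs@channelNames),
        frontal = rightFrontalScore(topo, epochs@channelNames,
                                    montageRoi("frontal")))
    }
  }
  rfPass <- vapply(cand, function(c) c$rf >= rfThreshold, TRUE)
  if (!any(rfPass))
    rfPass <- vapply(cand, function(c) c$frontal >= rfThreshold, TRUE)
  cand <- cand[rfPass]
  if (!length(cand)) return(NULL)
  gains <- vapply(cand, function(c) c$gain, 0)
  if (max(gains) <= 0) return(NULL)
  best <- cand[[which.max(gains)]]
  new("SpatialFilter", weights = best$w,
      topography = best$topo, channelNames = epochs@channelNames,
      freqHz = best$freq, eigenvalue = best$lambda, rank = best$rank,
      rfScore = best$rf, betaGainDb = best$gain)
}

#' Serialize a spatial filter
#'
#' Writes a TSV (channel, weight, topography) plus JSON metadata
#' (freq_hz, eigenvalue, rank, rf_score, beta_gain_db).
#'
#' @param filter a \linkS4class{SpatialFilter}.
#' @param pathPrefix path without extension.
#' @return invisibly, the TSV path.
#' @export
writeSpatialFilter <- function(filter, pathPrefix) {
  tsv <- paste0(pathPrefix, ".tsv")
  writeTsv(data.frame(channel = filter@channelNames,
                      weight = filter@weights,
                      topography = filter@topography), tsv)
  jsonlite::write_json(
    list(freq_hz = filter@freqHz, eigenvalue = filter@eigenvalue,
         rank = filter@rank, rf_score = filter@rfScore,
         beta_gain_db = filter@betaGainDb),
    paste0(pathPrefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}
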