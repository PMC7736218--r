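## Narrowband filtering, analytic amplitude, Morlet time-frequency maps and
## basic epoch preprocessing.
##
## All spectral operations work in the frequency domain on reflection-padded
## epochs: filters are real, symmetric (zero-phase) frequency responses.

## Reflection padding of the columns of a matrix.
reflectPad <- function(mat, nPad) {
  n <- nrow(mat)
  nPad <- min(nPad, n - 1)
  rbind(mat[(nPad + 1):2, , drop = FALSE], mat,
        mat[(n - 1):(n - nPad), , drop = FALSE])
}

## Apply a real symmetric frequency response H (length n) to columns.
applyFreqResponse <- function(mat, H) {
  sp <- stats::mvfft(mat)
  Re(stats::mvfft(sp * H, inverse = TRUE)) / nrow(mat)
}

## Two-sided frequency axis for an n-point FFT.
fftFreqs <- function(n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  pmin(f, fs - f)
}

## Reflection-pad columns to an FFT-friendly length, apply f(mat, padded
## length) column-wise in the frequency domain, and trim.
.padApplySpectral <- function(mat, fun) {
  n <- nrow(mat)
  nTot <- stats::nextn(n + min(n - 1, 256), c(2, 3, 5))
  nPad <- min(n - 1, floor((nTot - n) / 2))
  pad <- reflectPad(mat, nPad)
  out <- fun(pad)
  out[(nPad + 1):(nPad + n), , drop = FALSE]
}

## Raised-cosine transition from 0 to 1 over [f0, f1].
.rcStep <- function(f, f0, f1) {
  y <- (f - f0) / (f1 - f0)
  y <- pmin(1, pmax(0, y))
  0.5 - 0.5 * cos(pi * y)
}

#' Preprocess epoched EEG
#'
#' Zero-phase band-pass (default 2-100 Hz), notch removal of line noise and
#' its harmonics (60, 120, 180 Hz), optional resampling to
#' \code{fsTarget}, and common-average referencing. Filtering is performed
#' on reflection-padded epochs with a symmetric frequency response
#' (raised-cosine band edges, 4-Hz-wide notches).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param fsTarget target sampling rate (Hz).
#' @param band band-pass corner frequencies (Hz).
#' @param notchBase line frequency (Hz); harmonics up to
#'   \code{nHarmonics * notchBase} below Nyquist are notched.
#' @param nHarmonics number of harmonics (including the fundamental).
#' @return a preprocessed \linkS4class{EpochSet} at \code{fsTarget}.
#' @export
preprocessEpochs <- function(epochs, fsTarget = 512, band = c(2, 100),
                             notchBase = 60, nHarmonics = 3) {
  fs <- epochs@fsHz
  if (fs < 2 * band[2])
    stop("sampling rate below twice the band-pass upper edge (Nyquist)")
  d <- dim(epochs@data)
  mat <- matrix(aperm(epochs@data, c(3, 1, 2)), d[3], d[1] * d[2])
  ## reflection pad to an FFT-friendly (5-smooth) length
  nTot <- stats::nextn(d[3] + round(fs / 2), c(2, 3, 5))
  nPad <- min(d[3] - 1, floor((nTot - d[3]) / 2))
  pad <- reflectPad(mat, nPad)
  n <- nrow(pad)
  f <- fftFreqs(n, fs)
  H <- .rcStep(f, band[1] / 2, band[1] * 1.5) *
       (1 - .rcStep(f, band[2], band[2] * 1.1))
  for (k in seq_len(nHarmonics)) {
    f0 <- notchBase * k
    if (f0 < fs / 2) H <- H * (1 - exp(-((f - f0)^2) / (2 * 1.2^2)))
  }
  filt <- applyFreqResponse(pad, H)[(nPad + 1):(nPad + d[3]), , drop = FALSE]
  if (fsTarget != fs) {
    ratio <- fsTarget / fs
    p <- round(ratio * 1000); q <- 1000
    g <- .gcd(p, q); p <- p / g; q <- q / g
    filt <- apply(filt, 2, function(x) signal::resample(x, p, q))
    fs <- fsTarget
  }
  nNew <- nrow(filt)
  arr <- aperm(array(filt, c(nNew, d[1], d[2])), c(2, 3, 1))
  ## common-average reference per trial and sample
  chMean <- apply(arr, c(1, 3), mean)
  arr <- arr - aperm(array(chMean, c(d[1], nNew, d[2])), c(1, 3, 2))
  epochSet(arr, fs, epochs@channelNames, epochs@montage,
           epochs@windowMs, epochs@lockEvent, epochs@trialInfo)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Frequency-domain Gaussian band-pass
#'
#' Multiplies the spectrum by a Gaussian with unit peak gain,
#' \code{exp(-4 ln2 (f - center)^2 / fwhm^2)}, and inverse-transforms.
#'
#' @param x numeric vector, or matrix with series in columns.
#' @param fsHz sampling rate.
#' @param centerHz center frequency; must satisfy
#'   \code{centerHz - fwhmHz > 0} and be below Nyquist.
#' @param fwhmHz full width at half maximum (Hz).
#' @return narrowband signal, same shape as \code{x}.
#' @examples
#' t <- seq(0, 2, by = 1 / 512)
#' x <- sin(2 * pi * 18 * t)
#' y <- gaussianBandpass(x, 512, 18)
#' sd(y) / sd(x)  # ~1
#' @export
gaussianBandpass <- function(x, fsHz, centerHz, fwhmHz = 5) {
  if (centerHz >= fsHz / 2) stop("center frequency at or above Nyquist")
  if (centerHz - fwhmHz <= 0) stop("center - fwhm must be > 0")
  vec <- is.null(dim(x))
  mat <- if (vec) matrix(x, ncol = 1) else x
  out <- .padApplySpectral(mat, function(pad) {
    f <- fftFreqs(nrow(pad), fsHz)
    applyFreqResponse(pad, exp(-4 * log(2) * (f - centerHz)^2 / fwhmHz^2))
  })
  if (vec) drop(out) else out
}

#' Analytic amplitude (Hilbert envelope)
#'
#' Magnitude of the analytic signal of a real narrowband series.
#'
#' @param x numeric vector, or matrix with series in columns.
#' @return amplitude envelope, same shape as \code{x}.
#' @examples
#' t <- seq(0, 1, by = 1 / 512)
#' mean(analyticAmplitude(2 * cos(2 * pi * 20 * t))[50:450])  # ~2
#' @export
analyticAmplitude <- function(x) {
  vec <- is.null(dim(x))
  mat <- if (vec) matrix(x, ncol = 1) else x
  out <- .padApplySpectral(mat, function(pad) {
    n <- nrow(pad)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1, n / 2 + 1)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    sp <- stats::mvfft(pad) * h
    Mod(stats::mvfft(sp, inverse = TRUE)) / n
  })
  if (vec) drop(out) else out
}

#' Morlet time-frequency map
#'
#' Wavelet power from 4 to 30 Hz with 3 cycles at the lowest frequency,
#' increasing by 0.5 cycles per step of the 1-Hz frequency grid. Wavelets
#' are implemented as frequency-domain Gaussians with unit peak gain
#' (spectral FWHM \code{2 sqrt(2 ln 2) f / (2 pi n_cycles)} ... the exact
#' dual of a time-domain Morlet with \code{n_cycles/(2 pi f)} Gaussian SD).
#' Power is averaged over trials and expressed in dB relative to the mean
#' power in \code{baselineWin}.
#'
#' @param x matrix of per-trial series (trials in rows, samples in
#'   columns) or a single numeric vector.
#' @param fsHz sampling rate.
#' @param times sample times (ms) relative to the lock event.
#' @param freqs analysis frequencies (Hz, 1-Hz grid).
#' @param cycles wavelet cycles per frequency; default
#'   \code{3 + 0.5 * (seq_along(freqs) - 1)}.
#' @param baselineWin dB-baseline window (ms) on the \code{times} axis.
#' @return list of class \code{TfrMap}: \code{power} (freqs x times, dB),
#'   \code{rawPower}, \code{freqs}, \code{times}, \code{baselineWin}.
#' @export
morletTfr <- function(x, fsHz, times, freqs = 4:30,
                      cycles = 3 + 0.5 * (seq_along(freqs) - 1),
                      baselineWin = c(-500, -200)) {
  mat <- if (is.null(dim(x))) matrix(x, nrow = 1) else x
  n <- ncol(mat)
  longest <- max(cycles / freqs) * 1000
  if (longest > diff(range(times)))
    stop("longest wavelet exceeds the epoch duration")
  bIdx <- windowIndex(times, baselineWin)
  tm <- t(mat)                                     # samples x trials
  nP <- stats::nextn(n + min(n - 1, 256), c(2, 3, 5))
  nPad <- min(n - 1, floor((nP - n) / 2))
  pad <- reflectPad(tm, nPad)
  nFull <- nrow(pad)
  f <- fftFreqs(nFull, fsHz)
  ## complex Morlet: analytic (one-sided) spectrum, so Mod() is the
  ## instantaneous envelope
  hmult <- numeric(nFull)
  hmult[1] <- 1
  if (nFull %% 2 == 0) {
    hmult[nFull / 2 + 1] <- 1
    hmult[2:(nFull / 2)] <- 2
  } else hmult[2:((nFull + 1) / 2)] <- 2
  sp <- stats::mvfft(pad)
  pw <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    ## time-domain Gaussian SD n_cycles/(2 pi f) <-> spectral SD f/n_cycles
    sdHz <- freqs[k] / cycles[k]
    H <- exp(-(f - freqs[k])^2 / (2 * sdHz^2)) * hmult
    cx <- stats::mvfft(sp * H, inverse = TRUE) / nFull
    pw[k, ] <- rowMeans(Mod(cx[(nPad + 1):(nPad + n), , drop = FALSE])^2)
  }
  base <- rowMeans(pw[, bIdx, drop = FALSE])
  db <- 10 * log10(sweep(pw, 1, base, "/"))
  structure(list(power = db, rawPower = pw, freqs = freqs, times = times,
                 baselineWin = baselineWin), class = "TfrMap")
}

#' @export
print.TfrMap <- function(x, ...) {
  cat("TfrMap:", length(x$freqs), "frequencies (", min(x$freqs), "-",
      max(x$freqs), "Hz ) x", length(x$times), "times; dB baseline [",
      x$baselineWin[1], ",", x$baselineWin[2], "] ms\n")
  invisible(x)
}

#' Peak beta frequency from a time-frequency map
#'
#' The frequency within \code{band} with the highest mean baseline-corrected
#' power in \code{window} (typically stop signal to SSRT). Exact ties take
#' the lowest frequency and are flagged.
#'
#' @param tfr a \code{TfrMap}.
#' @param window time window (ms).
#' @param band frequency band (Hz), default 13-25.
#' @return the peak frequency (Hz), with attribute \code{tie} when flat.
#' @export
peakBetaFrequency <- function(tfr, window, band = c(13, 25)) {
  sel <- tfr$freqs >= band[1] & tfr$freqs <= band[2]
  if (!any(sel)) stop("no analysis frequency inside the band")
  tIdx <- windowIndex(tfr$times, window)
  m <- rowMeans(tfr$power[sel, tIdx, drop = FALSE])
  tie <- diff(range(m)) < 1e-12
  fpk <- tfr$freqs[sel][which.max(m)]
  if (tie) fpk <- structure(tfr$freqs[sel][1], tie = TRUE)
  fpk
}
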