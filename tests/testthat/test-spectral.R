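test_that("preprocessing attenuates line noise and preserves the passband", {
  fs <- 512
  t <- (0:1023) / fs
  ## three channels summing to zero so the average reference is a no-op
  mk <- function(f) {
    arr <- array(0, c(2, 3, 1024))
    ph <- c(0, 2 * pi / 3, 4 * pi / 3)
    for (tr in 1:2) for (ch in 1:3)
      arr[tr, ch, ] <- sin(2 * pi * f * t + ph[ch])
    epochSet(arr, fs, c("Fp1", "Fpz", "Fp2"), windowMs = c(0, 2000))
  }
  pp60 <- preprocessEpochs(mk(60), fsTarget = fs)
  expect_lt(20 * log10(sd(epochData(pp60)[1, 1, 200:800]) /
                         sd(sin(2 * pi * 60 * t))), -40)
  pp20 <- preprocessEpochs(mk(20), fsTarget = fs)
  gain <- sd(epochData(pp20)[1, 1, 200:800]) / sd(sin(2 * pi * 20 * t))
  expect_lt(abs(gain - 1), 0.05)
  ## average reference zeroes the channel mean at every sample
  set.seed(51)
  arr <- array(rnorm(2 * 3 * 1024), c(2, 3, 1024))
  pp <- preprocessEpochs(epochSet(arr, fs, c("Fp1", "Fpz", "Fp2"),
                                  windowMs = c(0, 2000)), fsTarget = fs)
  expect_lt(max(abs(apply(epochData(pp), c(1, 3), mean))), 1e-10)
  ## Nyquist violation
  lowFs <- epochSet(arr, 150, c("Fp1", "Fpz", "Fp2"),
                    windowMs = c(0, 2000))
  expect_error(preprocessEpochs(lowFs), "Nyquist")
})

test_that("resampling halves the rate and keeps slow content", {
  fs <- 1024
  t <- (0:2047) / fs
  arr <- array(0, c(1, 2, 2048))
  arr[1, 1, ] <- sin(2 * pi * 10 * t)
  arr[1, 2, ] <- -sin(2 * pi * 10 * t)
  ep <- epochSet(arr, fs, c("Fp1", "Fp2"), windowMs = c(0, 2000))
  pp <- preprocessEpochs(ep, fsTarget = 512)
  expect_equal(samplingRate(pp), 512)
  expect_equal(dim(epochData(pp))[3], 1024)
  expect_lt(abs(sd(epochData(pp)[1, 1, 200:800]) -
                  sd(sin(2 * pi * 10 * t))), 0.05)
})

test_that("the Gaussian band-pass has unit peak gain and the stated FWHM", {
  fs <- 512
  t <- (0:4095) / fs
  gain <- function(f, center) {
    x <- sin(2 * pi * f * t)
    sd(gaussianBandpass(x, fs, center)[500:3500]) / sd(x[500:3500])
  }
  expect_lt(abs(gain(18, 18) - 1), 0.01)
  expect_lt(abs(gain(20.5, 18) - 0.5), 0.01)
  expect_lt(abs(gain(15.5, 18) - 0.5), 0.01)
  expect_error(gaussianBandpass(t, fs, 300), "Nyquist")
  expect_error(gaussianBandpass(t, fs, 4), "fwhm")
  ## white noise output spectrum is Gaussian-shaped around the center
  set.seed(52)
  x <- rnorm(8192)
  y <- gaussianBandpass(x, fs, 20, 5)
  sp <- Mod(fft(y))^2
  f <- (seq_along(sp) - 1) * fs / length(sp)
  half <- f > 0 & f < fs / 2
  pkF <- f[half][which.max(stats::filter(sp[half], rep(1, 65) / 65))]
  expect_lt(abs(pkF - 20), 2)
})

test_that("analytic amplitude recovers constant and modulated envelopes", {
  fs <- 512
  t <- (0:2047) / fs
  env <- analyticAmplitude(2 * cos(2 * pi * 20 * t))
  expect_true(all(abs(env[100:1900] - 2) < 0.02))
  mod <- 1 + 0.5 * sin(2 * pi * 2 * t)
  x <- mod * cos(2 * pi * 30 * t)
  rec <- analyticAmplitude(x)
  expect_lt(max(abs(rec[200:1800] - mod[200:1800])), 0.05)
  expect_equal(analyticAmplitude(numeric(256)), numeric(256))
  ## shift equivariance and amplitude linearity of band-pass + envelope
  x0 <- cos(2 * pi * 18 * t) * exp(-((t - 2)^2))
  e1 <- analyticAmplitude(gaussianBandpass(x0, fs, 18))
  sh <- 128
  xs <- c(numeric(sh), x0[1:(length(x0) - sh)])
  e2 <- analyticAmplitude(gaussianBandpass(xs, fs, 18))
  idx <- 500:1500
  expect_lt(max(abs(e2[idx + sh] - e1[idx])), 0.03)
  e3 <- analyticAmplitude(gaussianBandpass(3 * x0, fs, 18))
  expect_lt(max(abs(e3[idx] - 3 * e1[idx])), 0.03)
})

test_that("Morlet maps localize frequency and respect the dB baseline", {
  fs <- 512
  times <- seq(-1000, 1000, by = 1000 / fs)
  n <- length(times)
  x <- matrix(sin(2 * pi * 20 * times / 1000), 1, n)
  tfr <- morletTfr(x, fs, times, baselineWin = c(-900, -500))
  expect_equal(tfr$freqs[which.max(rowMeans(tfr$rawPower))], 20)
  ## stationary broadband signal: 0 dB everywhere within sampling noise
  set.seed(55)
  xs <- matrix(rnorm(30 * n), 30, n)
  tfrS <- morletTfr(xs, fs, times, baselineWin = c(-900, -500))
  expect_lt(max(abs(rowMeans(tfrS$power[, times > -400 & times < 400]))),
            2)
  ## injected burst localized in time
  set.seed(53)
  y <- matrix(rnorm(n, 0, 0.2), 4, n, byrow = TRUE)
  hann <- exp(-((times - 300) / 120)^2)
  for (i in 1:4) y[i, ] <- y[i, ] + 3 * hann * sin(2 * pi * 18 * times / 1000)
  tfr2 <- morletTfr(y, fs, times, baselineWin = c(-900, -500))
  pkT <- times[which.max(tfr2$power[tfr2$freqs == 18, ])]
  expect_lt(abs(pkT - 300), 120)
  expect_error(morletTfr(x[, 1:100, drop = FALSE], fs, times[1:100],
                         freqs = 4:10), "wavelet")
})

test_that("Morlet power agrees with matched Gaussian band-pass power on noise", {
  set.seed(54)
  fs <- 512
  times <- seq(-1500, 1500, by = 1000 / fs)
  n <- length(times)
  x <- matrix(rnorm(6 * n), 6, n)
  freqs <- 10:24
  cycles <- 3 + 0.5 * (seq_along(freqs) - 1)
  tfr <- morletTfr(x, fs, times, freqs = freqs, cycles = cycles,
                   baselineWin = c(-1200, -800))
  mid <- times > -800 & times < 800
  for (k in c(3, 8, 13)) {
    fwhm <- 2 * sqrt(2 * log(2)) * freqs[k] / cycles[k]
    nb <- gaussianBandpass(t(x), fs, freqs[k], fwhm)
    direct <- mean(analyticAmplitude(nb)[mid, ]^2) / 2
    ## analytic power = 2x one-sided band power; wavelet power uses the
    ## complex series, compare on the same scale
    wav <- mean(tfr$rawPower[k, mid])
    expect_lt(abs(wav / (2 * direct) - 1), 0.05)
  }
})

test_that("peak beta frequency is the band argmax with low-end tie-break", {
  fs <- 512
  times <- seq(-1000, 1000, by = 1000 / fs)
  n <- length(times)
  ## window-limited carriers over a noise floor (power increases are
  ## what the dB baseline correction highlights)
  set.seed(56)
  win <- times > 0 & times < 300
  mk <- function(f, a = 1) {
    y <- matrix(rnorm(6 * n, 0, 0.3), 6, n)
    for (fi in seq_along(f))
      y <- y + rep(a[fi] * win * sin(2 * pi * f[fi] * times / 1000),
                   each = 6)
    y
  }
  tfr <- morletTfr(mk(18), fs, times, baselineWin = c(-900, -500))
  expect_equal(as.numeric(peakBetaFrequency(tfr, c(0, 300))), 18)
  tfr2 <- morletTfr(mk(c(16, 22), c(0.7, 1.3)), fs, times,
                    baselineWin = c(-900, -500))
  expect_equal(as.numeric(peakBetaFrequency(tfr2, c(0, 300))), 22)
  ## flat spectrum: lowest band frequency, flagged
  flat <- tfr
  flat$power[] <- 1
  pk <- peakBetaFrequency(flat, c(0, 300))
  expect_equal(as.numeric(pk), 13)
  expect_true(isTRUE(attr(pk, "tie")))
  expect_error(peakBetaFrequency(tfr, c(0, 300), band = c(40, 50)),
               "band")
})
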