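# Signal conditioning: notch, zero-phase Butterworth, detrend, ambient
# correction and landmark extraction, each against closed forms or
# independent oracles.

fs <- 10
n <- 381
tAxis <- (seq_len(n) - 1) / fs

steady <- function(x, frac = 0.2) {
  k <- floor(length(x) * frac)
  x[(k + 1):(length(x) - k)]
}

test_that("notch filtering leaves a constant signal untouched and kills the notched tone", {
  fr <- makeFrame(rep(2.5, n))
  out <- removeResonances(fr, frequencies = 1.2, bandwidth = 0.2)
  expect_lt(max(abs(steady(breathSignals(out)[, 1]) - 2.5)), 1e-6)

  tone <- sin(2 * pi * 1.2 * tAxis)
  out <- removeResonances(makeFrame(tone), 1.2, bandwidth = 0.2)
  expect_lt(max(abs(steady(breathSignals(out)[, 1]))), 0.05)
  expect_error(removeResonances(makeFrame(tone), 5.5, 0.2), "Nyquist")
})

test_that("notch output matches an FFT spectral-zeroing oracle on a two-tone signal", {
  # 120 s record: both tones sit on exact FFT bins and the narrow-band
  # filter's transients have decayed well before the compared segment
  nn <- 1200
  tt <- (seq_len(nn) - 1) / fs
  x <- sin(2 * pi * 1.2 * tt) + 0.8 * sin(2 * pi * 0.3 * tt)
  out <- breathSignals(removeResonances(makeFrame(x), 1.2, 0.2))[, 1]
  X <- fft(x)
  freqs <- (seq_len(nn) - 1) * fs / nn
  freqs <- pmin(freqs, fs - freqs)
  X[freqs >= 1.1 & freqs <= 1.3] <- 0
  oracle <- Re(fft(X, inverse = TRUE)) / nn
  mid <- function(v) steady(v, 0.4)
  rel <- sqrt(mean((mid(out) - mid(oracle))^2)) / sqrt(mean(mid(oracle)^2))
  expect_lt(rel, 0.02)
})

test_that("Butterworth magnitude response matches the closed form", {
  fr <- makeFrame(rep(1.5, n))
  expect_lt(max(abs(steady(breathSignals(
    lowpassFilter(fr, 0.5, 2))[, 1]) - 1.5)), 1e-8)

  amp <- function(cutoff, f0, order, fsr = 10) {
    nn <- 80 * fsr + 1
    tt <- (seq_len(nn) - 1) / fsr
    x <- sin(2 * pi * f0 * tt)
    y <- breathSignals(lowpassFilter(makeFrame(x, fs = fsr), cutoff,
                                     order))[, 1]
    max(abs(steady(y)))
  }
  # two zero-phase passes square the response: 1/2 at the cutoff
  expect_equal(amp(0.5, 0.5, 2), 0.5, tolerance = 0.02)
  # |H(f)|^2 = 1/(1 + (f/fc)^(2*order)) at 4x the cutoff, order 2;
  # sampled fast so bilinear warping is negligible vs the analog form
  expect_equal(amp(0.25, 1.0, 2, fsr = 40), 1 / (1 + 4^4),
               tolerance = 0.05)
  expect_error(lowpassFilter(fr, 6), "cutoff")
})

test_that("detrending annihilates exact lines and matches the normal equations", {
  line <- 0.7 + 0.03 * tAxis
  out <- breathSignals(detrendLinear(makeFrame(line)))[, 1]
  expect_lt(max(abs(out)), 1e-9)
  out0 <- breathSignals(detrendLinear(makeFrame(numeric(n))))[, 1]
  expect_identical(max(abs(out0)), 0)

  x <- sin(2 * pi * 0.17 * tAxis) + 1.2 - 0.05 * tAxis
  out <- breathSignals(detrendLinear(makeFrame(x)))[, 1]
  expect_lt(max(abs(out - (x - lsLineOracle(tAxis, x)))), 1e-9)
})

test_that("ambient correction recovers the true lag and cancels the shared component", {
  base <- sin(2 * pi * 0.3 * tAxis) + 0.5 * sin(2 * pi * 0.45 * tAxis)

  # ambient identical to breath: lag 0, corrected identically zero
  out <- ambientCorrect(makeFrame(base, base), maxLag = 2)
  expect_identical(unname(frameMetadata(out)$ambientLags), rep(0, 7))
  expect_lt(max(abs(breathSignals(out))), 1e-12)

  # ambient = breath delayed by 0.5 s: recovered lag within one sample of
  # the brute-force lag-scan oracle
  delayed <- c(rep(base[1], 5), base[1:(n - 5)])
  out <- ambientCorrect(makeFrame(base, delayed), maxLag = 2,
                        alignHighpass = 0)
  oracle <- local({
    lags <- -20:20
    cc <- vapply(lags, function(l) {
      a <- breathprint:::.shiftSeries(delayed, l)
      cor(base, a)
    }, numeric(1))
    lags[which.max(cc)] / fs
  })
  expect_equal(oracle, 0.5)
  expect_lt(max(abs(frameMetadata(out)$ambientLags - oracle)), 0.1 + 1e-12)

  # flat ambient: flagged, lag 0, corrected equals breath exactly
  out <- ambientCorrect(makeFrame(base, numeric(n)), maxLag = 2)
  expect_identical(breathSignals(out)[, 1], base)
  expect_match(frameMetadata(out)$ambientFlags[1], "zero-variance")
  expect_error(ambientCorrect(makeFrame(base), maxLag = 100), "maxLag")
})

test_that("landmarks find the injected peak and obey the tie-break contract", {
  x <- numeric(n)
  expw <- tAxis > 28
  x[expw] <- 3.0 * exp(-((tAxis[expw] - 33) / 2)^2)  # max 3.0 at t = 33
  hold <- tAxis >= 23 & tAxis <= 28
  x[hold] <- 0.8
  lm <- findLandmarks(makeFrame(x))
  expect_equal(lm$peak_value, rep(3.0, 7))
  expect_equal(lm$peak_time, rep(33, 7))
  expect_equal(lm$trough_value, rep(0.8, 7))
  expect_equal(lm$trough_time, rep(23, 7))  # first sample of constant hold
  expect_true(attr(lm, "evaluable"))

  # monotone increasing expiration: peak at the phase's last sample
  y <- numeric(n); y[tAxis >= 28] <- seq_len(sum(tAxis >= 28))
  y[tAxis >= 23 & tAxis < 28] <- 0.5
  lm2 <- findLandmarks(makeFrame(y))
  expect_equal(lm2$peak_time, rep(38, 7))

  # non-positive trough flags the subject non-evaluable
  z <- numeric(n); z[tAxis >= 28] <- 1
  lm3 <- findLandmarks(makeFrame(z))
  expect_false(attr(lm3, "evaluable"))
})

test_that("conditioning preserves the time axis and sample count", {
  prof <- maneuverProfile()
  fr <- simulateManeuver(prof, seed = 2)
  cf <- conditionFrame(fr, testConfig())
  expect_identical(frameTime(cf), frameTime(fr))
  expect_identical(dim(breathSignals(cf)), dim(breathSignals(fr)))
  expect_identical(framePhases(cf), framePhases(fr))
})

test_that("noise-free fixtures are recovered within 1% by full conditioning", {
  prof <- maneuverProfile(noiseSD = 0)
  cfg <- testConfig()
  for (seed in 1:3) {
    fr <- simulateManeuver(prof, featureShift = rnorm(13, 0, 0.05) * rep(c(1, 2), c(6, 7)),
                           seed = seed)
    md <- frameMetadata(fr)
    lm <- findLandmarks(conditionFrame(fr, cfg))
    expect_lt(max(abs(lm$peak_value - md$cleanPeaks) / md$cleanPeaks), 0.01)
    expect_lt(max(abs(lm$trough_value - md$cleanTroughs) / md$cleanTroughs),
              0.01)
  }

  # zero-phase filtering: on a nuisance-free maneuver the peak time of the
  # conditioned signal matches the unfiltered signal within one sample
  prof0 <- maneuverProfile(noiseSD = 0, driftSlope = 0,
                           contaminantAmplitude = 0,
                           resonance = data.frame(frequency = numeric(0),
                                                  amplitude = numeric(0)))
  fr0 <- simulateManeuver(prof0, seed = 1)
  lmRaw <- findLandmarks(fr0)
  lmCond <- findLandmarks(conditionFrame(fr0, cfg))
  expect_lte(max(abs(lmCond$peak_time - lmRaw$peak_time)), 0.1 + 1e-9)
})
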