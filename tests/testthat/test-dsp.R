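test_that("band-pass filter meets passband, stopband and zero-phase contracts", {
  rate <- 500
  t <- (0:4999) / rate
  x150 <- sin(2 * pi * 150 * t)
  y <- fir_bandpass(x150, rate, 100, 250, transition = 5)
  expect_lt(abs(sd(y) / sd(x150) - 1), 0.02)
  cc <- ccf(y, x150, lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  x50 <- sin(2 * pi * 50 * t)
  y50 <- fir_bandpass(x50, rate, 100, 250, transition = 5)
  expect_lt(var(y50) / var(x50), 1e-3)

  # white noise band power matches the ideal brickwall fraction
  set.seed(7)
  w <- rnorm(50000)
  yw <- fir_bandpass(w, rate, 100, 250, transition = 5)
  expect_lt(abs(var(yw) / var(w) - 150 / 250), 0.05 * 150 / 250)
  # energy is never created
  expect_lte(var(yw), var(w) * 1.02)
})

test_that("band edges at 0 and Nyquist give low- and high-pass filters", {
  rate <- 500
  t <- (0:2499) / rate
  lp <- fir_bandpass(sin(2 * pi * 5 * t), rate, 0, 20, transition = 5)
  expect_lt(abs(sd(lp) / sd(sin(2 * pi * 5 * t)) - 1), 0.02)
  hp <- fir_bandpass(sin(2 * pi * 200 * t), rate, 100, 250, transition = 5)
  expect_lt(abs(sd(hp) / sd(sin(2 * pi * 200 * t)) - 1), 0.02)
  expect_error(fir_bandpass(rnorm(1000), rate, 100, 300), "Nyquist")
  expect_warning(fir_bandpass(rnorm(600), rate, 100, 250, transition = 0.5),
                 "capped")
})

test_that("Butterworth low-pass: DC gain 1, strong attenuation, zero net phase", {
  rate <- 500
  expect_equal(butter_lowpass(rep(3, 1000), rate), rep(3, 1000),
               tolerance = 1e-9)
  t <- (0:4999) / rate
  y100 <- butter_lowpass(sin(2 * pi * 100 * t), rate, 20, 4)
  expect_lt(20 * log10(sd(y100) / sd(sin(2 * pi * 100 * t))), -40)
  y1 <- butter_lowpass(sin(2 * pi * 1 * t), rate, 20, 4)
  expect_lt(abs(sd(y1) / sd(sin(2 * pi * 1 * t)) - 1), 0.01)
  cc <- ccf(butter_lowpass(sin(2 * pi * 5 * t), rate), sin(2 * pi * 5 * t),
            lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(butter_lowpass(rnorm(100), 30, cutoff = 20), "Nyquist")
})

test_that("resampling preserves the passband and rejects aliased content", {
  rate <- 1000
  t <- (0:9999) / rate
  y <- resample_signal(sin(2 * pi * 10 * t), rate, 500)
  expect_equal(length(y), 5000)
  expect_lt(abs(sd(y) * sqrt(2) - 1), 0.01)
  y400 <- resample_signal(sin(2 * pi * 400 * t), rate, 500)
  expect_lt(var(y400) / var(sin(2 * pi * 400 * t)), 0.01)
  expect_equal(resample_signal(rep(2, 1000), 1000, 500), rep(2, 500),
               tolerance = 1e-6)
  expect_error(resample_signal(rnorm(10), 500, 1000), "unsupported")
})

test_that("Hilbert phase follows the cosine convention and unwraps linearly", {
  rate <- 500
  n <- 2500
  t <- (0:(n - 1)) / rate
  ph_cos <- hilbert_phase(cos(2 * pi * 5 * t))
  expect_lt(abs(ph_cos[1]), 1e-6)
  ph_sin <- hilbert_phase(sin(2 * pi * 5 * t))
  expect_lt(abs(ph_sin[1] - (-pi / 2)), 1e-6)
  un <- cumsum(c(ph_cos[1], (diff(ph_cos) + pi) %% (2 * pi) - pi))
  slope <- mean(diff(un[100:(n - 100)])) * rate / (2 * pi)
  expect_lt(abs(slope / 5 - 1), 0.001)
})

test_that("Morlet magnitudes localise frequency and scale linearly", {
  rate <- 500
  t <- (0:2499) / rate
  freqs <- seq(100, 250, by = 2)
  m <- morlet_tfr(sin(2 * pi * 150 * t), rate, freqs)
  expect_equal(freqs[which.max(colMeans(m))], 150)
  m1 <- morlet_tfr(sin(2 * pi * 150 * t), rate, 150)
  m3 <- morlet_tfr(3 * sin(2 * pi * 150 * t), rate, 150)
  expect_equal(mean(m3) / mean(m1), 3, tolerance = 1e-6)
  # superposition: two tones give two ridges
  m2 <- morlet_tfr(sin(2 * pi * 120 * t) + sin(2 * pi * 200 * t), rate, freqs)
  prof <- colMeans(m2)
  peaks <- freqs[which(diff(sign(diff(prof))) == -2) + 1]
  expect_true(any(abs(peaks - 120) <= 2))
  expect_true(any(abs(peaks - 200) <= 2))
})

test_that("z-scoring is exact and affine-invariant", {
  z <- zscore_signal(c(1, 2, 3))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(1000)
  expect_equal(zscore_signal(x), zscore_signal(5 * x - 2), tolerance = 1e-10)
  expect_error(zscore_signal(rep(1, 10)), "degenerate")
})

test_that("Slepian tapers are orthonormal and spectrally concentrated", {
  for (n in c(300, 2500)) {
    tp <- dpss_tapers(n, 3, 5)
    expect_equal(crossprod(tp), diag(5), tolerance = 1e-10)
    # concentration: most taper energy within +/- NW/n of DC
    w <- 3 / n
    for (j in 1:5) {
      spec <- Mod(fft(c(tp[, j], numeric(7 * n))))^2
      f <- (0:(8 * n - 1)) / (8 * n)
      inband <- sum(spec[f <= w | f >= 1 - w]) / sum(spec)
      # the last usable taper (k = 2NW-1) has visibly lower concentration
      expect_gt(inband, if (j < 5) 0.99 else 0.94)
    }
  }
  expect_error(dpss_tapers(100, 3, 6), "at most")
})
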