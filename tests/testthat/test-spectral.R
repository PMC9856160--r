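test_that("multitaper PSD satisfies Parseval and the bandwidth contract", {
  rate <- 500
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(2500)
    sp <- multitaper_psd(x, rate)
    expect_lt(abs(sum(sp$psd) * diff(sp$freqs[1:2]) / var(x) - 1), 0.05)
  }
  # sinusoid peak at the right frequency, half-width ~ TW / window
  t <- (0:2499) / rate
  sp <- multitaper_psd(2 * sin(2 * pi * 5.5 * t), rate)
  expect_equal(sp$freqs[which.max(sp$psd)], 5.5, tolerance = 0.2)
  pk <- max(sp$psd)
  above <- sp$freqs[sp$psd > pk / 2]
  halfwidth <- (max(above) - min(above)) / 2
  expect_equal(halfwidth, sp$tw / sp$window_s, tolerance = 0.35)
  # line power integrates to A^2/2
  sel <- sp$freqs > 4 & sp$freqs < 7
  expect_equal(sum(sp$psd[sel]) * diff(sp$freqs[1:2]), 2, tolerance = 0.05)
  expect_equal(multitaper_psd(numeric(1000), rate)$psd, numeric(501))
  expect_error(multitaper_psd(rnorm(1000), rate, tw = 3, k = 7), "at most")
  expect_error(multitaper_psd(rnorm(5), rate), "too short")
})

test_that("band_power averages the density and whiten_1f flattens 1/f", {
  sp <- structure(list(freqs = seq(0, 100, by = 0.5),
                       psd = rep(2.5, 201)), class = "spectrum_mt")
  for (b in default_bands()) expect_equal(band_power(sp, b), 2.5)
  expect_error(band_power(sp, band_def("x", 100.2, 100.4)), "no frequency")
  # defining case: psd = 1/f whitens to a constant
  sp2 <- structure(list(freqs = seq(0.5, 100, by = 0.5)), class = "spectrum_mt")
  sp2$psd <- 1 / sp2$freqs
  w <- whiten_1f(sp2)
  expect_equal(w$psd, rep(1, length(w$psd)))
  # flat input whitens to a ramp proportional to f
  sp2$psd <- rep(1, length(sp2$freqs))
  expect_equal(whiten_1f(sp2)$psd, sp2$freqs)
})

test_that("whitened pink noise is flat on a log-log scale", {
  set.seed(11)
  rate <- 500
  n <- 2^17
  X <- fft(rnorm(n))
  f <- abs(c(0:(n / 2), -(n / 2 - 1):-1)) * rate / n
  amp <- 1 / sqrt(pmax(f, 0.5)); amp[1] <- 0
  x <- Re(fft(X * amp, inverse = TRUE) / n)
  acc <- NULL
  for (i in 0:9) acc <- if (is.null(acc)) multitaper_psd(x[i * 10000 + 1:10000], rate)$psd else
    acc + multitaper_psd(x[i * 10000 + 1:10000], rate)$psd
  sp <- multitaper_psd(x[1:10000], rate)
  sp$psd <- acc / 10
  w <- whiten_1f(sp)
  sel <- w$freqs >= 2 & w$freqs <= 200
  fit <- lm(log(w$psd[sel]) ~ log(w$freqs[sel]))
  expect_lt(abs(coef(fit)[2]), 0.1)
})

test_that("spike spectra: Poisson trains are flat at 1, modulation makes peaks", {
  ep <- data.frame(start = seq(0, 545, by = 10), end = seq(5, 550, by = 10))
  set.seed(2)
  times <- cumsum(rexp(3000, 5))
  sp <- spike_psd(times, ep)
  expect_lt(abs(mean(sp$psd[sp$freqs > 20 & sp$freqs < 400]) - 1), 0.1)
  # 5.5 Hz sinusoidally modulated train peaks at 5.5 Hz
  set.seed(3)
  cand <- cumsum(rexp(12000, 10))
  keep <- runif(length(cand)) < 0.5 * (1 + 0.8 * cos(2 * pi * 5.5 * cand))
  sp2 <- spike_psd(cand[keep & cand < 550], ep)
  sel <- sp2$freqs > 2 & sp2$freqs < 10
  expect_equal(sp2$freqs[sel][which.max(sp2$psd[sel])], 5.5, tolerance = 0.5)
  # bursting train: 3-spike bursts at 5 ms ISI elevate power near 200 Hz
  set.seed(4)
  burst_starts <- cumsum(rexp(800, 2))
  bt <- sort(c(burst_starts, burst_starts + 0.005, burst_starts + 0.010))
  sp3 <- spike_psd(bt[bt < 550], ep)
  hi <- mean(sp3$psd[sp3$freqs > 150 & sp3$freqs < 250])
  mid <- mean(sp3$psd[sp3$freqs > 300 & sp3$freqs < 400])
  expect_gt(hi, 1.2 * mid)
  expect_error(spike_psd(c(1, 2, 3), ep), "insufficient")
})

test_that("compare_bands: nulls stay null, shifts are detected, identity gives p = 1", {
  bands <- default_bands()
  set.seed(5)
  off <- matrix(rlnorm(30 * 4), 30)
  tab0 <- compare_bands(off, off, bands)
  expect_true(all(tab0$p_raw == 1))
  expect_false(any(tab0$significant))
  # a 1 SD paired shift at n = 30 is detected
  on <- off
  on[, 2] <- off[, 2] + sd(off[, 2])
  tab1 <- compare_bands(off, on, bands)
  expect_lt(tab1$p_raw[2], 0.01)
  expect_true(tab1$significant[2])
  expect_error(compare_bands(off[1:4, ], on[1:4, ], bands), "insufficient")
})

test_that("compare_bands false-positive rate stays near the nominal level", {
  bands <- default_bands()[1:1]
  set.seed(6)
  hits <- 0L
  for (i in 1:200) {
    off <- matrix(rlnorm(20), 20)
    on <- matrix(rlnorm(20), 20)
    hits <- hits + (compare_bands(off, on, bands)$p_raw[1] < 0.05)
  }
  expect_lte(hits / 200, 0.075)
})

test_that("band_power is stable under frequency-grid refinement", {
  rate <- 500
  t <- (0:2499) / rate
  set.seed(8)
  x <- 2 * rnorm(2500)
  sp1 <- multitaper_psd(x, rate)
  # refine the grid by zero-padding the same data window
  tap <- dpss_tapers(2500, 3, 5)
  X <- mvfft(rbind(tap * (x - mean(x)), matrix(0, 2500, 5)))
  nf <- 2501
  psd2 <- rowMeans(Mod(X[1:nf, ])^2) / rate * c(1, rep(2, nf - 2), 1)
  sp2 <- structure(list(freqs = (0:(nf - 1)) * rate / 5000, psd = psd2),
                   class = "spectrum_mt")
  b <- band_def("theta", 4, 7)
  expect_equal(band_power(sp2, b), band_power(sp1, b), tolerance = 0.02)
})
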