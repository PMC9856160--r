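test_that("OLS VAR fitting recovers known coefficients and shrinks ~ 1/sqrt(n)", {
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.3, 0.0, 0.4), 2, byrow = TRUE)
  A[, , 2] <- matrix(c(-0.2, 0.1, 0.0, -0.1), 2, byrow = TRUE)
  sig <- matrix(c(1, 0.2, 0.2, 0.8), 2)
  x <- simulate_var(A, sig, 10000, seed = 51)
  fit <- fit_var_ols(x, order = 2, rate = 500)
  expect_lt(max(abs(fit$A - A)), 0.05)
  expect_lt(max(abs(fit$sigma - sig)), 0.05)
  expect_lt(fit$spectral_radius, 1)
  errs <- vapply(c(2000, 8000, 32000), function(n) {
    xx <- simulate_var(A, sig, n, seed = n)
    max(abs(fit_var_ols(xx, order = 2, rate = 500)$A - A))
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  # white noise: coefficients near zero, sigma near the sample covariance
  set.seed(52)
  w <- matrix(rnorm(20000), ncol = 2)
  fw <- fit_var_ols(w, order = 2, rate = 500)
  expect_lt(max(abs(fw$A)), 0.05)
  expect_lt(max(abs(fw$sigma - diag(2))), 0.05)
})

test_that("Geweke spectrum: decoupled zero, unidirectional recovery, gain invariance", {
  Ad <- array(0, c(2, 2, 2)); Ad[1, 1, 1] <- 0.4; Ad[2, 2, 1] <- 0.5
  gd <- gc_spectrum(list(A = Ad, sigma = diag(2), rate = 500), "1->2")
  expect_equal(max(gd$gc), 0)
  expect_equal(max(gc_spectrum(list(A = Ad, sigma = diag(2), rate = 500),
                               "2->1")$gc), 0)

  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.6
  mod <- list(A = A, sigma = diag(2), rate = 500)
  g12 <- gc_spectrum(mod, "1->2")
  g21 <- gc_spectrum(mod, "2->1")
  expect_gt(g12$gc[2], 0.5)
  expect_equal(max(g21$gc), 0)
  # gain invariance: common rescaling of both channels
  g12s <- gc_spectrum(list(A = A, sigma = diag(2) * 9, rate = 500), "1->2")
  expect_lt(max(abs(g12$gc - g12s$gc)), 1e-8)
  expect_true(all(g12$gc >= 0) && all(is.finite(g12$gc)))
})

test_that("formula spectral matrix matches a simulation + multitaper oracle", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.6
  mod <- list(A = A, sigma = diag(2), rate = 500)
  # oracle: long simulation, multitaper estimate of the target channel PSD
  x <- simulate_var(A, diag(2), 2500 * 40, seed = 53)
  acc <- 0
  for (i in 0:39) acc <- acc + multitaper_psd(x[i * 2500 + 1:2500, 2], 500)$psd
  est <- acc / 40
  freqs <- multitaper_psd(x[1:2500, 2], 500)$freqs
  # closed-form S22 from the transfer function
  th <- -2 * pi * freqs / 500
  a11 <- 1 - A[1, 1, 1] * exp(1i * th); a22 <- 1 - A[2, 2, 1] * exp(1i * th)
  a21 <- -A[2, 1, 1] * exp(1i * th)
  det <- a11 * a22
  h21 <- -a21 / det; h22 <- a11 / det
  s22 <- (Mod(h21)^2 + Mod(h22)^2) * 2 / 500  # one-sided density
  sel <- freqs > 5 & freqs < 240
  expect_lt(stats::median(abs(est[sel] / s22[sel] - 1)), 0.10)
  # fitted-model gc matches true-model gc at the spectral peak
  fit <- fit_var_ols(simulate_var(A, diag(2), 50000, seed = 54),
                     order = 1, rate = 500)
  g_true <- gc_spectrum(mod, "1->2")
  g_fit <- gc_spectrum(fit, "1->2")
  pk <- which.max(g_true$gc)
  expect_lt(abs(g_fit$gc[pk] / g_true$gc[pk] - 1), 0.15)
})

test_that("direction recovery holds across trial-level fits", {
  A <- array(0, c(2, 2, 1))
  A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4
  band <- band_def("theta", 3, 6)
  wins <- 0L
  n_fit <- 20L
  for (i in seq_len(n_fit)) {
    x <- simulate_var(A, diag(2), 2500, seed = 60 + i)
    fit <- suppressWarnings(fit_var_ols(x, order = 10, rate = 500))
    g12 <- band_gc(gc_spectrum(fit, "1->2"), band)
    g21 <- band_gc(gc_spectrum(fit, "2->1"), band)
    wins <- wins + (g12 > g21)
  }
  expect_gte(wins, ceiling(0.95 * n_fit))
})

test_that("band_gc averages correctly and flags empty bands", {
  sp <- structure(list(freqs = seq(0, 250, length.out = 1000),
                       gc = rep(0.37, 1000)), class = "gc_spectrum")
  expect_equal(band_gc(sp, band_def("theta", 3, 6)), 0.37)
  expect_error(band_gc(sp, band_def("x", 250.5, 251)), "no frequency")
})

test_that("MUA signal: unit mass, linearity, theta peak from modulated units", {
  st <- spike_train_set(list(list(unit_id = "a", region = "MS",
                                  times = c(5.0))))
  m <- mua_rate_signal(st, "MS", 0, 10)
  expect_equal(sum(m), 0, tolerance = 1e-9)            # mean subtraction exact
  # undoing the mean subtraction recovers a smoothed bump of unit mass
  expect_equal(sum(m + 1 / length(m)), 1, tolerance = 1e-6)
  expect_equal(which.max(m) / 500, 5.0, tolerance = 0.01)
  # linearity: doubling the spikes doubles the amplitude
  st2 <- spike_train_set(list(list(unit_id = "a", region = "MS",
                                   times = c(5.0, 5.002))))
  m2 <- mua_rate_signal(st2, "MS", 0, 10)
  expect_equal(max(m2) / max(m), 2, tolerance = 0.1)
  # theta-modulated population yields a theta MUA spectral peak
  set.seed(55)
  units <- lapply(1:8, function(u) {
    cand <- cumsum(rexp(4000, 12))
    keep <- runif(length(cand)) < (1 + 0.9 * cos(2 * pi * 5.5 * cand)) / 2
    list(unit_id = paste0("m", u), region = "MS",
         times = cand[keep & cand < 200])
  })
  mu <- mua_rate_signal(spike_train_set(units), "MS", 0, 200)
  sp <- multitaper_psd(mu[1:(200 * 500)], 500, tw = 5, k = 9)
  sel <- sp$freqs > 2 & sp$freqs < 10
  expect_equal(sp$freqs[sel][which.max(sp$psd[sel])], 5.5, tolerance = 0.6)
  expect_error(mua_rate_signal(spike_train_set(list()), "HP"), "no units")
})

test_that("causality/slow-power contrast: perfect anticorrelation and null behave", {
  gc <- 1:50
  slow <- 51 - (1:50)
  ct <- suppressWarnings(gc_delta_contrast(gc, slow))
  expect_equal(ct$spearman_r, -1)
  expect_length(ct$low_gc_idx, 2)
  # independent columns stay near zero at the pooled-trial scale
  set.seed(56)
  rs <- replicate(100, suppressWarnings(
    gc_delta_contrast(rnorm(405), rnorm(405))$spearman_r))
  expect_gte(mean(abs(rs) < 0.2), 0.9)
  expect_warning(gc_delta_contrast(rnorm(20), rnorm(20)), "fewer than 40")
})

test_that("percentile-triggered averages align the theta peak at t = 0", {
  rate <- 500
  set.seed(57)
  segs <- lapply(1:45, function(i) {
    t <- (0:(5 * rate - 1)) / rate
    cos(2 * pi * 5 * t + runif(1, 0, 2 * pi)) + 0.2 * rnorm(length(t))
  })
  gc <- runif(45); slow <- runif(45)
  ct <- suppressWarnings(
    gc_delta_contrast(gc, slow, segments = segs, rate = rate))
  ta <- ct$theta_peak_avg
  expect_equal(ta$time[which.max(ta$amplitude)], 0)
  expect_equal(length(ct$psd_low_gc$psd), length(ct$psd_low_gc$freqs))
  expect_equal(sum(ct$psd_low_gc$psd), 1, tolerance = 1e-9)
})
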