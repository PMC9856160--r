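# Frequency-domain Wiener-Granger causality for channel pairs.
#
# A two-channel VAR(p) is fitted by ordinary least squares; the Geweke
# frequency-domain measure is evaluated from the transfer function
# H(w) = (I - sum_k A_k e^{-i w k})^{-1} and the residual covariance:
#   gc_{s->t}(w) = ln[ S_tt(w) / (S_tt(w) - (sigma_ss - sigma_ts^2 /
#                  sigma_tt) |H_ts(w)|^2) ]
# which is >= 0, zero for decoupled channels, and invariant to common
# rescaling of the channels.

#' Fit a two-channel VAR by ordinary least squares
#'
#' Channels are mean-subtracted, the lagged design matrix is built and
#' solved by QR; the residual covariance uses a degrees-of-freedom
#' correction.  A warning is raised if the companion matrix has
#' spectral radius >= 1 (unstable fit).
#'
#' @param x numeric matrix, samples x 2 channels.
#' @param order model order p (default 20; the headline configuration
#'   of the analyses uses 50 on 5-s segments at 500 Hz).
#' @param rate sampling rate in Hz (stored for the spectrum).
#' @return a `var_model`: list with `A` (2 x 2 x p array), `sigma`
#'   (2 x 2), `order`, `rate`, `nobs`.
#' @export
fit_var_ols <- function(x, order = 20, rate = 500) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m != 2) stop("pairwise analysis: exactly 2 channels expected")
  n <- nrow(x)
  p <- as.integer(order)
  if (n <= 10 * p) warning("few samples per coefficient; estimates will be noisy")
  x <- sweep(x, 2, colMeans(x))
  Y <- x[(p + 1):n, , drop = FALSE]
  X <- matrix(0, n - p, m * p)
  for (kk in seq_len(p)) {
    X[, (kk - 1L) * m + seq_len(m)] <- x[(p + 1L - kk):(n - kk), , drop = FALSE]
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient VAR design matrix")
  B <- qr.coef(qr_x, Y)
  resid <- Y - X %*% B
  sigma <- crossprod(resid) / (nrow(Y) - m * p)
  A <- array(0, c(m, m, p))
  for (kk in seq_len(p)) A[, , kk] <- t(B[(kk - 1L) * m + seq_len(m), , drop = FALSE])
  comp <- matrix(0, m * p, m * p)
  comp[seq_len(m), ] <- do.call(cbind, lapply(seq_len(p), function(kk) A[, , kk]))
  if (p > 1) comp[(m + 1):(m * p), seq_len(m * (p - 1))] <- diag(m * (p - 1))
  sr <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (sr >= 1) warning(sprintf("unstable VAR fit (spectral radius %.3f)", sr))
  structure(list(A = A, sigma = sigma, order = p, rate = rate, nobs = n,
                 spectral_radius = sr),
            class = "var_model")
}

#' Simulate a two-channel VAR process
#'
#' @param A 2 x 2 x p coefficient array.
#' @param sigma 2 x 2 residual covariance.
#' @param n samples to return (after `burn` burn-in samples).
#' @param burn burn-in length (default 500).
#' @param seed optional RNG seed.
#' @return numeric matrix n x 2.
#' @export
simulate_var <- function(A, sigma, n, burn = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- dim(A)[3]
  m <- 2L
  L <- t(chol(sigma))
  ntot <- n + burn
  e <- t(L %*% matrix(stats::rnorm(m * ntot), m))
  x <- matrix(0, ntot, m)
  x[seq_len(p), ] <- e[seq_len(p), ]
  for (t in (p + 1):ntot) {
    acc <- e[t, ]
    for (kk in seq_len(p)) acc <- acc + A[, , kk] %*% x[t - kk, ]
    x[t, ] <- acc
  }
  x[(burn + 1):ntot, , drop = FALSE]
}

#' Geweke frequency-domain Granger causality spectrum
#'
#' @param model a [fit_var_ols()] model (or list with `A`, `sigma`,
#'   `rate`).
#' @param direction `"1->2"` or `"2->1"` (channel indices of the input
#'   matrix; source -> target).
#' @param n_freq frequency-grid size on `[0, rate/2]` (default 1000).
#' @return a `gc_spectrum`: list with `freqs`, `gc` (>= 0), `direction`.
#' @export
gc_spectrum <- function(model, direction = c("1->2", "2->1"), n_freq = 1000) {
  direction <- match.arg(direction)
  src <- if (direction == "1->2") 1L else 2L
  tgt <- 3L - src
  A <- model$A; sigma <- model$sigma; rate <- model$rate
  p <- dim(A)[3]
  freqs <- seq(0, rate / 2, length.out = n_freq)
  th <- outer(freqs, seq_len(p), function(f, kk) -2 * pi * f * kk / rate)
  ex <- exp(1i * th)                       # n_freq x p
  a11 <- 1 - ex %*% A[1, 1, ]; a12 <- -ex %*% A[1, 2, ]
  a21 <- -ex %*% A[2, 1, ];    a22 <- 1 - ex %*% A[2, 2, ]
  det <- a11 * a22 - a12 * a21
  if (any(Mod(det) < 1e-300)) stop("singular transfer function on the grid")
  h11 <- a22 / det; h12 <- -a12 / det
  h21 <- -a21 / det; h22 <- a11 / det
  H <- list(list(h11, h12), list(h21, h22))
  s11 <- sigma[1, 1]; s22 <- sigma[2, 2]; s12 <- sigma[1, 2]
  Ht1 <- H[[tgt]][[1]]; Ht2 <- H[[tgt]][[2]]
  S_tt <- Re(Mod(Ht1)^2 * s11 + Mod(Ht2)^2 * s22 +
               2 * Re(Ht1 * Conj(Ht2)) * s12)
  sig_cond <- sigma[src, src] - sigma[tgt, src]^2 / sigma[tgt, tgt]
  Hts <- H[[tgt]][[src]]
  denom <- S_tt - sig_cond * Mod(Hts)^2
  gc <- log(pmax(S_tt, .Machine$double.xmin) /
              pmax(denom, .Machine$double.xmin))
  gc <- pmax(gc, 0)
  structure(list(freqs = freqs, gc = as.numeric(gc), direction = direction),
            class = "gc_spectrum")
}

#' Mean Granger causality over a band
#'
#' @param spec a [gc_spectrum()].
#' @param band a [band_def()] (directed-causality contrasts use theta
#'   3--6 Hz).
#' @return mean gc over grid frequencies inside the band.
#' @export
band_gc <- function(spec, band) {
  sel <- spec$freqs >= band$lo & spec$freqs <= band$hi
  if (!any(sel)) stop("band contains no frequency grid points")
  mean(spec$gc[sel])
}

#' Multiunit-activity rate signal for a region
#'
#' Pools all spikes of a region, bins at 2 ms, smooths with a Gaussian
#' kernel (sigma 10 ms) and mean-subtracts, yielding a continuous
#' rate signal usable as a Granger channel.
#'
#' @param spikes a [spike_train_set()].
#' @param region "MS" or "HP".
#' @param t0,t1 time span (s).
#' @param rate_out output rate in Hz (default 500).
#' @param sigma_s Gaussian smoothing SD in seconds (default 0.01).
#' @return numeric vector of length `round((t1-t0)*rate_out)`.
#' @export
mua_rate_signal <- function(spikes, region, t0 = 0, t1 = 600,
                            rate_out = 500, sigma_s = 0.01) {
  tt <- sort(unlist(lapply(spikes$units, function(u)
    if (u$region == region) u$times else NULL)))
  if (!length(tt)) stop("no units in region ", region)
  nb <- round((t1 - t0) * rate_out)
  rel <- tt[tt >= t0 & tt < t1] - t0
  counts <- tabulate(pmin(nb, floor(rel * rate_out) + 1L), nbins = nb)
  half <- ceiling(4 * sigma_s * rate_out)
  kt <- seq(-half, half) / rate_out
  kern <- exp(-kt^2 / (2 * sigma_s^2))
  kern <- kern / sum(kern)
  sm <- fft_conv_same(counts, kern)
  sm - mean(sm)
}

#' Trial-wise causality vs slow-wave power contrast
#'
#' Spearman rank correlation between per-trial theta-band Granger
#' causality and slow-band (0.5--3 Hz) LFP power, plus the
#' percentile-triggered averages: the trials in the lowest `pct`
#' quantile of causality and the highest `pct` quantile of slow power
#' are returned with their average normalised PSD and z-scored
#' theta-filtered amplitude aligned to the hippocampal theta peak
#' (peak at t = 0).
#'
#' @param gc_trials per-trial band causality values.
#' @param slow_power_trials per-trial slow-band powers (same length).
#' @param segments optional list of per-trial HP LFP segments (for the
#'   triggered averages).
#' @param rate sampling rate of the segments (Hz).
#' @param pct percentile (default 0.05).
#' @param theta_band band for the aligned amplitude (default 3--6 Hz).
#' @param align_halfwidth seconds around the theta peak (default 0.5).
#' @return list: `spearman_r`, `p_value`, `n_trials`, `low_gc_idx`,
#'   `high_slow_idx`, and (with segments) `psd_low_gc`,
#'   `psd_high_slow` (normalised spectra) and `theta_peak_avg`
#'   (z-scored theta amplitude aligned to the peak).
#' @export
gc_delta_contrast <- function(gc_trials, slow_power_trials, segments = NULL,
                              rate = NULL, pct = 0.05,
                              theta_band = band_def("theta", 3, 6),
                              align_halfwidth = 0.5) {
  stopifnot(length(gc_trials) == length(slow_power_trials))
  n <- length(gc_trials)
  if (n < 40) warning("fewer than 40 trials: the ", pct,
                      " percentile subsets hold < 2 trials")
  if (max(table(rank(gc_trials))) > n / 2) warning("heavy ties in causality ranks")
  ct <- suppressWarnings(stats::cor.test(gc_trials, slow_power_trials,
                                         method = "spearman", exact = FALSE))
  k <- max(1L, floor(pct * n))
  low_gc <- order(gc_trials)[seq_len(k)]
  high_slow <- order(slow_power_trials, decreasing = TRUE)[seq_len(k)]
  out <- list(spearman_r = unname(ct$estimate), p_value = ct$p.value,
              n_trials = n, low_gc_idx = low_gc, high_slow_idx = high_slow)
  if (!is.null(segments)) {
    stopifnot(!is.null(rate))
    norm_psd <- function(idx) {
      acc <- NULL
      for (i in idx) {
        sp <- multitaper_psd(segments[[i]], rate)
        v <- sp$psd / sum(sp$psd)
        acc <- if (is.null(acc)) v else acc + v
      }
      list(freqs = multitaper_psd(segments[[idx[1]]], rate)$freqs,
           psd = acc / length(idx))
    }
    aligned_theta <- function(idx) {
      hw <- round(align_halfwidth * rate)
      acc <- numeric(2L * hw + 1L)
      used <- 0L
      for (i in idx) {
        th <- fir_bandpass(segments[[i]], rate, theta_band$lo, theta_band$hi,
                           transition = 1)
        z <- zscore_signal(th)
        centre <- seq(hw + 1L, length(z) - hw)
        pk <- centre[which.max(z[centre])]
        acc <- acc + z[(pk - hw):(pk + hw)]
        used <- used + 1L
      }
      list(time = seq(-hw, hw) / rate, amplitude = acc / used)
    }
    out$psd_low_gc <- norm_psd(low_gc)
    out$psd_high_slow <- norm_psd(high_slow)
    out$theta_peak_avg <- aligned_theta(high_slow)
  }
  out
}
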