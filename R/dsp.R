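# Internal: FFT-based linear convolution of x with kernel h, returning the
# "same"-length central part (delay-compensated for odd-length kernels).
fft_conv_same <- function(x, h) {
  n <- length(x)
  l <- length(h)
  nfft <- stats::nextn(n + l - 1L, 2L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - l))), inverse = TRUE)) / nfft
  delay <- (l - 1L) %/% 2L
  y[(delay + 1L):(delay + n)]
}

# Internal: zero-phase FIR filtering (forward + backward application of a
# linear-phase kernel) with reflection padding to suppress edge transients.
filtfilt_fir <- function(x, h) {
  n <- length(x)
  pad <- min(n - 1L, length(h))
  xe <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- fft_conv_same(xe, h)
  y <- rev(fft_conv_same(rev(y), h))
  y[(pad + 1L):(pad + n)]
}

# Internal: windowed-sinc FIR design (Hamming window).  `lo = 0` gives a
# low-pass, `hi = rate/2` a high-pass, otherwise a band-pass.  Returns an
# odd-length symmetric (type I, exactly linear phase) kernel.
design_fir <- function(rate, lo, hi, order) {
  nyq <- rate / 2
  stopifnot(lo >= 0, hi > lo, hi <= nyq + 1e-9)
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  m <- seq(-order / 2, order / 2)
  sinc <- function(f) {
    out <- 2 * f / rate * rep(1, length(m))
    nz <- m != 0
    out[nz] <- sin(2 * pi * f * m[nz] / rate) / (pi * m[nz])
    out
  }
  h <- if (lo <= 0) {
    sinc(hi)
  } else if (hi >= nyq - 1e-9) {
    ideal <- -sinc(lo)
    ideal[m == 0] <- 1 - 2 * lo / rate
    ideal
  } else {
    sinc(hi) - sinc(lo)
  }
  w <- 0.54 + 0.46 * cos(2 * pi * m / (order + 1L))
  h <- h * w
  # normalise passband gain to 1 at band centre
  fc <- if (lo <= 0) 0 else if (hi >= nyq - 1e-9) nyq else (lo + hi) / 2
  gain <- Mod(sum(h * exp(-2i * pi * fc * m / rate)))
  h / gain
}

#' Band-pass filter a signal with a zero-phase FIR filter
#'
#' Designs a linear-phase FIR filter (windowed-sinc) for the requested band
#' and applies it forward and backward so the net phase response is zero.
#' The filter order is chosen from the transition-width contract
#' `order = 3.3 * rate / transition`, capped at one third of the signal
#' length (with a warning when the cap degrades the transition band, as on
#' short test fixtures).  `lo = 0` yields a low-pass filter and
#' `hi >= rate/2` a high-pass filter, so ripple-band filtering at a 500 Hz
#' sampling rate (100--250 Hz, upper edge at Nyquist) is well defined.
#'
#' @param x numeric vector, the signal.
#' @param rate sampling rate in Hz.
#' @param lo,hi band edges in Hz (`0 <= lo < hi <= rate/2`).
#' @param transition transition width in Hz controlling the filter order
#'   (default 0.5 Hz, the ripple-detection contract).
#' @return filtered signal, same length as `x`.
#' @export
fir_bandpass <- function(x, rate, lo, hi, transition = 0.5) {
  n <- length(x)
  if (hi > rate / 2 + 1e-9) stop("band edge above Nyquist")
  if (lo < 0 || lo >= hi) stop("need 0 <= lo < hi")
  order <- ceiling(3.3 * rate / transition)
  cap <- floor(n / 3)
  if (cap < 8) stop("signal too short to filter")
  if (order > cap) {
    warning("signal too short for requested transition width; filter order capped")
    order <- cap
  }
  h <- design_fir(rate, lo, hi, order)
  filtfilt_fir(x, h)
}

#' Low-pass filter with a Butterworth filter applied forward and backward
#'
#' 4th-order Butterworth low-pass (the ripple-envelope smoothing stage),
#' applied with [signal::filtfilt()] so the net phase shift is zero and the
#' effective magnitude response is the squared 4th-order response.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 20).
#' @param order filter order (default 4).
#' @return filtered signal.
#' @export
butter_lowpass <- function(x, rate, cutoff = 20, order = 4) {
  if (cutoff >= rate / 2) stop("cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  n <- length(x)
  pad <- min(n - 1L, 20L * ceiling(rate / cutoff))
  xe <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, xe)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Resample a signal to a lower rate with anti-alias filtering
#'
#' Low-pass filters at 80% of the output Nyquist frequency (zero phase)
#' and then resamples onto the new time grid.  Integer decimation factors
#' pick every `rate_in/rate_out`-th sample; other ratios use linear
#' interpolation of the anti-aliased signal.
#'
#' @param x numeric vector.
#' @param rate_in,rate_out input and output sampling rates in Hz.
#' @return resampled signal of length `round(length(x) * rate_out / rate_in)`.
#' @export
resample_signal <- function(x, rate_in, rate_out) {
  if (rate_out > rate_in) stop("upsampling unsupported")
  if (rate_out == rate_in) return(x)
  cutoff <- 0.8 * rate_out / 2
  xf <- fir_bandpass(x, rate_in, 0, cutoff, transition = 0.2 * rate_out / 2)
  n_out <- round(length(x) * rate_out / rate_in)
  fac <- rate_in / rate_out
  if (abs(fac - round(fac)) < 1e-9) {
    idx <- 1L + (seq_len(n_out) - 1L) * as.integer(round(fac))
    xf[idx]
  } else {
    t_out <- (seq_len(n_out) - 1L) / rate_out
    t_in <- (seq_along(x) - 1L) / rate_in
    stats::approx(t_in, xf, xout = t_out, rule = 2)$y
  }
}

#' Instantaneous phase via the Hilbert transform
#'
#' Phase of the analytic signal, wrapped to (-pi, pi].  The convention is
#' phase 0 at the peak of a cosine: `cos(2*pi*f*t)` has phase 0 at `t = 0`.
#' Callers are expected to band-pass filter first; the phase of a broadband
#' signal is not meaningful.
#'
#' @param x numeric vector (narrowband signal).
#' @return phase in radians, same length as `x`.
#' @export
hilbert_phase <- function(x) {
  Arg(analytic_signal(x))
}

# Internal: analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Morlet wavelet time-frequency magnitude
#'
#' Convolves the signal with complex Morlet wavelets of `n_cycles` cycles
#' (temporal SD `n_cycles / (2*pi*f)`) at each requested frequency and
#' returns the magnitude of the complex coefficients.  Wavelets are
#' L1-normalised so an amplitude-A sinusoid at frequency f yields a ridge
#' of magnitude proportional to A independent of f.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param freqs frequencies of interest in Hz (all below Nyquist).
#' @param n_cycles wavelet width in cycles (default 7).
#' @return matrix `length(x)` x `length(freqs)` of magnitudes.
#' @export
morlet_tfr <- function(x, rate, freqs, n_cycles = 7) {
  if (any(freqs > rate / 2)) stop("wavelet frequency above Nyquist")
  n <- length(x)
  out <- matrix(0, n, length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sd_t <- n_cycles / (2 * pi * f)
    half <- ceiling(4 * sd_t * rate)
    tt <- seq(-half, half) / rate
    w <- exp(-tt^2 / (2 * sd_t^2)) * exp(2i * pi * f * tt)
    w <- w / sum(Mod(w))
    re <- fft_conv_same(x, Re(w))
    im <- fft_conv_same(x, Im(w))
    out[, j] <- sqrt(re^2 + im^2)
  }
  colnames(out) <- as.character(freqs)
  out
}

#' Z-score a signal using its whole-trace mean and SD
#'
#' @param x numeric vector with positive standard deviation.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore_signal <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate signal: zero variance")
  (x - mean(x)) / s
}
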