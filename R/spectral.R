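#' Frequency band definition
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @return a `band_def` object.
#' @export
band_def <- function(name, lo, hi) {
  stopifnot(is.character(name), lo >= 0, lo < hi)
  structure(list(name = name, lo = lo, hi = hi), class = "band_def")
}

#' Default band registry for hippocampal LFP contrasts
#'
#' Slow (0.5--3 Hz), theta (4--7 Hz), slow-gamma (20--40 Hz) and
#' high-gamma (60--140 Hz).  The directed-causality analyses use a lower
#' theta band (3--6 Hz), available as `default_bands("gc")`.
#'
#' @param set `"lfp"` (default) or `"gc"`.
#' @return named list of [band_def()] objects.
#' @export
default_bands <- function(set = c("lfp", "gc")) {
  set <- match.arg(set)
  if (set == "lfp") {
    list(
      slow = band_def("slow", 0.5, 3),
      theta = band_def("theta", 4, 7),
      slow_gamma = band_def("slow_gamma", 20, 40),
      high_gamma = band_def("high_gamma", 60, 140)
    )
  } else {
    list(
      slow = band_def("slow", 0.5, 3),
      theta = band_def("theta", 3, 6),
      slow_gamma = band_def("slow_gamma", 20, 40),
      high_gamma = band_def("high_gamma", 60, 140)
    )
  }
}

#' Multitaper power spectral density
#'
#' Averages Slepian-tapered periodograms (time-bandwidth product `tw`,
#' `k` tapers).  The one-sided density is scaled so that its integral
#' over `[0, rate/2]` equals the signal variance (Parseval contract);
#' units are input-units squared per Hz.  The half bandwidth of the
#' estimate is `tw / window_s` Hz.
#'
#' @param x numeric vector (one segment; the mean is removed).
#' @param rate sampling rate in Hz.
#' @param tw time-bandwidth product (default 3).
#' @param k taper count (default `2*tw - 1`).
#' @param demean subtract the segment mean first (default TRUE).
#' @return a `spectrum_mt` object: list with `freqs`, `psd`, `tw`, `k`,
#'   `window_s`.
#' @export
multitaper_psd <- function(x, rate, tw = 3, k = 2 * tw - 1, demean = TRUE) {
  n <- length(x)
  if (n < 2 * k) stop("segment too short for the requested taper count")
  if (demean) x <- x - mean(x)
  tap <- dpss_tapers(n, tw, k)
  X <- stats::mvfft(tap * x)
  nf <- floor(n / 2) + 1L
  p <- rowMeans(Mod(X[1:nf, , drop = FALSE])^2) / rate
  scale <- rep(2, nf)
  scale[1] <- 1
  if (n %% 2L == 0L) scale[nf] <- 1
  structure(list(
    freqs = (0:(nf - 1L)) * rate / n,
    psd = p * scale,
    tw = tw, k = k, window_s = n / rate
  ), class = "spectrum_mt")
}

#' Mean power density over a frequency band
#'
#' @param spec a `spectrum_mt` object (or any list with `freqs`, `psd`).
#' @param band a [band_def()] object.
#' @return mean of `psd` over frequencies in `[lo, hi]` (same units as
#'   the density, matching mean-density band summaries).
#' @export
band_power <- function(spec, band) {
  sel <- spec$freqs >= band$lo & spec$freqs <= band$hi
  if (!any(sel)) stop("band contains no frequency grid points")
  mean(spec$psd[sel])
}

#' Whiten a spectrum by the 1/f power law
#'
#' Multiplies the density by frequency, `psd'(f) = psd(f) * f`, dropping
#' the DC bin; this flattens the 1/f background so narrowband rhythms
#' (e.g. gamma) stand out.
#'
#' @param spec a `spectrum_mt` object.
#' @return a `spectrum_mt` object without the DC bin.
#' @export
whiten_1f <- function(spec) {
  keep <- spec$freqs > 0
  out <- spec
  out$freqs <- spec$freqs[keep]
  out$psd <- spec$psd[keep] * out$freqs
  out
}

#' Spike-train power spectrum across epochs
#'
#' Bins the spikes of one unit at `bin_rate`, computes a mean-subtracted
#' multitaper spectrum per epoch, averages across epochs, and normalises
#' by the mean firing rate so a homogeneous Poisson train is flat at 1.
#' Theta-modulated units show a peak at the modulation frequency and
#' bursting units elevated power near the intra-burst frequency.
#'
#' @param times spike times in seconds (ascending).
#' @param epochs data.frame with `start`, `end` columns (seconds,
#'   half-open intervals); all epochs must share one duration.
#' @param bin_rate binning rate in Hz (default 1000).
#' @param tw,k multitaper parameters.
#' @return a `spectrum_mt` object (normalised units; Poisson floor = 1).
#' @export
spike_psd <- function(times, epochs, bin_rate = 1000, tw = 3, k = 2 * tw - 1) {
  durs <- epochs$end - epochs$start
  if (max(durs) - min(durs) > 1e-9) stop("epochs must share one duration")
  nb <- round(durs[1] * bin_rate)
  tot <- 0L
  acc <- NULL
  for (i in seq_len(nrow(epochs))) {
    sel <- times >= epochs$start[i] & times < epochs$end[i]
    tot <- tot + sum(sel)
  }
  if (tot < 50) stop("insufficient spikes for a spectrum (need >= 50)")
  for (i in seq_len(nrow(epochs))) {
    rel <- times[times >= epochs$start[i] & times < epochs$end[i]] - epochs$start[i]
    counts <- tabulate(pmin(nb, floor(rel * bin_rate) + 1L), nbins = nb)
    sp <- multitaper_psd(counts, bin_rate, tw = tw, k = k)
    acc <- if (is.null(acc)) sp$psd else acc + sp$psd
  }
  spec <- multitaper_psd(numeric(nb) + 0, bin_rate, tw = tw, k = k, demean = FALSE)
  spec$psd <- acc / nrow(epochs)
  lambda <- tot / sum(durs)
  # one-sided density of a Poisson count process binned at bin_rate is
  # 2*lambda/bin_rate^2; dividing by it sets the Poisson floor to 1
  spec$psd <- spec$psd * bin_rate^2 / (2 * lambda)
  spec
}

#' Per-band paired on/off contrast table
#'
#' For each band, tests the paired per-trial differences: a
#' Kolmogorov--Smirnov normality check on the standardised differences
#' selects a paired t-test (normal) or a Wilcoxon signed-rank test, and
#' Benjamini--Hochberg FDR is applied across bands.
#'
#' @param off,on numeric matrices or data.frames, trials x bands, of
#'   per-trial band powers under the two conditions (same column order
#'   as `bands`).
#' @param bands list of [band_def()] objects, one per column.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return data.frame with one row per band: means, SEMs, raw and
#'   FDR-adjusted p values, significance flag.
#' @export
compare_bands <- function(off, on, bands, alpha = 0.05) {
  off <- as.matrix(off); on <- as.matrix(on)
  stopifnot(ncol(off) == length(bands), all(dim(off) == dim(on)))
  if (nrow(off) < 6) stop("insufficient trial pairs (need >= 6)")
  p_raw <- numeric(length(bands))
  for (j in seq_along(bands)) {
    d <- on[, j] - off[, j]
    if (all(d == 0)) { p_raw[j] <- 1; next }
    ks <- suppressWarnings(stats::ks.test(scale(d), "pnorm"))
    p_raw[j] <- if (ks$p.value > 0.05) {
      stats::t.test(on[, j], off[, j], paired = TRUE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(on[, j], off[, j], paired = TRUE))$p.value
    }
  }
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  data.frame(
    band = vapply(bands, function(b) b$name, character(1)),
    lo = vapply(bands, function(b) b$lo, numeric(1)),
    hi = vapply(bands, function(b) b$hi, numeric(1)),
    mean_off = colMeans(off), sem_off = apply(off, 2, sem),
    mean_on = colMeans(on), sem_on = apply(on, 2, sem),
    p_raw = p_raw, p_fdr = p_fdr,
    significant = p_fdr < alpha,
    row.names = NULL
  )
}

#' Per-trial band powers for a set of epochs
#'
#' Convenience wrapper: one multitaper spectrum per epoch on a single
#' LFP channel, reduced to band means.
#'
#' @param x LFP trace (numeric vector).
#' @param rate sampling rate in Hz.
#' @param epochs data.frame with `start`, `end` (seconds).
#' @param bands list of [band_def()] objects.
#' @param tw,k multitaper parameters.
#' @return matrix, epochs x bands, of mean band densities.
#' @export
epoch_band_powers <- function(x, rate, epochs, bands, tw = 3, k = 2 * tw - 1) {
  out <- matrix(NA_real_, nrow(epochs), length(bands))
  colnames(out) <- vapply(bands, function(b) b$name, character(1))
  for (i in seq_len(nrow(epochs))) {
    i0 <- floor(epochs$start[i] * rate) + 1L
    i1 <- min(length(x), floor(epochs$end[i] * rate))
    sp <- multitaper_psd(x[i0:i1], rate, tw = tw, k = k)
    out[i, ] <- vapply(bands, function(b) band_power(sp, b), numeric(1))
  }
  out
}
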