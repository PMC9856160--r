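# Spike-field and LFP-LFP coherence, pairwise phase consistency, and
# CA1 layer assignment from ripple-triggered laminar profiles.

#' Multitaper magnitude-squared coherence over trials
#'
#' `|S_ab|^2 / (S_aa * S_bb)` with the cross- and auto-spectra averaged
#' over Slepian tapers and trial segments.  At least two averaging
#' segments are required (with a single segment the estimate is
#' identically 1).  For spike-field coherence pass the binned,
#' mean-subtracted spike train as one of the channels (see
#' [bin_spike_train()]).
#'
#' @param xa,xb numeric matrices (samples x trials) or vectors of equal
#'   length; columns are averaging segments.
#' @param rate sampling rate in Hz.
#' @param tw time-bandwidth product (default 3).
#' @param k taper count (default 5).
#' @param kind label stored on the result ("lfp_lfp" or "spike_field").
#' @return a `coherence_curve`: list with `freqs`, `coh` (in [0, 1]),
#'   `n_segments`, `kind`.
#' @export
coherence <- function(xa, xb, rate, tw = 3, k = 5, kind = "lfp_lfp") {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  stopifnot(all(dim(xa) == dim(xb)))
  m <- ncol(xa)
  if (m < 2) stop("coherence needs at least 2 averaging segments")
  n <- nrow(xa)
  tap <- dpss_tapers(n, tw, k)
  nf <- floor(n / 2) + 1L
  saa <- sbb <- numeric(nf)
  sab <- complex(nf)
  for (j in seq_len(m)) {
    A <- stats::mvfft(tap * (xa[, j] - mean(xa[, j])))[1:nf, , drop = FALSE]
    B <- stats::mvfft(tap * (xb[, j] - mean(xb[, j])))[1:nf, , drop = FALSE]
    saa <- saa + rowSums(Mod(A)^2)
    sbb <- sbb + rowSums(Mod(B)^2)
    sab <- sab + rowSums(A * Conj(B))
  }
  coh <- Mod(sab)^2 / pmax(saa * sbb, .Machine$double.xmin)
  structure(list(freqs = (0:(nf - 1L)) * rate / n,
                 coh = pmin(1, coh), n_segments = m, kind = kind),
            class = "coherence_curve")
}

#' Bin a spike train into a mean-subtracted count signal
#'
#' @param times spike times (s).
#' @param t0,t1 segment bounds (s, half-open).
#' @param rate bin rate in Hz (default 500, i.e. 2 ms bins).
#' @return numeric vector of mean-subtracted counts.
#' @export
bin_spike_train <- function(times, t0, t1, rate = 500) {
  nb <- round((t1 - t0) * rate)
  rel <- times[times >= t0 & times < t1] - t0
  counts <- tabulate(pmin(nb, floor(rel * rate) + 1L), nbins = nb)
  counts - mean(counts)
}

#' Mean band coherence for epoch-segmented traces
#'
#' Cuts both channels into the given epochs and averages the coherence
#' over a band.
#'
#' @param xa,xb full-length traces.
#' @param rate sampling rate (Hz).
#' @param epochs data.frame with `start`, `end` (equal durations).
#' @param band a [band_def()].
#' @param tw,k multitaper parameters.
#' @return mean coherence in the band.
#' @export
epoch_band_coherence <- function(xa, xb, rate, epochs, band, tw = 3, k = 5) {
  segs_a <- segs_b <- NULL
  for (i in seq_len(nrow(epochs))) {
    i0 <- floor(epochs$start[i] * rate) + 1L
    i1 <- i0 + round((epochs$end[i] - epochs$start[i]) * rate) - 1L
    if (i1 > length(xa)) next
    segs_a <- cbind(segs_a, xa[i0:i1])
    segs_b <- cbind(segs_b, xb[i0:i1])
  }
  cc <- coherence(segs_a, segs_b, rate, tw = tw, k = k)
  sel <- cc$freqs >= band$lo & cc$freqs <= band$hi
  mean(cc$coh[sel])
}

#' Pairwise phase consistency of a phase sample
#'
#' The mean cosine of the angular distance over all spike pairs,
#' computed through the O(N) identity
#' `(|sum e^{i theta}|^2 - N) / (N (N - 1))`, which equals the O(N^2)
#' pairwise average exactly.  Unbiased: uniform phases give 0 in
#' expectation; equal phases give 1; an antipodal pair gives -1.
#'
#' @param phases numeric vector of phases in radians (length >= 2).
#' @return the PPC value (<= 1).
#' @export
ppc_from_phases <- function(phases) {
  n <- length(phases)
  if (n < 2) return(NA_real_)
  (Mod(sum(exp(1i * phases)))^2 - n) / (n * (n - 1))
}

#' Spike-LFP pairwise phase consistency spectrum
#'
#' For each grid frequency the LFP is band-pass filtered in
#' `f +/- half_bw` Hz, the instantaneous phase extracted with the
#' Hilbert transform, sampled at the spike times, and reduced with
#' [ppc_from_phases()].
#'
#' @param times spike times (s), all within the trace.
#' @param lfp LFP trace.
#' @param rate sampling rate (Hz).
#' @param freqs frequency grid in Hz (default 0 to 10 Hz, 0.25 Hz step;
#'   the 0 Hz point uses a low-pass band).
#' @param half_bw filter half-bandwidth around each grid point (default
#'   0.5 Hz).
#' @return a `ppc_curve`: list with `freqs`, `ppc`, `n_spikes`.
#' @export
ppc <- function(times, lfp, rate, freqs = seq(0, 10, by = 0.25),
                half_bw = 0.5) {
  if (length(times) < 2) {
    return(structure(list(freqs = freqs, ppc = rep(NA_real_, length(freqs)),
                          n_spikes = length(times)), class = "ppc_curve"))
  }
  idx <- pmin(length(lfp), pmax(1L, round(times * rate) + 1L))
  vals <- vapply(freqs, function(f) {
    lo <- max(0, f - half_bw)
    hi <- min(rate / 2, f + half_bw)
    filt <- fir_bandpass(lfp, rate, lo, hi, transition = max(0.5, half_bw))
    ppc_from_phases(hilbert_phase(filt)[idx])
  }, numeric(1))
  structure(list(freqs = freqs, ppc = vals, n_spikes = length(times)),
            class = "ppc_curve")
}

#' Theta-band coherence between hippocampal shanks
#'
#' For every pair of HP shanks (one representative channel per shank,
#' the one closest to the pyramidal-layer depth), computes the mean
#' band coherence separately for on and off epochs, labelled by
#' inter-shank index distance.
#'
#' @param rec a [recording()].
#' @param epochs data.frame from [epochs_from_protocol()].
#' @param band a [band_def()] (default theta 4--7 Hz).
#' @param pyr_depth preferred depth index (default: median depth).
#' @return data.frame: shank_a, shank_b, distance, coh_off, coh_on.
#' @export
coherence_by_distance <- function(rec, epochs, band = band_def("theta", 4, 7),
                                  pyr_depth = NULL) {
  ch <- rec$channels
  hp <- ch[ch$region == "HP", ]
  shanks <- sort(unique(hp$shank))
  if (length(shanks) < 2) stop("need at least 2 HP shanks")
  if (is.null(pyr_depth)) pyr_depth <- stats::median(hp$depth_index)
  rep_ch <- vapply(shanks, function(s) {
    g <- hp[hp$shank == s, ]
    g$id[which.min(abs(g$depth_index - pyr_depth))]
  }, numeric(1))
  rows <- which(ch$id %in% rep_ch)
  names(rows) <- ch$shank[rows]
  out <- NULL
  off_ep <- epochs[epochs$label == "off_pre", ]
  on_ep <- epochs[epochs$label == "on", ]
  for (i in seq_along(shanks)) {
    for (j in seq_along(shanks)) {
      if (j <= i) next
      xa <- rec$data[rows[as.character(shanks[i])], ]
      xb <- rec$data[rows[as.character(shanks[j])], ]
      out <- rbind(out, data.frame(
        shank_a = shanks[i], shank_b = shanks[j],
        distance = abs(shanks[j] - shanks[i]),
        coh_off = epoch_band_coherence(xa, xb, rec$rate, off_ep, band),
        coh_on = epoch_band_coherence(xa, xb, rec$rate, on_ep, band)))
    }
  }
  out
}

#' Assign CA1 layers from a ripple-triggered laminar profile
#'
#' The pyramidal-layer channel is the one maximising ripple-band
#' (100--250 Hz) RMS in the profile; channels dorsal to it (smaller
#' depth index) with a positive mean sharp-wave deflection over
#' +/- 50 ms are labelled oriens, ventral channels with a negative
#' deflection radiatum, everything else unknown.  If no channel's RMS
#' exceeds `rms_factor` times the median RMS the profile is considered
#' ambiguous and all channels stay unknown.
#'
#' @param profile list from [ripple_triggered_profile()].
#' @param rate sampling rate of the profile (Hz).
#' @param rms_factor pyramidale RMS prominence threshold (default 1.5).
#' @param sw_window half-window for the deflection sign in seconds
#'   (default 0.05).
#' @return data.frame: channel `id`, `depth_index`, `layer`.
#' @export
assign_layers <- function(profile, rate, rms_factor = 1.5, sw_window = 0.05) {
  ch <- profile$channels
  hp_rows <- which(ch$region == "HP")
  mat <- profile$profile
  nt <- ncol(mat)
  rms <- vapply(hp_rows, function(r) {
    seg <- mat[r, ] - mean(mat[r, ])
    bp <- tryCatch(fir_bandpass(seg, rate, 100, min(250, rate / 2),
                                transition = 20),
                   warning = function(w) suppressWarnings(
                     fir_bandpass(seg, rate, 100, min(250, rate / 2),
                                  transition = 20)))
    sqrt(mean(bp^2))
  }, numeric(1))
  out <- data.frame(id = ch$id[hp_rows],
                    depth_index = ch$depth_index[hp_rows],
                    layer = "unknown")
  if (length(hp_rows) > 1 && max(rms) <= rms_factor * stats::median(rms)) {
    warning("ambiguous laminar profile: no clear ripple-band RMS peak")
    return(out)
  }
  pyr_i <- which.max(rms)
  pyr_depth <- out$depth_index[pyr_i]
  out$layer[pyr_i] <- "pyramidale"
  mid <- (nt + 1) / 2
  win <- abs(seq_len(nt) - mid) <= sw_window * rate
  defl <- vapply(seq_along(hp_rows), function(i)
    mean(mat[hp_rows[i], win]) - mean(mat[hp_rows[i], !win]), numeric(1))
  # probe orientation is inferred from the sharp-wave polarity itself:
  # the side of pyramidale with positive deflections is stratum oriens
  dorsal <- out$depth_index < pyr_depth
  ventral <- out$depth_index > pyr_depth
  oriens_dorsal <- mean(defl[dorsal]) >= mean(defl[ventral])
  if (!any(dorsal) || !any(ventral))
    oriens_dorsal <- if (any(dorsal)) mean(defl[dorsal]) > 0 else
      !(mean(defl[ventral]) > 0)
  ori_side <- if (oriens_dorsal) dorsal else ventral
  rad_side <- if (oriens_dorsal) ventral else dorsal
  out$layer[ori_side & defl > 0] <- "oriens"
  out$layer[rad_side & defl < 0] <- "radiatum"
  out
}
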