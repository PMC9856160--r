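# Sharp-wave ripple detection and event metrics.
#
# Pipeline: downsample to 500 Hz -> band-pass 100-250 Hz (zero-phase
# FIR) -> rectify -> 20 Hz 4th-order Butterworth low-pass (smooth
# envelope) -> z-score over the whole trace -> threshold.  Events are
# the epochs exceeding `threshold` SD, extended to the surrounding
# `boundary` SD crossings, with a refractory merge window to prevent
# double detections.

#' Detect sharp-wave ripples on one LFP channel
#'
#' @param x LFP trace in microvolts.
#' @param rate sampling rate in Hz (the trace is downsampled to
#'   `work_rate` first when higher).
#' @param threshold detection threshold in envelope SD units (default 3.5).
#' @param boundary onset/end threshold in SD units (default 1).
#' @param refractory merge window in seconds (default 0.05): an event
#'   starting within this window of the previous event's end is merged
#'   into it.
#' @param work_rate processing rate in Hz (default 500).
#' @param channel_id id recorded in the output (default `NA`).
#' @return data.frame of events: `onset`, `end`, `peak_time` (s),
#'   `duration_ms`, `amplitude_z` (peak envelope z), `channel_id`;
#'   `peak_freq_hz` is filled by [ripple_metrics()].
#' @export
detect_ripples <- function(x, rate, threshold = 3.5, boundary = 1,
                           refractory = 0.05, work_rate = 500,
                           channel_id = NA_integer_) {
  if (length(x) < 2 * rate) stop("trace too short for ripple detection")
  if (stats::sd(x) == 0) stop("degenerate signal: zero variance")
  if (rate > work_rate) {
    x <- resample_signal(x, rate, work_rate)
    rate <- work_rate
  }
  bp <- fir_bandpass(x, rate, 100, min(250, rate / 2))
  env <- butter_lowpass(abs(bp), rate, cutoff = 20, order = 4)
  z <- zscore_signal(env)

  above <- z > threshold
  if (!any(above)) {
    return(data.frame(onset = numeric(0), end = numeric(0),
                      peak_time = numeric(0), duration_ms = numeric(0),
                      peak_freq_hz = numeric(0), amplitude_z = numeric(0),
                      channel_id = integer(0)))
  }
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L

  below <- z < boundary
  n <- length(z)
  onset_i <- integer(length(starts))
  end_i <- integer(length(starts))
  for (i in seq_along(starts)) {
    j <- starts[i]
    prior <- which(below[seq_len(j)])
    onset_i[i] <- if (length(prior)) max(prior) else 1L
    j2 <- ends[i]
    post <- which(below[j2:n])
    end_i[i] <- if (length(post)) j2 + min(post) - 1L else n
  }

  # merge events whose onset falls within the refractory window of the
  # previous event's end (also handles overlapping boundary extensions)
  ord <- order(onset_i)
  onset_i <- onset_i[ord]; end_i <- end_i[ord]
  keep_on <- onset_i[1]; keep_end <- end_i[1]
  for (i in seq_along(onset_i)[-1]) {
    gap <- (onset_i[i] - keep_end[length(keep_end)]) / rate
    if (gap <= refractory) {
      keep_end[length(keep_end)] <- max(keep_end[length(keep_end)], end_i[i])
    } else {
      keep_on <- c(keep_on, onset_i[i])
      keep_end <- c(keep_end, end_i[i])
    }
  }

  peak_i <- integer(length(keep_on))
  amp <- numeric(length(keep_on))
  for (i in seq_along(keep_on)) {
    seg <- keep_on[i]:keep_end[i]
    peak_i[i] <- seg[which.max(z[seg])]
    amp[i] <- z[peak_i[i]]
  }
  data.frame(
    onset = (keep_on - 1L) / rate,
    end = (keep_end - 1L) / rate,
    peak_time = (peak_i - 1L) / rate,
    duration_ms = (keep_end - keep_on) / rate * 1000,
    peak_freq_hz = NA_real_,
    amplitude_z = amp,
    channel_id = channel_id
  )
}

#' Fill per-event spectral metrics with Morlet wavelets
#'
#' For each event, the mean 7-cycle Morlet magnitude over the event
#' window is maximised over 100--250 Hz to give the peak frequency;
#' amplitude and duration stay as measured on the detection envelope.
#'
#' @param events data.frame from [detect_ripples()].
#' @param x the raw LFP trace the events were detected on.
#' @param rate sampling rate of `x` in Hz.
#' @param freq_step wavelet frequency grid step in Hz (default 2).
#' @param work_rate processing rate (default 500, matching detection).
#' @return `events` with `peak_freq_hz` filled.
#' @export
ripple_metrics <- function(events, x, rate, freq_step = 2, work_rate = 500) {
  if (!nrow(events)) return(events)
  if (rate > work_rate) {
    x <- resample_signal(x, rate, work_rate)
    rate <- work_rate
  }
  if (any(events$end > length(x) / rate + 1e-9))
    stop("event outside trace bounds")
  freqs <- seq(100, min(250, rate / 2), by = freq_step)
  pad <- 0.1
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor((events$onset[i] - pad) * rate) + 1L)
    i1 <- min(length(x), ceiling((events$end[i] + pad) * rate))
    tfr <- morlet_tfr(x[i0:i1], rate, freqs)
    j0 <- floor(events$onset[i] * rate) + 1L - i0 + 1L
    j1 <- floor(events$end[i] * rate) + 1L - i0 + 1L
    prof <- colMeans(tfr[j0:j1, , drop = FALSE])
    events$peak_freq_hz[i] <- freqs[which.max(prof)]
  }
  events
}

#' Peri-stimulus ripple density and on/off contrast
#'
#' Bins event times relative to each pulse onset over `[-lead, pulse)`
#' seconds, averages across trials, and contrasts the on-epoch mean
#' rate against the pre-pulse mean: `(on - off) / off`.
#'
#' @param events data.frame with a `peak_time` (or `onset`) column.
#' @param protocol a [stim_protocol()].
#' @param bin bin width in seconds (default 5).
#' @param lead pre-onset window length in seconds (default 15).
#' @return list: `curve` (data.frame `t0`, `t1`, `rate_hz`, `sem`),
#'   `off_rate`, `on_rate`, `contrast` (fractional change).
#' @export
ripple_density <- function(events, protocol, bin = 5, lead = 15) {
  tt <- if (nrow(events)) {
    if (!is.null(events$peak_time)) events$peak_time else events$onset
  } else numeric(0)
  d <- protocol$pulse_duration
  edges <- seq(-lead, d, by = bin)
  nb <- length(edges) - 1L
  counts <- matrix(0, length(protocol$onsets), nb)
  for (i in seq_along(protocol$onsets)) {
    rel <- tt - protocol$onsets[i]
    sel <- rel >= -lead & rel < d
    if (any(sel))
      counts[i, ] <- tabulate(findInterval(rel[sel], edges), nbins = nb)
  }
  rates <- counts / bin
  curve <- data.frame(t0 = edges[-length(edges)], t1 = edges[-1],
                      rate_hz = colMeans(rates),
                      sem = apply(rates, 2, stats::sd) / sqrt(nrow(rates)))
  off_rate <- mean(rates[, edges[-length(edges)] < 0])
  on_rate <- mean(rates[, edges[-length(edges)] >= 0])
  if (off_rate == 0) {
    warning("no off-epoch events: contrast undefined")
    contrast <- NA_real_
  } else {
    contrast <- (on_rate - off_rate) / off_rate
  }
  list(curve = curve, off_rate = off_rate, on_rate = on_rate,
       contrast = contrast)
}

#' Ripple-triggered laminar LFP profile
#'
#' Per-channel average of the raw LFP in `+/- half_window` around each
#' event peak; the basis for CA1 layer assignment from sharp-wave
#' polarity and ripple-band amplitude.
#'
#' @param events data.frame with `peak_time` (seconds).
#' @param rec a [recording()].
#' @param half_window seconds around the peak (default 0.1).
#' @return list: `profile` (channels x time matrix), `time` (s relative
#'   to peak), `n_events`, `channels` (metadata of `rec`).
#' @export
ripple_triggered_profile <- function(events, rec, half_window = 0.1) {
  if (nrow(events) < 10)
    warning("fewer than 10 events: laminar profile unreliable")
  rate <- rec$rate
  hw <- round(half_window * rate)
  n <- ncol(rec$data)
  acc <- matrix(0, nrow(rec$data), 2L * hw + 1L)
  used <- 0L
  for (tp in events$peak_time) {
    ic <- round(tp * rate) + 1L
    if (ic - hw < 1L || ic + hw > n) next
    acc <- acc + rec$data[, (ic - hw):(ic + hw), drop = FALSE]
    used <- used + 1L
  }
  if (used == 0) stop("no events fully inside the trace")
  list(profile = acc / used, time = seq(-hw, hw) / rate,
       n_events = used, channels = rec$channels)
}
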