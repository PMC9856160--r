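# Synthetic septo-hippocampal session generator.
#
# Emulates a 10-min urethane-state recording under a 15 s off / 5 s on
# light protocol: hippocampal channels carry a 1/f background, a slow
# (0.5-3 Hz) oscillation, a drifting theta rhythm (4-7 Hz), slow- and
# high-gamma components and laminar sharp-wave ripples; septal channels
# carry the same theta leading the hippocampal copy by a fixed lag
# (directional MS -> HP coupling).  Spike trains are inhomogeneous point
# processes locked to the theta phase with class-specific on-epoch
# gains.  All stochastic draws run off the single seed in the config.

#' Synthetic session configuration
#'
#' Defaults encode the effect sizes the analyses are validated against:
#' a 14.8% on-epoch theta power gain, a 17.3% ripple-density drop,
#' septal excited/inhibited fractions 21.5%/7.3% with gains
#' 1.532/0.545, hippocampal fractions 20.2%/4.7% with gains
#' 1.341/0.806, and a negative coupling between slow-wave amplitude and
#' the septo-hippocampal theta drive.
#'
#' @param seed integer seed driving every random draw.
#' @param session_length seconds (default 600).
#' @param rate sampling rate in Hz (default 1000; analyses downsample to
#'   500 Hz, which still covers the 100--250 Hz ripple band).
#' @param n_hp_channels hippocampal channels spanning oriens to radiatum
#'   (default 8).
#' @param n_ms_channels septal channels (default 2).
#' @param theta_freq centre theta frequency in Hz (default 5.5; the
#'   instantaneous frequency drifts inside 4--7 Hz).
#' @param theta_power_gain_on multiplicative theta-band power gain
#'   during light pulses (default 1.148).
#' @param ripple_rate_off ripple rate outside pulses, events/s (default 0.3).
#' @param ripple_rate_gain_on multiplicative ripple-rate factor during
#'   pulses (default 0.827).
#' @param frac_hp_excited,hp_excited_gain,frac_hp_inhibited,hp_inhibited_gain
#'   hippocampal response-class fractions and rate gains.
#' @param frac_ms_excited,ms_excited_gain,frac_ms_inhibited,ms_inhibited_gain
#'   septal response-class fractions and rate gains.
#' @param kappa_theta_locking von Mises concentration of spike phase
#'   locking (default 1).
#' @param ms_to_hp_lag septal theta lead over hippocampus in seconds
#'   (default 0.02).
#' @param delta_gc_coupling coupling in [-1, 0] between slow-wave
#'   amplitude and the MS->HP theta drive (default -0.3: strong slow
#'   waves co-occur with weak theta transfer).
#' @param n_units_per_region units per region (default 40).
#' @param ripple_amp_z ripple burst amplitude in multiples of the
#'   ripple-band background SD (default 6).
#' @param gain_cv within-class coefficient of variation of unit gains
#'   (default 0.1, log-normal).
#' @param pyr_depth depth index of stratum pyramidale (default 3).
#' @param blockade_onset optional time (s) after which the theta gain
#'   reverts to 1, emulating local cholinergic receptor blockade
#'   (default `NULL`, no blockade).
#' @param pulse_duration,period protocol geometry in seconds.
#' @return a `synth_config` object (a validated list).
#' @export
synth_config <- function(seed = 1,
                         session_length = 600,
                         rate = 1000,
                         n_hp_channels = 8,
                         n_ms_channels = 2,
                         theta_freq = 5.5,
                         theta_power_gain_on = 1.148,
                         ripple_rate_off = 0.3,
                         ripple_rate_gain_on = 0.827,
                         frac_hp_excited = 0.202,
                         hp_excited_gain = 1.341,
                         frac_hp_inhibited = 0.047,
                         hp_inhibited_gain = 0.806,
                         frac_ms_excited = 0.215,
                         ms_excited_gain = 1.532,
                         frac_ms_inhibited = 0.073,
                         ms_inhibited_gain = 0.545,
                         kappa_theta_locking = 1.0,
                         ms_to_hp_lag = 0.02,
                         delta_gc_coupling = -0.3,
                         n_units_per_region = 40,
                         ripple_amp_z = 6,
                         gain_cv = 0.1,
                         pyr_depth = 3,
                         blockade_onset = NULL,
                         pulse_duration = 5,
                         period = 20) {
  stopifnot(rate >= 500, session_length > 0,
            frac_hp_excited + frac_hp_inhibited <= 1,
            frac_ms_excited + frac_ms_inhibited <= 1,
            hp_excited_gain > 0, ms_excited_gain > 0,
            delta_gc_coupling <= 0, delta_gc_coupling >= -1,
            pyr_depth >= 0, pyr_depth < n_hp_channels)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

# Internal: smooth unit-SD noise from spline-interpolated Gaussian knots
# spaced `knot_s` seconds apart (correlation time ~ knot spacing).
smooth_noise <- function(n, rate, knot_s) {
  nk <- max(4L, ceiling(n / rate / knot_s) + 3L)
  kt <- seq(-knot_s, n / rate + knot_s, length.out = nk)
  kv <- stats::rnorm(nk)
  v <- stats::spline(kt, kv, xout = (seq_len(n) - 1L) / rate)$y
  v / stats::sd(v)
}

# Internal: unit-SD Gaussian noise band-limited to [lo, hi] Hz via FFT
# masking.
band_noise <- function(n, rate, lo, hi) {
  nfft <- stats::nextn(n, 2)
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- c(0:(nfft / 2), -(nfft / 2 - 1):-1) * rate / nfft
  X[abs(f) < lo | abs(f) > hi] <- 0
  v <- Re(stats::fft(X, inverse = TRUE) / nfft)[seq_len(n)]
  v / stats::sd(v)
}

# Internal: 1/f-power background noise (amplitude ~ f^(-1/2) above f_min)
# scaled to unit SD.
pink_noise <- function(n, rate, f_min = 0.5) {
  nfft <- stats::nextn(n, 2)
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- abs(c(0:(nfft / 2), -(nfft / 2 - 1):-1)) * rate / nfft
  amp <- 1 / sqrt(pmax(f, f_min))
  amp[1] <- 0
  v <- Re(stats::fft(X * amp, inverse = TRUE) / nfft)[seq_len(n)]
  v / stats::sd(v)
}

#' Parametric ripple burst waveform
#'
#' Gaussian-windowed sinusoid: `amp * exp(-t^2 / (2*(dur/6)^2)) *
#' cos(2*pi*freq*t)` sampled over +/- dur/2 around the centre.
#'
#' @param rate sampling rate in Hz.
#' @param freq oscillation frequency in Hz (default 150).
#' @param duration burst duration in seconds (default 0.06).
#' @param amplitude peak amplitude (default 1).
#' @return numeric waveform of `round(duration*rate)+1` samples.
#' @export
synth_ripple_burst <- function(rate, freq = 150, duration = 0.06,
                               amplitude = 1) {
  half <- round(duration * rate / 2)
  tt <- seq(-half, half) / rate
  amplitude * exp(-tt^2 / (2 * (duration / 6)^2)) * cos(2 * pi * freq * tt)
}

#' Inject ripple bursts into a trace at known times
#'
#' Scales each burst to `amp_z` multiples of the ripple-band
#' (100--250 Hz) standard deviation of the input trace, giving detector
#' tests an exact ground truth.
#'
#' @param x background trace (numeric vector, microvolts).
#' @param rate sampling rate in Hz.
#' @param times burst centre times in seconds.
#' @param freq,duration burst parameters (Hz, seconds).
#' @param amp_z burst amplitude in ripple-band-SD units (default 6).
#' @return list with `signal` (trace plus bursts) and `truth`
#'   (data.frame: centre, onset, end, freq, duration, amplitude_uv).
#' @export
inject_ripples <- function(x, rate, times, freq = 150, duration = 0.06,
                           amp_z = 6) {
  band_sd <- stats::sd(fir_bandpass(x, rate, 100, min(250, rate / 2),
                                    transition = 10))
  amp <- amp_z * band_sd
  w <- synth_ripple_burst(rate, freq, duration, amp)
  half <- (length(w) - 1L) / 2L
  for (tc in times) {
    ic <- round(tc * rate) + 1L
    idx <- (ic - half):(ic + half)
    ok <- idx >= 1L & idx <= length(x)
    x[idx[ok]] <- x[idx[ok]] + w[ok]
  }
  list(signal = x,
       truth = data.frame(centre = times, onset = times - duration / 2,
                          end = times + duration / 2, freq = freq,
                          duration = duration, amplitude_uv = amp))
}

# Internal: per-sample on-pulse logical mask for a protocol.
on_mask <- function(protocol, rate, n) {
  m <- logical(n)
  for (t in protocol$onsets) {
    i0 <- floor(t * rate) + 1L
    i1 <- min(n, floor((t + protocol$pulse_duration) * rate))
    m[i0:i1] <- TRUE
  }
  m
}

#' Generate the multichannel LFP of a synthetic session
#'
#' See [synth_config()] for the signal model.  The returned recording
#' carries a `truth` attribute with the injected ground truth: the
#' ripple event table, the hippocampal and septal theta phase traces,
#' the theta-drive envelope, the protocol and the laminar layout.
#'
#' @param cfg a [synth_config()].
#' @return a [recording()] (channels: HP by increasing depth, then MS).
#' @export
generate_lfp <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  rate <- cfg$rate
  n <- round(cfg$session_length * rate)
  protocol <- default_protocol(cfg$session_length, cfg$pulse_duration, cfg$period)
  on <- on_mask(protocol, rate, n)

  # theta: drifting frequency inside 4-7 Hz, stochastic amplitude
  f_inst <- pmin(7, pmax(4, cfg$theta_freq + 0.6 * smooth_noise(n, rate, 20)))
  phase_ms <- 2 * pi * cumsum(f_inst) / rate
  env_theta <- 1 + 0.08 * smooth_noise(n, rate, 25)
  env_theta <- pmax(env_theta, 0.1)
  ms_theta_core <- env_theta * cos(phase_ms)

  # MS -> HP theta-transfer weight (the coherent fraction of HP theta
  # predictable from the septal rhythm) and the anticorrelated
  # slow-wave envelope: strong slow waves co-occur with weak transfer
  w_drive <- pmin(0.97, pmax(0.25, 0.75 + 0.25 * smooth_noise(n, rate, 25)))
  slow_env <- pmax(0.15, 1 + cfg$delta_gc_coupling * (w_drive - 0.75) / 0.25)
  # transfer loss realised as slow phase jitter: leaves theta power
  # untouched while the MS-coherent amplitude fraction equals w_drive
  sigma_jit <- sqrt(pmax(0, -2 * log(w_drive)))
  jit <- smooth_noise(n, rate, 1)

  # theta gain during pulses (reverts to 1 after a cholinergic blockade)
  g_theta <- rep(1, n)
  g_on <- sqrt(cfg$theta_power_gain_on)
  tvec_on <- which(on)
  if (!is.null(cfg$blockade_onset)) {
    keep <- tvec_on <= cfg$blockade_onset * rate
    g_theta[tvec_on[keep]] <- g_on
  } else {
    g_theta[tvec_on] <- g_on
  }

  lagn <- round(cfg$ms_to_hp_lag * rate)
  lagged <- function(v) c(rep(v[1], lagn), v[seq_len(n - lagn)])
  phase_hp <- lagged(phase_ms) + sigma_jit * jit
  hp_theta_core <- lagged(env_theta) * cos(phase_hp)

  a_theta <- 150; a_slow <- 250; a_sg <- 30; a_hg <- 15; a_bg <- 45
  slow_base <- band_noise(n, rate, 0.5, 3)
  hp_slow <- a_slow * slow_env * slow_base
  hp_theta <- a_theta * g_theta * hp_theta_core
  sg <- a_sg * band_noise(n, rate, 25, 35)
  hg <- a_hg * band_noise(n, rate, 65, 100)

  nch_hp <- cfg$n_hp_channels
  nch <- nch_hp + cfg$n_ms_channels
  data <- matrix(0, nch, n)
  depth <- seq_len(nch_hp) - 1L
  for (ch in seq_len(nch_hp)) {
    data[ch, ] <- hp_slow + hp_theta + sg + hg + a_bg * pink_noise(n, rate)
  }

  # ripple events with laminar sharp-wave polarity
  pyr <- cfg$pyr_depth
  band_sd <- stats::sd(fir_bandpass(data[pyr + 1L, seq_len(min(n, 60L * rate))],
                                    rate, 100, min(250, rate / 2),
                                    transition = 10))
  ev <- NULL
  seg_bounds <- sort(unique(c(0, protocol$onsets,
                              protocol$onsets + protocol$pulse_duration,
                              cfg$session_length)))
  for (si in seq_len(length(seg_bounds) - 1L)) {
    s0 <- seg_bounds[si]; s1 <- seg_bounds[si + 1L]
    seg_on <- any(protocol$onsets <= s0 + 1e-9 &
                    protocol$onsets + protocol$pulse_duration >= s1 - 1e-9)
    lam <- cfg$ripple_rate_off * if (seg_on) cfg$ripple_rate_gain_on else 1
    k <- stats::rpois(1, lam * (s1 - s0))
    if (k > 0) ev <- c(ev, stats::runif(k, s0, s1))
  }
  ev <- sort(ev)
  ev <- ev[ev > 0.5 & ev < cfg$session_length - 0.5]
  if (length(ev) > 1) ev <- ev[c(TRUE, diff(ev) > 0.2)]
  ripples <- NULL
  if (length(ev)) {
    dur <- stats::runif(length(ev), 0.05, 0.08)
    frq <- pmin(200, pmax(120, stats::rnorm(length(ev), 150, 10)))
    amp <- cfg$ripple_amp_z * band_sd *
      exp(stats::rnorm(length(ev), 0, 0.08))
    pol_denom <- max(pyr, nch_hp - 1L - pyr, 1L)
    ripple_gain <- exp(-(depth - pyr)^2 / (2 * 0.8^2))
    sw_pol <- (pyr - depth) / pol_denom
    for (i in seq_along(ev)) {
      half <- round(dur[i] * rate / 2)
      ic <- round(ev[i] * rate) + 1L
      idx <- (ic - half):(ic + half)
      ok <- idx >= 1L & idx <= n
      tt <- (idx[ok] - ic) / rate
      burst <- exp(-tt^2 / (2 * (dur[i] / 6)^2)) * cos(2 * pi * frq[i] * tt)
      swh <- round(0.05 * rate)
      sidx <- (ic - swh):(ic + swh)
      sok <- sidx >= 1L & sidx <= n
      stt <- (sidx[sok] - ic) / rate
      sw <- exp(-stt^2 / (2 * 0.02^2))
      for (ch in seq_len(nch_hp)) {
        data[ch, idx[ok]] <- data[ch, idx[ok]] +
          amp[i] * ripple_gain[ch] * burst
        data[ch, sidx[sok]] <- data[ch, sidx[sok]] +
          3 * amp[i] * sw_pol[ch] * sw
      }
    }
    ripples <- data.frame(centre = ev, onset = ev - dur / 2, end = ev + dur / 2,
                          freq = frq, duration_ms = dur * 1000,
                          amplitude_uv = amp)
  }

  # septal channels: leading theta + own slow component + background
  for (j in seq_len(cfg$n_ms_channels)) {
    ch <- nch_hp + j
    data[ch, ] <- a_theta * ms_theta_core +
      0.5 * a_slow * band_noise(n, rate, 0.5, 3) +
      a_bg * pink_noise(n, rate)
  }

  layer <- rep("unknown", nch)
  layer[seq_len(nch_hp)] <- ifelse(depth < pyr, "oriens",
                                   ifelse(depth == pyr, "pyramidale", "radiatum"))
  channels <- data.frame(
    id = seq_len(nch) - 1L,
    region = c(rep("HP", nch_hp), rep("MS", cfg$n_ms_channels)),
    shank = c(depth %/% max(1L, (nch_hp %/% 4L)), rep(0L, cfg$n_ms_channels)),
    depth_index = c(depth, seq_len(cfg$n_ms_channels) - 1L),
    layer = layer
  )
  rec <- recording(data, rate, channels,
                   session_id = sprintf("synth-%d", cfg$seed))
  attr(rec, "truth") <- list(
    ripples = ripples, protocol = protocol,
    phase_hp = phase_hp, phase_ms = phase_ms,
    drive_env = w_drive[seq(1, n, by = max(1L, rate %/% 10))],
    pyr_channel = pyr, band_sd = band_sd
  )
  rec
}

#' Generate spike trains for a synthetic session
#'
#' Each unit is an inhomogeneous point process: log-normal baseline
#' rate, von Mises theta phase modulation sharing the LFP theta phase,
#' a class gain applied during light pulses, and (for hippocampal
#' "pyramidal" units) a rate boost inside ripple events.  Unit class
#' labels, gains and baselines are returned in the `truth` attribute.
#'
#' @param cfg a [synth_config()].
#' @param rec the matching [generate_lfp()] recording (shares the theta
#'   phase trace).
#' @return a [spike_train_set()] with a `truth` attribute (data.frame).
#' @export
generate_spikes <- function(cfg, rec) {
  truth <- attr(rec, "truth")
  if (is.null(truth)) stop("recording lacks generator ground truth")
  set.seed(cfg$seed + 1000003L)
  rate <- rec$rate
  n <- ncol(rec$data)
  protocol <- truth$protocol
  onsets <- protocol$onsets
  pd <- protocol$pulse_duration
  kappa <- cfg$kappa_theta_locking
  i0k <- besselI(kappa, 0)
  sdlog <- sqrt(log(1 + cfg$gain_cv^2))

  rip_iv <- if (!is.null(truth$ripples))
    truth$ripples[, c("onset", "end")] else NULL

  make_units <- function(region, n_units, frac_exc, gain_exc, frac_inh, gain_inh) {
    n_exc <- round(frac_exc * n_units)
    n_inh <- round(frac_inh * n_units)
    cls <- c(rep("excited", n_exc), rep("inhibited", n_inh),
             rep("none", n_units - n_exc - n_inh))
    cls <- sample(cls)
    phase <- if (region == "HP") truth$phase_hp else truth$phase_ms
    units <- vector("list", n_units)
    meta <- NULL
    for (u in seq_len(n_units)) {
      base <- stats::rlnorm(1, log(4), 0.5)
      subtype <- if (region == "HP" && stats::runif(1) < 0.75) "pyr" else "int"
      if (region == "HP" && subtype == "int") base <- base * 2.5
      g <- switch(cls[u],
                  excited = gain_exc * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)),
                  inhibited = gain_inh * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)),
                  none = 1)
      phi <- stats::runif(1, -pi, pi)
      boost <- if (region == "HP" && subtype == "pyr") 3 else 1
      lam_max <- base * exp(kappa) / i0k * max(1, g) * boost
      n_cand <- stats::rpois(1, lam_max * cfg$session_length)
      tc <- sort(stats::runif(n_cand, 0, cfg$session_length))
      idx <- pmin(n, floor(tc * rate) + 1L)
      lam <- base * exp(kappa * cos(phase[idx] - phi)) / i0k
      ponset <- findInterval(tc, onsets)
      on_c <- ponset > 0 & (tc - onsets[pmax(1, ponset)]) < pd
      lam[on_c] <- lam[on_c] * g
      if (boost > 1 && !is.null(rip_iv) && nrow(rip_iv)) {
        ri <- findInterval(tc, rip_iv$onset)
        in_rip <- ri > 0 & tc < rip_iv$end[pmax(1, ri)]
        lam[in_rip] <- lam[in_rip] * boost
      }
      keep <- stats::runif(n_cand) < lam / lam_max
      tt <- tc[keep]
      tt <- tt[c(TRUE, diff(tt) > 0)]
      uid <- sprintf("%s%02d", tolower(region), u)
      units[[u]] <- list(unit_id = uid, region = region, times = tt)
      meta <- rbind(meta, data.frame(
        unit_id = uid, region = region, class = cls[u], gain = g,
        base_rate = base, subtype = subtype, phase_pref = phi))
    }
    list(units = units, meta = meta)
  }

  hp <- make_units("HP", cfg$n_units_per_region, cfg$frac_hp_excited,
                   cfg$hp_excited_gain, cfg$frac_hp_inhibited,
                   cfg$hp_inhibited_gain)
  ms <- make_units("MS", cfg$n_units_per_region, cfg$frac_ms_excited,
                   cfg$ms_excited_gain, cfg$frac_ms_inhibited,
                   cfg$ms_inhibited_gain)
  out <- spike_train_set(c(hp$units, ms$units))
  attr(out, "truth") <- rbind(hp$meta, ms$meta)
  out
}

#' Generate a full synthetic session
#'
#' Bundles [generate_lfp()], [generate_spikes()] and the default
#' 15 s off / 5 s on protocol; optionally writes the three fixture
#' files (`<name>.dat` + `.json`, `spikes.csv`, `protocol.csv`).
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory for fixture files.
#' @return list with `recording`, `spikes`, `protocol`.
#' @export
generate_session <- function(cfg, out_dir = NULL) {
  rec <- generate_lfp(cfg)
  spikes <- generate_spikes(cfg, rec)
  protocol <- attr(rec, "truth")$protocol
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_recording(rec, file.path(out_dir, "session.dat"),
                    file.path(out_dir, "session.json"), scale = 0.5)
    write_spikes(spikes, file.path(out_dir, "spikes.csv"))
    write_protocol(protocol, file.path(out_dir, "protocol.csv"))
  }
  list(recording = rec, spikes = spikes, protocol = protocol)
}
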