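# Event-triggered "sliding-sweeps" unit analysis with interval-shuffle
# significance.
#
# For each light pulse a +/-15 s window (500 ms bins, 60 bins) around
# the onset is turned into a template of per-bin spike fractions; the
# trial-averaged template is compared against a null built by
# independently permuting the unit's inter-spike intervals and the
# protocol's inter-onset intervals.

SWEEP_WINDOW <- 15
SWEEP_BIN <- 0.5

#' Trial-averaged sliding-sweeps template
#'
#' Bins spikes in `[-window, window)` around each onset (bin width
#' `bin` s), normalises each trial's vector to sum to 1 (trials without
#' spikes are skipped), and averages across trials.
#'
#' @param times spike times in seconds.
#' @param onsets pulse onset times in seconds; windows must lie inside
#'   `[0, session_length]` (incomplete windows are dropped).
#' @param session_length session length in seconds.
#' @param window half-window in seconds (default 15).
#' @param bin bin width in seconds (default 0.5).
#' @param pool normalise pooled counts instead of per-trial templates
#'   (default FALSE: per-trial normalisation before averaging).
#' @return a `sweep_template`: list with `bins` (fractions, summing to
#'   1), `edges` (bin left edges, s), `n_trials` (usable trials),
#'   `n_trials_total`.
#' @export
sliding_sweeps <- function(times, onsets, session_length = 600,
                           window = SWEEP_WINDOW, bin = SWEEP_BIN,
                           pool = FALSE) {
  onsets <- onsets[onsets - window >= 0 & onsets + window <= session_length]
  nb <- as.integer(round(2 * window / bin))
  if (length(onsets) < 5) stop("fewer than 5 usable trials")
  counts <- matrix(0, length(onsets), nb)
  for (i in seq_along(onsets)) {
    rel <- times - onsets[i]
    sel <- rel >= -window & rel < window
    if (any(sel))
      counts[i, ] <- tabulate(floor((rel[sel] + window) / bin) + 1L, nbins = nb)
  }
  tot <- rowSums(counts)
  usable <- tot > 0
  if (!any(usable)) stop("no spikes in any trial window")
  bins <- if (pool) {
    colSums(counts) / sum(counts)
  } else {
    colMeans(counts[usable, , drop = FALSE] / tot[usable])
  }
  structure(list(bins = bins,
                 edges = seq(-window, window - bin, by = bin),
                 n_trials = sum(usable),
                 n_trials_total = length(onsets)),
            class = "sweep_template")
}

# Internal: the on-window statistic = mean template mass per bin over
# [0, on_duration) (1/60 under a flat template).
on_window_stat <- function(template, on_duration = 5) {
  sel <- template$edges >= 0 & template$edges < on_duration
  mean(template$bins[sel])
}

# Internal: fast statistic without building the full template: mean over
# usable trials of (fraction of window spikes in [0, on_duration)) per
# bin.  `times` must be sorted ascending.
fast_on_stat <- function(times, onsets, window, on_duration, n_on_bins) {
  lo <- findInterval(onsets - window - 1e-12, times)
  hi <- findInterval(onsets + window - 1e-12, times)
  a <- findInterval(onsets - 1e-12, times)
  b <- findInterval(onsets + on_duration - 1e-12, times)
  n_win <- hi - lo
  n_on <- b - a
  use <- n_win > 0
  if (!any(use)) return(NA_real_)
  mean(n_on[use] / n_win[use]) / n_on_bins
}

#' Interval-shuffle null distribution of the on-window statistic
#'
#' Each shuffle independently permutes the unit's inter-spike intervals
#' and the protocol's inter-onset intervals (both including the initial
#' offset from the session start), rebuilds the two timestamp
#' sequences, and recomputes the mean normalised on-window mass.  The
#' shuffle conserves spike count, the interval multiset and the total
#' span exactly.
#'
#' @param times spike times in seconds.
#' @param onsets pulse onset times in seconds.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed RNG seed for reproducibility (default 1).
#' @param session_length session length in seconds.
#' @param window,bin,on_duration sweep geometry (seconds).
#' @return numeric vector of `n_shuffles` null statistics.
#' @export
shuffle_null <- function(times, onsets, n_shuffles = 1000, seed = 1,
                         session_length = 600, window = SWEEP_WINDOW,
                         bin = SWEEP_BIN, on_duration = 5) {
  if (length(times) < 2 || length(onsets) < 2)
    stop("need at least 2 spikes and 2 onsets")
  set.seed(seed)
  isi <- diff(c(0, times))
  ioi <- diff(c(0, onsets))
  n_on_bins <- round(on_duration / bin)
  out <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    ts <- cumsum(sample(isi))
    os <- cumsum(sample(ioi))
    os <- os[os - window >= 0 & os + window <= session_length]
    out[s] <- if (length(os)) {
      fast_on_stat(ts, os, window, on_duration, n_on_bins)
    } else NA_real_
  }
  out[!is.na(out)]
}

#' Classify a unit against its shuffle null
#'
#' Excited if the observed on-window mass exceeds the `1 - alpha/2`
#' null quantile, inhibited if below the `alpha/2` quantile, otherwise
#' unmodulated.  The effect size is the percent change of the on-epoch
#' firing rate relative to the off-epoch rate.
#'
#' @param template a [sliding_sweeps()] template.
#' @param null numeric vector from [shuffle_null()].
#' @param off_rate,on_rate firing rates (Hz) in the off / on epochs.
#' @param alpha two-sided level (default 0.05).
#' @param on_duration seconds (default 5).
#' @return list: `label` ("excited"/"inhibited"/"none"), `effect_pct`,
#'   `p_like` (attained null quantile of the observed statistic),
#'   `stat`, `lo`, `hi` (the null band).
#' @export
classify_unit <- function(template, null, off_rate, on_rate,
                          alpha = 0.05, on_duration = 5) {
  stat <- on_window_stat(template, on_duration)
  qs <- stats::quantile(null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  label <- if (stat > qs[2]) "excited" else if (stat < qs[1]) "inhibited" else "none"
  effect <- if (off_rate > 0) {
    100 * (on_rate - off_rate) / off_rate
  } else {
    warning("off-epoch rate is zero: effect size undefined")
    NA_real_
  }
  list(label = label, effect_pct = effect,
       p_like = mean(null < stat) + 0.5 * mean(null == stat),
       stat = stat, lo = qs[1], hi = qs[2])
}

#' Firing rates of one unit in on and off epochs
#'
#' @param times spike times (s).
#' @param epochs data.frame from [epochs_from_protocol()].
#' @return list with `off_rate`, `on_rate` in Hz.
#' @export
epoch_rates <- function(times, epochs) {
  off <- count_in_epochs(times, epochs[epochs$label == "off_pre", ])
  on <- count_in_epochs(times, epochs[epochs$label == "on", ])
  list(off_rate = off$count / off$duration, on_rate = on$count / on$duration)
}

#' Classify every unit of a spike-train set
#'
#' Runs [sliding_sweeps()], [shuffle_null()] and [classify_unit()] per
#' unit.  Shuffle seeds are derived deterministically from `seed` and
#' the unit index.
#'
#' @param spikes a [spike_train_set()].
#' @param protocol a [stim_protocol()].
#' @param n_shuffles shuffles per unit (default 1000).
#' @param seed base seed (default 1).
#' @param alpha two-sided level (default 0.05).
#' @return data.frame: unit_id, region, label, effect_pct, p_like,
#'   off_rate_hz, on_rate_hz.
#' @export
classify_units <- function(spikes, protocol, n_shuffles = 1000, seed = 1,
                           alpha = 0.05) {
  epochs <- epochs_from_protocol(protocol)
  out <- NULL
  for (i in seq_along(spikes$units)) {
    u <- spikes$units[[i]]
    row <- data.frame(unit_id = u$unit_id, region = u$region,
                      label = "none", effect_pct = NA_real_,
                      p_like = NA_real_, off_rate_hz = NA_real_,
                      on_rate_hz = NA_real_)
    res <- try({
      tmpl <- sliding_sweeps(u$times, protocol$onsets,
                             session_length = protocol$session_length)
      null <- shuffle_null(u$times, protocol$onsets,
                           n_shuffles = n_shuffles, seed = seed + i,
                           session_length = protocol$session_length,
                           on_duration = protocol$pulse_duration)
      rates <- epoch_rates(u$times, epochs)
      cl <- classify_unit(tmpl, null, rates$off_rate, rates$on_rate,
                          alpha = alpha,
                          on_duration = protocol$pulse_duration)
      row$label <- cl$label
      row$effect_pct <- cl$effect_pct
      row$p_like <- cl$p_like
      row$off_rate_hz <- rates$off_rate
      row$on_rate_hz <- rates$on_rate
    }, silent = TRUE)
    out <- rbind(out, row)
  }
  out
}

#' Population summary of unit classifications
#'
#' @param classifications data.frame from [classify_units()] (one region).
#' @return list: `n`, `frac_excited`, `frac_inhibited`, per-class mean
#'   and SEM of `effect_pct`, and `global_rate_change_pct` (percent
#'   change of the summed population rate, on vs off).
#' @export
population_summary <- function(classifications) {
  cl <- classifications
  if (nrow(cl) < 10) stop("need at least 10 units for a population summary")
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  exc <- cl$effect_pct[cl$label == "excited" & is.finite(cl$effect_pct)]
  inh <- cl$effect_pct[cl$label == "inhibited" & is.finite(cl$effect_pct)]
  off_sum <- sum(cl$off_rate_hz, na.rm = TRUE)
  on_sum <- sum(cl$on_rate_hz, na.rm = TRUE)
  list(
    n = nrow(cl),
    frac_excited = mean(cl$label == "excited"),
    frac_inhibited = mean(cl$label == "inhibited"),
    mean_excited_pct = if (length(exc)) mean(exc) else NA_real_,
    sem_excited_pct = sem(exc),
    mean_inhibited_pct = if (length(inh)) mean(inh) else NA_real_,
    sem_inhibited_pct = sem(inh),
    global_rate_change_pct = 100 * (on_sum - off_sum) / off_sum
  )
}
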