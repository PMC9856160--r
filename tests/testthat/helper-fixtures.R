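# Small fixtures shared across tests.  Everything is generated in code;
# sizes are kept desk-scale so the default run stays fast.

quick_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_hp_channels = 1, n_ms_channels = 1,
               pyr_depth = 0, ...)
}

# short one-channel background without ripples, for detector fixtures
ripple_free_trace <- function(seed, length_s = 120) {
  cfg <- quick_cfg(seed, session_length = length_s, ripple_rate_off = 0)
  generate_lfp(cfg)$data[1, ]
}

# deterministic burst centres with a minimum separation
burst_times <- function(seed, n = 20, t0 = 3, t1 = 117, min_gap = 0.5) {
  set.seed(seed)
  repeat {
    tt <- sort(runif(n, t0, t1))
    if (all(diff(tt) > min_gap)) return(tt)
  }
}

sine <- function(freq, rate, n, phase = 0) {
  cos(2 * pi * freq * (0:(n - 1)) / rate + phase)
}
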