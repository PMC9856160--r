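test_that("sweep templates: normalisation, delta case, flat null", {
  onsets <- default_protocol()$onsets
  # all spikes just after onsets: the first on bin holds everything
  times <- sort(onsets + 0.1)
  tm <- sliding_sweeps(times, onsets)
  expect_equal(sum(tm$bins), 1)
  expect_equal(tm$bins[tm$edges == 0], 1)
  expect_equal(sum(tm$bins != 0), 1L)
  # homogeneous Poisson: near-flat template
  set.seed(21)
  pt <- cumsum(rexp(3000, 5))
  tp <- sliding_sweeps(pt, onsets)
  expect_equal(sum(tp$bins), 1, tolerance = 1e-12)
  expect_lt(max(abs(tp$bins - 1 / 60)), 0.5 / 60)
  expect_error(sliding_sweeps(numeric(0), onsets), "no spikes")
  expect_error(sliding_sweeps(pt, onsets[1:3]), "fewer than 5")
})

test_that("a 2x on-epoch gain matches the closed-form template expectation", {
  # closed form: 10 on bins at weight 2, 50 off bins at weight 1 ->
  # on-bin mass = 2 / (2*10 + 50) each
  onsets <- default_protocol()$onsets
  set.seed(22)
  lam <- function(t) ifelse((t %% 20) >= 15, 10, 5)  # pulses at 15..20 in each cycle
  cand <- cumsum(rexp(12000, 10))
  keep <- runif(length(cand)) < lam(cand) / 10
  times <- cand[keep & cand < 600]
  tm <- sliding_sweeps(times, onsets)
  on_mass <- mean(tm$bins[tm$edges >= 0 & tm$edges < 5])
  expect_equal(on_mass, 2 / 70, tolerance = 0.07)
  off_mass <- mean(tm$bins[tm$edges < 0 | tm$edges >= 5])
  expect_equal(off_mass, 1 / 70, tolerance = 0.07)
})

test_that("interval shuffle conserves count, interval multiset and span", {
  set.seed(23)
  times <- sort(runif(200, 0, 600))
  isi <- diff(c(0, times))
  set.seed(1)
  ts <- cumsum(sample(isi))
  expect_equal(length(ts), length(times))
  expect_equal(sort(diff(c(0, ts))), sort(isi), tolerance = 1e-12)
  expect_equal(max(ts), max(times), tolerance = 1e-9)
  # fixed seed reproduces the null exactly
  n1 <- shuffle_null(times, default_protocol()$onsets, n_shuffles = 50, seed = 7)
  n2 <- shuffle_null(times, default_protocol()$onsets, n_shuffles = 50, seed = 7)
  expect_identical(n1, n2)
  expect_error(shuffle_null(1.0, c(1, 2)), "at least 2")
})

test_that("Poisson units sit inside the shuffle band; injected gains are detected", {
  prot <- default_protocol()
  ep <- epochs_from_protocol(prot)
  inside <- 0L
  for (s in 1:10) {
    set.seed(s)
    times <- cumsum(rexp(2500, 4))
    times <- times[times < 600]
    tm <- sliding_sweeps(times, prot$onsets)
    null <- shuffle_null(times, prot$onsets, n_shuffles = 300, seed = s)
    cl <- classify_unit(tm, null, 4, 4)
    inside <- inside + (cl$label == "none")
  }
  expect_gte(inside, 9L)

  gain_unit <- function(seed, gain) {
    set.seed(seed)
    lam0 <- 4
    lmax <- lam0 * max(1, gain)
    cand <- cumsum(rexp(5000, lmax))
    on <- (cand %% 20) >= 15
    keep <- runif(length(cand)) < ifelse(on, gain, 1) * lam0 / lmax
    cand[keep & cand < 600]
  }
  for (s in 1:5) {
    for (g in c(1.5, 0.5)) {
      times <- gain_unit(100 * s + g * 10, g)
      tm <- sliding_sweeps(times, prot$onsets)
      null <- shuffle_null(times, prot$onsets, n_shuffles = 300, seed = s)
      r <- epoch_rates(times, ep)
      cl <- classify_unit(tm, null, r$off_rate, r$on_rate)
      expect_equal(cl$label, if (g > 1) "excited" else "inhibited")
      expect_equal(cl$effect_pct, 100 * (g - 1), tolerance = 10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("zero off-rate labels from the percentile with a warning", {
  prot <- default_protocol()
  times <- sort(prot$onsets + runif(30, 0, 5))
  tm <- sliding_sweeps(times, prot$onsets)
  null <- shuffle_null(times, prot$onsets, n_shuffles = 200, seed = 2)
  expect_warning(cl <- classify_unit(tm, null, 0, 0.4), "zero")
  expect_equal(cl$label, "excited")
  expect_true(is.na(cl$effect_pct))
})

test_that("population summary recovers configured fractions and net excitation", {
  ses <- generate_session(quick_cfg(31, n_units_per_region = 40))
  cl <- classify_units(ses$spikes, ses$protocol, n_shuffles = 400, seed = 5)
  truth <- attr(ses$spikes, "truth")
  for (rg in c("MS", "HP")) {
    ps <- population_summary(cl[cl$region == rg, ])
    frac_true_exc <- mean(truth$class[truth$region == rg] == "excited")
    frac_true_inh <- mean(truth$class[truth$region == rg] == "inhibited")
    # binomial error around the configured fractions at n = 40
    expect_lt(abs(ps$frac_excited - frac_true_exc), 0.15)
    expect_lt(abs(ps$frac_inhibited - frac_true_inh), 0.10)
    expect_gt(ps$global_rate_change_pct, 0)  # both regions net excited
  }
  expect_error(population_summary(cl[1:5, ]), "at least 10")
})
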