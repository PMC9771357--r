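# IPSC-train depression, pool estimation, quantal metrics, IPSC detection.

test_that("depression fit recovers a planted exponential time course", {
  tau_true <- 200 # ms
  t <- (0:59) * 20 # 50 Hz
  a <- 0.5 + 0.5 * exp(-t / tau_true)
  train <- ipsc_train(50, amplitude = 40 * a)
  fit <- fit_depression_train(train)
  expect_true(fit$tau_identifiable)
  expect_equal(fit$tau_ms, tau_true, tolerance = 0.05)
  expect_equal(fit$plateau, 0.5, tolerance = 0.02)
})

test_that("constant trains flag the time constant unidentifiable", {
  train <- ipsc_train(50, amplitude = rep(40, 30))
  fit <- fit_depression_train(train)
  expect_false(fit$tau_identifiable)
  expect_equal(fit$plateau, 1.0)
  expect_error(fit_depression_train(ipsc_train(50, rep(40, 10))),
               "at least 20")
})

test_that("steady-state slope is zero for identical plateaus and charge rises", {
  ss <- steady_state_analysis(list(0.5, 0.5, 0.5),
                              frequencies = c(10, 50, 100))
  expect_equal(ss$slope, 0)
  expect_true(all(diff(ss$table$charge_transfer) > 0))
  expect_error(steady_state_analysis(list(0.5, 0.5)), "at least 3")
})

test_that("pool estimate is exact for a zero-depression train", {
  cc <- 2.5 # constant charge per stimulus
  train <- ipsc_train(50, amplitude = rep(40, 60), charge = rep(cc, 60))
  est <- estimate_pool(train)
  expect_equal(est$mobilization_pc_per_stim, cc, tolerance = 1e-9)
  expect_equal(est$rrp_pc, 0, tolerance = 1e-9)
  expect_error(estimate_pool(ipsc_train(50, rep(1, 30))), "at least 40")
})

test_that("pool estimate recovers the planted pool on the depleting preset", {
  errs <- vapply(1:10, function(s) {
    spec <- ipsc_gen_spec(preset = "depleting", n_stim = 60, seed = s)
    tr <- gen_ipsc_trains(spec)
    est <- estimate_pool(tr, mean_quantal_charge = spec$q_charge)
    abs(est$rrp_quanta - 100) / 100
  }, 1)
  expect_lte(median(errs), 0.10)
})

test_that("mobilization per second accelerates with stimulus frequency", {
  get_mob <- function(freq) {
    spec <- ipsc_gen_spec(preset = "pc_mli", frequency = freq, seed = 3)
    est <- estimate_pool(gen_ipsc_trains(spec),
                         mean_quantal_charge = spec$q_charge)
    est$mobilization_quanta_per_s
  }
  expect_gt(get_mob(100), get_mob(20))
})

test_that("quantal arithmetic matches the defining ratios", {
  qm <- quantal_metrics(evoked_amp = 39.1, spont_amp = 18,
                        evoked_integral_qc = 6.7, rrp_quanta = 99,
                        holding_mV = -40, reversal_mV = -74,
                        repeated_evoked = c(30, 40, 50))
  expect_equal(qm$quantal_content, 39.1 / 18, tolerance = 1e-12)
  expect_equal(qm$release_probability, 6.7 / 99, tolerance = 1e-12)
  expect_equal(qm$conductance_nS, 39.1 / 34, tolerance = 1e-12)
  expect_equal(qm$cv, sd(c(30, 40, 50)) / 40, tolerance = 1e-12)
  expect_equal(quantal_metrics(0, 18, holding_mV = -40)$conductance_nS, 0)
  expect_error(quantal_metrics(30, 0, holding_mV = -40), "spont_amp")
  expect_error(quantal_metrics(30, 18, holding_mV = -74, reversal_mV = -74),
               "holding")
})

test_that("IPSC detection applies the amplitude threshold and window", {
  t <- seq(0, 40, by = 0.01)
  mk_event <- function(amp, onset, tau_rise = 1, tau_decay = 8) {
    ifelse(t < onset, 0,
           amp * (1 - exp(-(t - onset) / tau_rise)) *
             exp(-(t - onset) / tau_decay) /
             max((1 - exp(-seq(0, 30, 0.01) / tau_rise)) *
                   exp(-seq(0, 30, 0.01) / tau_decay)))
  }
  # 10 pA event: below the 15 pA minimum
  expect_false(detect_ipsc(t, mk_event(10, 10))$detected)
  # 30 pA event peaking outside the 4-24 ms window
  expect_false(detect_ipsc(t, mk_event(30, 28))$detected)
  # 40 pA event at 8 ms: detected, onset and rise time recovered
  det <- detect_ipsc(t, mk_event(40, 8))
  expect_true(det$detected)
  expect_equal(det$latency_ms, 8, tolerance = 0.3)
  # analytic 20-80% interval of the saturating-exponential rise
  rise <- mk_event(40, 0)
  pk <- max(rise)
  t20 <- t[which(rise >= 0.2 * pk)[1]]
  t80 <- t[which(rise >= 0.8 * pk)[1]]
  expect_equal(det$rise_time_ms, t80 - t20, tolerance = 0.2)
})

test_that("exhaustion: full release on the first stimulus empties the pool", {
  spec <- ipsc_gen_spec(release_frac = 1, mobil_base = 0, mobil_act = 0,
                        n_stim = 40, n_sweeps = 1, q_cv = 0, seed = 1)
  tr <- gen_ipsc_trains(spec)
  expect_equal(tr$amplitude_pA[1], 100 * spec$q_amp, tolerance = 1e-9)
  expect_true(all(tr$amplitude_pA[-1] == 0))
})

test_that("pc_mli preset holds a frequency-independent plateau near 0.5", {
  plateaus <- vapply(c(10, 50, 100), function(f) {
    spec <- ipsc_gen_spec(preset = "pc_mli", frequency = f, n_sweeps = 20,
                          seed = 40 + f)
    fit_depression_train(gen_ipsc_trains(spec))$plateau
  }, 1)
  expect_true(all(abs(plateaus - 0.5) <= 0.1))
})

test_that("IPSC trains round-trip through CSV", {
  spec <- ipsc_gen_spec(preset = "pc_mli", seed = 5)
  tr <- gen_ipsc_trains(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipsc_csv(tr, path)
  back <- read_ipsc_csv(path)
  expect_equal(attr(back, "frequency"), attr(tr, "frequency"))
  expect_equal(back$amplitude_pA, tr$amplitude_pA, tolerance = 1e-9)
})
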