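# Eyelid-trace processing: filter properties, CR measures on analytic
# ramps, truncation, velocity.

test_that("low-pass filter has unit DC gain and attenuates 200 Hz", {
  const <- rep(2.5, 1000)
  # compare away from the ends: the zero-phase filter has edge transients
  expect_equal(preprocess_eyelid(const)[100:900], const[100:900],
               tolerance = 1e-6)
  t <- seq_len(2000)
  hf <- sin(2 * pi * 200 * t / 1000)
  base <- 0.5 * sin(2 * pi * 2 * t / 1000)
  filt <- preprocess_eyelid(base + hf)
  # residual high-frequency power attenuated by more than 20 dB
  resid <- filt - base
  mid <- 300:1700
  expect_lt(sd(resid[mid]), sd(hf[mid]) / 10)
  expect_error(preprocess_eyelid(rep(0, 1000), expected_length = 2500),
               "expected 2500")
})

test_that("truncated view contains no samples at or after US onset", {
  x <- seq(0, 2.499, by = 0.001)
  out <- truncate_at_us(x, us_onset = 700)
  expect_length(out, 700)
  expect_identical(out, x[1:700]) # t = 0 .. 699 ms
})

test_that("CR measures recover analytic ramp geometry", {
  # ramp starting 300 ms post-CS at 0.01 mm/ms, US at 500 ms post-CS
  trace <- c(rep(0, 500), 0.01 * seq_len(450))
  cr <- cr_measures(trace, cs_onset = 200, us_onset = 700,
                    already_filtered = TRUE)
  expect_true(cr$is_cr)
  expect_equal(cr$amplitude_mm, 2.0, tolerance = 0.011)
  expect_equal(cr$criterion_ms, 330, tolerance = 1)
  expect_equal(cr$onset_ms, 300, tolerance = 5)
  expect_lte(cr$onset_ms, cr$criterion_ms)
})

test_that("sub-criterion responses and flat traces are not CRs", {
  flat <- rep(0.7, 950)
  cr <- cr_measures(flat, cs_onset = 200, us_onset = 700,
                    already_filtered = TRUE)
  expect_false(cr$is_cr)
  expect_equal(cr$amplitude_mm, 0)
  expect_true(is.na(cr$onset_ms))
  # ramp reaching only 0.2 mm before the US
  small <- c(rep(0, 500), seq(0, 0.2, length.out = 450))
  expect_false(cr_measures(small, cs_onset = 200, us_onset = 700,
                           already_filtered = TRUE)$is_cr)
})

test_that("CR amplitude is invariant to a constant offset", {
  trace <- c(rep(0, 400), 0.008 * seq_len(550))
  a <- cr_measures(trace, 200, 700, already_filtered = TRUE)
  b <- cr_measures(trace + 3.3, 200, 700, already_filtered = TRUE)
  expect_equal(a$amplitude_mm, b$amplitude_mm, tolerance = 1e-9)
  expect_equal(a$criterion_ms, b$criterion_ms)
})

test_that("onset never exceeds criterion latency on noisy synthetic CRs", {
  gen <- gen_session_data(session_gen_spec(n_trials = 30, seed = 21,
                                           n_baseline_epochs = 1,
                                           baseline_s = 1))
  for (i in seq_len(nrow(gen$trials))) {
    cr <- cr_measures(gen$trials$eyelid[[i]], cs_onset = gen$cs_onset,
                      us_onset = gen$us_onset, already_filtered = TRUE)
    if (cr$is_cr && !is.na(cr$onset_ms)) {
      expect_lte(cr$onset_ms, cr$criterion_ms)
    }
  }
})

test_that("velocity is exact for lines and matches calculus for sinusoids", {
  expect_equal(eyelid_velocity(rep(1.2, 100)), rep(0, 100))
  ramp <- 0.01 * seq_len(500) # 0.01 mm/ms = 10 mm/s
  expect_equal(eyelid_velocity(ramp), rep(10, 500), tolerance = 1e-9)
  t <- seq_len(3000)
  f <- 3 # Hz
  x <- sin(2 * pi * f * t / 1000)
  v <- eyelid_velocity(x)
  expected <- 2 * pi * f * cos(2 * pi * f * t / 1000)
  expect_equal(v[10:2990], expected[10:2990], tolerance = 0.01)
})
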