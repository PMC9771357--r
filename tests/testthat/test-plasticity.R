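# Timing-gated parallel-fiber rule, nuclear rule, and weight summaries.

test_that("burst detection finds threshold bursts greedily", {
  expect_length(detect_bursts(c(0, 50, 100)), 0) # no pair within 10 ms
  expect_equal(detect_bursts(c(0, 4, 50, 52, 200)), c(0, 50))
  expect_equal(detect_bursts(c(0, 3, 6, 9), threshold = 3, window = 10), 0)
  expect_length(detect_bursts(numeric(0)), 0)
  expect_error(detect_bursts(c(5, 1)), "sorted")
})

test_that("climbing-fiber timing window gates LTD vs LTP", {
  cfg <- plasticity_config()
  # burst 200 ms before the climbing-fiber spike: inside the window -> LTD
  w <- apply_pf_pc_plasticity(0.5, list(1000), 1200, cfg)
  expect_equal(w, 0.5 - cfg$ltd_step)
  # no climbing fiber at all -> LTP
  w <- apply_pf_pc_plasticity(0.5, list(1000), numeric(0), cfg)
  expect_equal(w, 0.5 + cfg$ltp_step)
  # lag 50 ms: outside the window -> LTP
  w <- apply_pf_pc_plasticity(0.5, list(1000), 1050, cfg)
  expect_equal(w, 0.5 + cfg$ltp_step)
  # window edges are inclusive
  expect_equal(apply_pf_pc_plasticity(0.5, list(1000), 1100, cfg),
               0.5 - cfg$ltd_step)
  expect_equal(apply_pf_pc_plasticity(0.5, list(1000), 1300, cfg),
               0.5 - cfg$ltd_step)
  expect_error(apply_pf_pc_plasticity(0.5, list(1000), c(30, 10), cfg),
               "sorted")
})

test_that("rule agrees with a brute-force scan of all burst-CF lags", {
  cfg <- plasticity_config()
  set.seed(31)
  for (rep in 1:20) {
    n_syn <- 30
    bursts <- lapply(seq_len(n_syn), function(i)
      sort(runif(sample(0:4, 1), 0, 3000)))
    cf <- sort(runif(3, 0, 3000))
    w0 <- runif(n_syn, 0.2, 0.8)
    got <- apply_pf_pc_plasticity(w0, bursts, cf, cfg)
    want <- w0
    for (i in seq_len(n_syn)) {
      for (b in bursts[[i]]) {
        lags <- cf - b
        if (any(lags >= 100 & lags <= 300)) {
          want[i] <- want[i] - cfg$ltd_step
        } else {
          want[i] <- want[i] + cfg$ltp_step
        }
      }
    }
    want <- pmin(pmax(want, 0), cfg$w_max)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("weights never leave [0, w_max]", {
  cfg <- plasticity_config(ltd_step = 0.4, ltp_step = 0.3)
  w <- apply_pf_pc_plasticity(c(0.1, 0.9), list(c(0, 400, 800), c(0, 400, 800)),
                              numeric(0), cfg)
  expect_true(all(w >= 0 & w <= cfg$w_max))
  w2 <- apply_pf_pc_plasticity(0.1, list(c(0, 500, 1000)),
                               c(200, 700, 1200), cfg)
  expect_gte(w2, 0)
})

test_that("nuclear rule depresses during pauses, potentiates during bursts", {
  cfg <- plasticity_config()
  base_rate <- rep(60, 1000)
  mf_act <- list(c(250, 800), c(50))
  # constant rate: no pauses or strong episodes -> unchanged
  expect_equal(apply_mf_dcn_plasticity(c(0.5, 0.5), mf_act, base_rate, cfg),
               c(0.5, 0.5))
  # 150-ms near-silence at 200-350 ms: only the fiber active inside changes
  pause <- base_rate; pause[200:350] <- 5
  w <- apply_mf_dcn_plasticity(c(0.5, 0.5), mf_act, pause, cfg)
  expect_equal(w, c(0.5 - cfg$dcn_ltd_step, 0.5))
  # strong epoch at 700-900 ms
  strong <- base_rate; strong[700:900] <- 120
  w <- apply_mf_dcn_plasticity(c(0.5, 0.5), mf_act, strong, cfg)
  expect_equal(w, c(0.5 + cfg$dcn_ltp_step, 0.5))
  expect_error(apply_mf_dcn_plasticity(0.5, mf_act[1], rep(60, 10), cfg),
               "window longer")
})

test_that("weight-change summaries bin and cumulate correctly", {
  s <- weight_change_summary(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.6),
                             bin_width = 0.1)
  expect_equal(s$histogram$count[s$histogram$bin_left == -0.2], 2L)
  expect_equal(s$histogram$count[s$histogram$bin_left == 0.1], 1L)
  expect_equal(sum(s$histogram$count), 3L)
  # identical weights: all mass in the zero bin
  z <- weight_change_summary(rep(0.4, 10), rep(0.4, 10))
  expect_identical(z$histogram$bin_left, 0)
  expect_identical(z$histogram$count, 10L)
  # cumulative is monotone and ends at 1
  set.seed(4)
  s2 <- weight_change_summary(runif(500), runif(500))
  expect_true(all(diff(s2$cumulative$cum_fraction) >= 0))
  expect_equal(max(s2$cumulative$cum_fraction), 1)
  expect_error(weight_change_summary(1:3, 1:4), "equal length")
})

test_that("summary differences align bins over their union", {
  a <- weight_change_summary(c(0.5, 0.5), c(0.2, 0.8), bin_width = 0.1)
  b <- weight_change_summary(c(0.5, 0.5), c(0.5, 0.8), bin_width = 0.1)
  d <- weight_summary_difference(a, b)
  expect_equal(d$count_diff[d$bin_left == -0.3], 1L)
  expect_equal(d$count_diff[d$bin_left == 0], -1L)
  expect_equal(sum(d$count_diff), 0L)
})

test_that("timing selectivity emerges on a toy network of granule synapses", {
  # synapses whose bursts precede the CF by 100-300 ms depress on average;
  # synapses bursting elsewhere potentiate
  cfg <- plasticity_config()
  set.seed(77)
  n <- 100
  in_window <- rep(c(TRUE, FALSE), length.out = n)
  w0 <- rep(0.5, n)
  w <- w0
  for (trial in 1:20) {
    cf <- 700
    bursts <- lapply(seq_len(n), function(i) {
      if (in_window[i]) sort(runif(2, 420, 580)) else sort(runif(2, 0, 380))
    })
    w <- apply_pf_pc_plasticity(w, bursts, cf, cfg)
  }
  expect_lt(mean(w[in_window]), 0.5)
  expect_gt(mean(w[!in_window]), 0.5)
})
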