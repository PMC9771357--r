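# Triggered cross-correlograms with shuffle nulls: percentile event
# selection, significance rules, null calibration and coupling detection.

test_that("percentile selection matches an exhaustive sort", {
  # 20 inter-spike intervals of lengths 1..20 ms, 35%: the 7 of length >= 14
  times <- cumsum(c(0, 1:20))
  pauses <- select_isi_events(times, "pause", 0.35)
  isi <- diff(times)
  expect_length(pauses, 7)
  expect_setequal(pauses, times[which(isi >= 14)])
  bursts <- select_isi_events(times, "burst", 0.35)
  expect_setequal(bursts, times[which(isi <= 7)])
  # ties at the threshold interval are all included
  t2 <- cumsum(c(0, c(1, 1, 1, 5, 5, 5)))
  expect_length(select_isi_events(t2, "pause", 1 / 3), 3)
  # constant-ISI trains cannot discriminate
  expect_error(select_isi_events(seq(0, 100, 10), "pause", 0.35),
               "insufficient data")
})

test_that("independent Poisson trains are flat and rarely significant", {
  set.seed(101)
  n_sig <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    gen <- gen_coupled_trains(duration_s = 10, n_epochs = 3, coupling = 0,
                              seed = 1000 + s)
    cg <- spike_triggered_correlogram(gen$pc, gen$mli, n_shuffles = 100)
    n_sig <- n_sig + cg$significant
    if (s == 1) {
      expect_equal(mean(cg$bins$norm_count, na.rm = TRUE), 1,
                   tolerance = 0.05)
    }
  }
  expect_lte(n_sig / n_seeds, 0.08)
})

test_that("inhibitory coupling produces a significant post-trigger trough", {
  gen <- gen_coupled_trains(duration_s = 10, n_epochs = 8, coupling = 0.6,
                            lag = 1, dur = 4, pc_rate = 60, mli_rate = 25,
                            seed = 5)
  cg <- spike_triggered_correlogram(gen$pc, gen$mli, n_shuffles = 200)
  expect_true(cg$significant)
  post <- cg$bins[cg$bins$lag >= 1 & cg$bins$lag <= 5, ]
  expect_lte(min(post$z), -3.34)
  expect_lt(min(post$norm_count), 1)
  # shuffled-trigger control: shuffling PC spike timing abolishes the effect
  set.seed(9)
  shuf_pc <- lapply(gen$pc, function(ts) sort(runif(length(ts), 0, 1e4)))
  cg0 <- spike_triggered_correlogram(shuf_pc, gen$mli, n_shuffles = 100)
  expect_false(cg0$significant)
})

test_that("correlogram mirrors when trigger and target swap", {
  gen <- gen_coupled_trains(duration_s = 10, n_epochs = 6, coupling = 0.5,
                            seed = 12)
  ab <- spike_triggered_correlogram(gen$pc, gen$mli, n_shuffles = 100)
  ba <- spike_triggered_correlogram(gen$mli, gen$pc, n_shuffles = 100)
  # raw counts mirror exactly about lag 0
  expect_equal(ab$bins$count, rev(ba$bins$count))
})

test_that("pause-triggered correlogram shows post-0 increase under coupling", {
  gen <- gen_coupled_trains(duration_s = 10, n_epochs = 8, coupling = 0.6,
                            lag = 1, dur = 6, pc_rate = 60, mli_rate = 25,
                            seed = 31)
  cg <- event_triggered_correlogram(gen$pc, gen$mli, "pause",
                                    percentile = 0.35, n_shuffles = 100)
  # lags past the trigger spike's own brief suppression window
  post <- mean(cg$bins$norm_count[cg$bins$lag >= 8 & cg$bins$lag <= 28])
  pre <- mean(cg$bins$norm_count[cg$bins$lag <= -1 & cg$bins$lag >= -21])
  expect_gt(post, pre)
  # burst-triggered goes the other way: more PC spikes, more suppression
  cb <- event_triggered_correlogram(gen$pc, gen$mli, "burst",
                                    percentile = 0.35, n_shuffles = 100)
  post_b <- mean(cb$bins$norm_count[cb$bins$lag >= 8 & cb$bins$lag <= 28])
  expect_lt(post_b, post)
})

test_that("insufficient data is reported", {
  expect_error(spike_triggered_correlogram(c(1), c(2, 3), n_shuffles = 10),
               "insufficient")
  expect_error(event_triggered_correlogram(c(1, 2, 3), c(2, 3),
                                           "pause", n_shuffles = 10),
               "insufficient")
})
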