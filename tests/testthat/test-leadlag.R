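# Lead-lag (pre-CR fraction) statistic and trial grouping.

test_that("extreme lead-lag configurations give the defined values", {
  cs <- 200; isi <- 500
  T <- 950
  tt <- seq_len(T) - 1
  # PC completes its full decrease before CR onset at 300 ms post-CS
  pc <- ifelse(tt < cs + 150, 60, 20)
  # MLI starts rising only after onset
  mli <- ifelse(tt < cs + 320, 10, 40)
  out <- pre_cr_fraction(pc, mli, cr_onset = 300, isi = isi, cs_onset = cs)
  expect_false(out$excluded)
  expect_equal(out$delta_pc, 1)
  expect_equal(out$delta_mli, 0, tolerance = 0.05)
  expect_equal(out$difference, 1, tolerance = 0.05)
  # both change linearly starting exactly at onset: both fractions 0
  ramp_dn <- ifelse(tt < cs + 300, 60, 60 - 0.2 * (tt - cs - 300))
  ramp_up <- ifelse(tt < cs + 300, 10, 10 + 0.2 * (tt - cs - 300))
  out2 <- pre_cr_fraction(ramp_dn, ramp_up, 300, isi, cs)
  expect_equal(out2$difference, 0, tolerance = 1e-6)
})

test_that("window length follows the ISI and late onsets are excluded", {
  pc <- rep(60, 950); mli <- rep(10, 950)
  expect_equal(pre_cr_fraction(pc, mli, 100, isi = 250)$window_ms, 100)
  expect_equal(pre_cr_fraction(pc, mli, 100, isi = 500)$window_ms, 150)
  out <- pre_cr_fraction(pc, mli, cr_onset = 420, isi = 500)
  expect_true(out$excluded)
  expect_match(out$reason, "US")
})

test_that("generator with a known PC lead yields positive differences", {
  spec <- session_gen_spec(n_trials = 100, lead_ms = 60, seed = 14,
                           n_baseline_epochs = 1, baseline_s = 1)
  gen <- gen_session_data(spec)
  diffs <- purrr::map_dbl(seq_len(nrow(gen$trials)), function(i) {
    tr <- gen$trials[i, ]
    if (!tr$is_cr) return(NA_real_)
    out <- pre_cr_fraction(tr$pc_rate_true[[1]], tr$mli_rate_true[[1]],
                           tr$onset_ms, isi = spec$isi)
    if (out$excluded) NA_real_ else out$difference
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("trials split into equal groups with remainder to the last", {
  mk <- function(n_cr, n_non) {
    tibble::tibble(is_cr = c(rep(TRUE, n_cr), rep(FALSE, n_non)),
                   onset_ms = c(runif(n_cr, 100, 400), rep(NA, n_non)),
                   amplitude_mm = c(runif(n_cr, 0.5, 5), rep(0, n_non)))
  }
  set.seed(8)
  g <- group_trials(mk(90, 5), key = "cr_onset", n_groups = 3)
  expect_equal(g$n[g$group != "non_cr"], c(30, 30, 30))
  g2 <- group_trials(mk(91, 0), key = "cr_onset", n_groups = 3)
  expect_equal(g2$n, c(30, 30, 31))
  expect_error(group_trials(mk(2, 0), n_groups = 3), "fewer CR trials")
})

test_that("group means recover planted onset clusters", {
  set.seed(19)
  onsets <- c(rnorm(30, 150, 5), rnorm(30, 250, 5), rnorm(30, 350, 5))
  d <- tibble::tibble(is_cr = TRUE, onset_ms = onsets,
                      amplitude_mm = 1,
                      eyelid = lapply(onsets, function(o)
                        c(rep(0, round(o)), rep(1, 500 - round(o)))))
  g <- group_trials(d, key = "cr_onset", n_groups = 3)
  expect_equal(g$n, rep(30, 3))
  mids <- (g$key_min + g$key_max) / 2
  expect_equal(sort(mids), c(150, 250, 350), tolerance = 0.05)
  # group-mean traces order by onset: earlier group has earlier rise
  m1 <- g$eyelid_mean[[1]]; m3 <- g$eyelid_mean[[3]]
  expect_gt(mean(m1[200:300]), mean(m3[200:300]))
  # 95% CI brackets the mean
  expect_true(all(g$eyelid_lo[[1]] <= g$eyelid_mean[[1]] + 1e-12))
  expect_true(all(g$eyelid_hi[[1]] >= g$eyelid_mean[[1]] - 1e-12))
})
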