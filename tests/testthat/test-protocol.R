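# CS/US encoding, session structure, and the DCN-to-eyelid conversion.

test_that("mossy-fiber role counts follow the stated fractions and rounding", {
  cfg <- sim_config(seed = 2)
  a <- assign_mf_roles(cfg, seed = 5)
  tab <- table(a$role)
  expect_equal(unname(tab[["phasic_cs"]]), 18)   # 0.03 x 600
  expect_equal(unname(tab[["tonic_cs"]]), 18)
  expect_equal(unname(tab[["dcn_collateral"]]), 31) # 0.052 x 600 = 31.2
  expect_identical(a, assign_mf_roles(cfg, seed = 5))
  expect_true(all(a$background_rate >= 1 & a$background_rate <= 40))
  tonic <- a$tonic_rate[a$role == "tonic_cs"]
  expect_true(all(tonic >= 80 & tonic <= 100))
})

test_that("drive probabilities are rate x dt with role-specific windows", {
  cfg <- sim_config(seed = 1, scale_factor = 1 / 6)
  a <- assign_mf_roles(cfg, seed = 1)
  tr <- trial_spec("paired", 500)
  # 100 Hz -> per-ms probability 0.1
  a2 <- a
  a2$background_rate[1] <- 100
  p <- mf_drive(a2, tr, t = 10)
  expect_equal(p[1], 0.1)
  # before CS onset, phasic/tonic fibers sit at background
  pre <- mf_drive(a, tr, t = 100)
  ph <- which(a$role == "phasic_cs")
  expect_equal(pre[ph], a$background_rate[ph] * 1e-3)
  # inside the CS: phasic burst for exactly 100 ms, tonic throughout
  at250 <- mf_drive(a, tr, t = 250)
  expect_true(all(at250[ph] == protocol_config()$phasic_rate * 1e-3))
  at350 <- mf_drive(a, tr, t = 350)
  expect_equal(at350[ph], a$background_rate[ph] * 1e-3)
  to <- which(a$role == "tonic_cs")
  expect_equal(at350[to], a$tonic_rate[to] * 1e-3)
})

test_that("stochastic drive matches the binomial count", {
  # simulated 10-s span at 40 Hz: empirical count within 3 SD of
  # Binomial(10000, 0.04)
  cfg <- tiny_config(seed = 1)
  net <- build_network(cfg)
  a <- assign_mf_roles(cfg, seed = 3)
  a$background_rate[] <- 40
  a$role[] <- "background"
  T <- 10000
  set.seed(99)
  res <- pcmli:::.run_segment(pcmli:::.pack_network(net), list(),
                              matrix(40, net$pops[["mf"]], T), integer(0),
                              integer(0), integer(0), protocol_config(), 0,
                              "mf")
  counts <- tabulate(res$spikes$mf$id, net$pops[["mf"]])
  expected <- T * 0.04
  sd3 <- 3 * sqrt(T * 0.04 * 0.96)
  expect_true(all(abs(counts - expected) < sd3))
})

test_that("sessions have 12 blocks of 9 trials starting with CS-alone", {
  cfg <- tiny_config(seed = 2)
  net <- build_network(cfg)
  a <- assign_mf_roles(cfg, seed = 2)
  set.seed(3)
  res <- run_session(net, a, isi = 300, plasticity_on = FALSE)
  expect_equal(nrow(res$cr_table), 108)
  cs_alone <- which(res$cr_table$type == "cs_alone")
  expect_equal(cs_alone, seq(1, 108, by = 9))
  # inter-trial intervals drawn uniformly on 20-40 s, mean ~30 s
  expect_true(all(res$cr_table$iti_s >= 20 & res$cr_table$iti_s <= 40))
  expect_equal(mean(res$cr_table$iti_s), 30, tolerance = 0.12)
})

test_that("paired-trial CS co-terminates with the US", {
  for (isi in c(150, 250, 500, 750)) {
    tr <- trial_spec("paired", isi)
    expect_equal(tr$cs_duration, isi + tr$us_duration)
    expect_equal(tr$us_onset + tr$us_duration,
                 tr$cs_onset + tr$cs_duration)
  }
})

test_that("CS-alone trials deliver no US climbing-fiber volley", {
  cfg <- tiny_config(seed = 4)
  net <- build_network(cfg)
  a <- assign_mf_roles(cfg, seed = 4)
  p0 <- protocol_config(cf_spont_hz = 0)
  set.seed(5)
  res <- run_trial(net, a, trial_spec("cs_alone", 300, p0),
                   plasticity_on = FALSE, protocol = p0)
  expect_equal(nrow(res$record$spikes$cf), 0)
  set.seed(5)
  resp <- run_trial(net, a, trial_spec("paired", 300, p0),
                    plasticity_on = FALSE, protocol = p0)
  expect_gt(nrow(resp$record$spikes$cf), 0)
})

test_that("spike logs are reproducible under identical seeds", {
  cfg <- tiny_config(seed = 6)
  net <- build_network(cfg)
  a <- assign_mf_roles(cfg, seed = 6)
  tr <- trial_spec("paired", 250)
  set.seed(77)
  r1 <- run_trial(net, a, tr, plasticity_on = FALSE)
  set.seed(77)
  r2 <- run_trial(net, a, tr, plasticity_on = FALSE)
  expect_identical(r1$record$spikes, r2$record$spikes)
})

test_that("DCN-to-eyelid conversion is a unit-gain causal smoother", {
  p <- protocol_config()
  # silent nucleus: flat zero trace
  silent <- dcn_output_to_eyelid(tibble::tibble(unit = integer(0),
                                                t = numeric(0)),
                                 n_dcn = 4, n_steps = 300, protocol = p)
  expect_equal(as.numeric(silent), rep(0, 300))
  expect_error(dcn_output_to_eyelid(NULL, 0, 100), "deep-nucleus")
  # constant-rate input: constant output once converged (shift invariance)
  regular <- tibble::tibble(unit = 1, t = seq(0, 4999, by = 10))
  out <- dcn_output_to_eyelid(regular, n_dcn = 1, n_steps = 5000,
                              protocol = p, baseline_window = 1)
  rate <- attr(out, "dcn_rate")
  expect_equal(mean(rate[3000:5000]), 100, tolerance = 0.03)
  # step input: response equals direct convolution with the two-stage kernel
  step_spikes <- tibble::tibble(unit = 1, t = 1000 + seq(0, 999, 2))
  got <- attr(dcn_output_to_eyelid(step_spikes, 1, 2000, protocol = p), "dcn_rate")
  inst <- 1000 * tabulate(floor(step_spikes$t) + 1, 2000)
  d <- exp(-1 / p$dcn_tau)
  kern <- (1 - d) * d^(0:1999)
  brute <- stats::convolve(inst, rev(kern), type = "open")[1:2000]
  expect_equal(got, brute, tolerance = 1e-8)
})
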