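# Point-neuron update: closed-form single-step checks, threshold dynamics,
# pacemaker rate against an independent integrator, and R/C++ equivalence.

test_that("leak dynamics: fixed point and one hand-computed Euler step", {
  net <- build_network(tiny_config(seed = 1))
  st <- init_state(net)
  drive <- list(mf = integer(net$pops[["mf"]]), cf = integer(net$pops[["cf"]]))
  # granule cells start at E_leak with zero conductance: exact fixed point
  st2 <- advance_timestep(net, st, drive)
  expect_equal(st2$grc$V, rep(net$params$grc$e_leak, net$pops[["grc"]]))
  expect_false(any(st2$grc$spiked))
  # one Euler step from -60 with g_leak/C = 0.1/ms toward E_leak = -70
  st$grc$V[] <- -60
  st3 <- advance_timestep(net, st, drive)
  expect_equal(st3$grc$V, rep(-61, net$pops[["grc"]]),
               tolerance = 1e-12)
})

test_that("threshold adapts by d_theta per spike and decays exponentially", {
  par <- list(theta0 = -50, d_theta = 10, tau_theta = 5)
  st <- list(theta = rep(-50, 3))
  st <- update_threshold(st, par, spiked = c(TRUE, FALSE, FALSE))
  expect_equal(st$theta, c(-40, -50, -50))
  for (i in 1:5) st <- update_threshold(st, par, spiked = rep(FALSE, 3))
  expect_equal(st$theta[1] + 50, 10 * exp(-1), tolerance = 1e-12)
  # two spikes in consecutive steps accumulate beyond a single spike
  st1 <- update_threshold(list(theta = -50), par, TRUE)
  st2 <- update_threshold(st1, par, TRUE)
  expect_gt(st2$theta + 50, st1$theta + 50)
})

test_that("conductances decay exponentially and sum linearly over spikes", {
  par <- list(slots = list(a = list(tau = 1, e = 0, gain = 0.5)))
  st <- list(g = matrix(1, 1, 1))
  st <- update_conductances(st, par, delivered = matrix(0, 1, 1))
  expect_equal(st$g[1, 1], exp(-1), tolerance = 1e-12)
  st0 <- list(g = matrix(0, 1, 1))
  expect_equal(update_conductances(st0, par, matrix(0, 1, 1))$g[1, 1], 0)
  one <- update_conductances(st0, par, matrix(1, 1, 1))$g[1, 1]
  five <- update_conductances(st0, par, matrix(5, 1, 1))$g[1, 1]
  expect_equal(five, 5 * one, tolerance = 1e-12)
  expect_error(update_conductances(st0, par, matrix(-1, 1, 1)), "negative")
})

test_that("pacemaker rate matches the continuous-time integrator within 5%", {
  # slow-leak pacemaker (no adaptation): spike times have a closed form
  par <- default_neuron_params()
  par$pc$g_leak <- 0.05
  par$pc$e_leak <- -55
  par$pc$theta0 <- -60
  par$pc$d_theta <- 0
  par$pc$e_reset <- -70
  cfg <- tiny_config(seed = 1, params = par)
  net <- build_network(cfg)
  # silence every afferent so the PC runs on its intrinsic dynamics
  for (nm in names(net$projections)) {
    if (net$projections[[nm]]$tgt_pop == "pc")
      net$projections[[nm]]$weight[] <- 0
  }
  T <- 5000
  res <- run_core_fixed(net, matrix(0L, net$pops[["mf"]], T))
  rate <- length(res$spikes$pc$id) / net$pops[["pc"]] / (T / 1000)
  # independent oracle: integrate dV/dt = gL (EL - V) at dt = 0.001 ms
  dt <- 1e-3
  V <- -70; t_cross <- NA
  for (k in seq_len(2e6)) {
    V <- V + dt * 0.05 * (-55 - V)
    if (V >= -60) { t_cross <- k * dt; break }
  }
  expect_equal(rate, 1000 / t_cross, tolerance = 0.05)
})

test_that("compiled core and R reference produce identical trajectories", {
  cfg <- tiny_config(seed = 4)
  net <- build_network(cfg)
  T <- 500
  set.seed(11)
  mf_spikes <- matrix(rbinom(net$pops[["mf"]] * T, 1, 0.03),
                      net$pops[["mf"]], T)
  cpp <- run_core_fixed(net, mf_spikes)
  st <- init_state(net)
  Vs <- matrix(0, T, net$pops[["pc"]])
  spikes_r <- list()
  for (t in seq_len(T)) {
    st <- advance_timestep(net, st, list(mf = mf_spikes[, t],
                                         cf = integer(net$pops[["cf"]])))
    Vs[t, ] <- st$pc$V
    for (p in c("grc", "goc", "pc", "bc", "sc", "dcn")) {
      w <- which(st[[p]]$spiked)
      if (length(w)) spikes_r[[length(spikes_r) + 1]] <-
          data.frame(pop = p, id = w, t = t - 1)
    }
  }
  spikes_r <- do.call(rbind, spikes_r)
  for (p in c("grc", "pc", "dcn", "bc")) {
    got <- data.frame(id = cpp$spikes[[p]]$id, t = cpp$spikes[[p]]$t)
    want <- spikes_r[spikes_r$pop == p, c("id", "t")]
    want <- want[order(want$t, want$id), ]
    got <- got[order(got$t, got$id), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)), info = p)
  }
  expect_equal(max(abs(cpp$state[[3]]$V - st$pc$V) / abs(st$pc$V)), 0,
               tolerance = 1e-9)
  expect_equal(cpp$state[[3]]$theta, st$pc$theta, tolerance = 1e-9)
})

test_that("membrane potential stays within the reversal-potential range", {
  cfg <- tiny_config(seed = 6)
  net <- build_network(cfg)
  T <- 2000
  set.seed(2)
  mf_spikes <- matrix(rbinom(net$pops[["mf"]] * T, 1, 0.1),
                      net$pops[["mf"]], T)
  res <- run_core_fixed(net, mf_spikes)
  for (k in seq_along(res$state)) {
    expect_true(all(res$state[[k]]$V >= -80 - 1e-9))
    expect_true(all(res$state[[k]]$V <= 0 + 1e-9))
  }
})

test_that("drive length mismatches are rejected", {
  net <- build_network(tiny_config(seed = 1))
  st <- init_state(net)
  expect_error(advance_timestep(net, st, list(mf = 1L, cf = 0L)),
               "drive lengths")
})
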