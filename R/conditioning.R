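# CS/US encoding as mossy-fiber and climbing-fiber drive, trial/session
# execution, and conversion of deep-nucleus output into the virtual eyelid.

#' Protocol-level constants for conditioning simulations
#'
#' @param phasic_rate Firing rate (Hz) of phasic CS mossy fibers during their
#'   100-ms burst at CS onset.
#' @param phasic_frac,tonic_frac,coll_frac Fractions of all mossy fibers
#'   assigned the phasic-CS, tonic-CS and nucleo-cortical collateral roles.
#' @param background_range,tonic_range Uniform ranges (Hz) for per-fiber
#'   background and tonic-CS rates.
#' @param us_duration US duration (ms); the CS co-terminates with it.
#' @param pre_ms,post_ms Recorded window before CS onset and after CS offset.
#' @param iti_range_s Inter-trial interval range (s), drawn uniformly.
#' @param cf_spont_hz Spontaneous climbing-fiber rate (Hz).
#' @param dcn_tau Time constant (ms) of the causal exponential kernel that
#'   smooths deep-nucleus output into the virtual eyelid drive.
#' @param plant_tau Time constant (ms) of the eyelid plant: the smoothed DCN
#'   drive passes through a second causal exponential stage representing the
#'   lid mechanics, which cannot follow millisecond rate fluctuations.
#' @param eyelid_gain Virtual-eyelid scaling (mm per Hz of smoothed DCN rate
#'   above baseline), calibrated once on a trained ISI-500 run so asymptotic
#'   virtual CRs approach full closure.
#' @param eyelid_max Full eyelid closure (mm).
#' @param cf_suppress_scale,cf_min_p Nucleo-olivary feedback: the probability
#'   that climbing fibers respond to the US falls linearly with the expressed
#'   CR amplitude, reaching `cf_min_p` at `cf_suppress_scale` mm. This is what
#'   lets learning self-limit instead of driving every eligible synapse to the
#'   weight floor.
#' @param coll_base,coll_gain,coll_cap Collateral mossy-fiber rate model:
#'   `base + gain x smoothed DCN rate`, capped at `coll_cap` Hz.
#' @return A `pcmli_protocol` list.
#' @export
protocol_config <- function(phasic_rate = 200, phasic_frac = 0.03,
                            tonic_frac = 0.03, coll_frac = 0.052,
                            background_range = c(1, 40),
                            tonic_range = c(80, 100), us_duration = 50,
                            pre_ms = 200, post_ms = 200,
                            iti_range_s = c(20, 40), cf_spont_hz = 1,
                            dcn_tau = 20, plant_tau = 60,
                            eyelid_gain = 0.08, eyelid_max = 6,
                            cf_suppress_scale = 3, cf_min_p = 0.1,
                            coll_base = 5, coll_gain = 0.5, coll_cap = 40) {
  if (phasic_frac + tonic_frac + coll_frac >= 1) {
    stop("configuration error: mossy-fiber role fractions must sum below 1",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pcmli_protocol")
}

#' Assign mossy-fiber roles and rates
#'
#' A randomly selected `phasic_frac` of mossy fibers burst for 100 ms at CS
#' onset, `tonic_frac` fire at 80-100 Hz for the CS duration, and `coll_frac`
#' carry nucleo-cortical collateral input driven by smoothed DCN output.
#' Every fiber (including CS fibers outside the CS) has a background rate
#' drawn uniformly from 1-40 Hz. Role counts are the nearest integer to
#' `fraction x n_mf`; roles are disjoint.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the assignment is deterministic given it.
#' @param protocol A [protocol_config()].
#' @return A `pcmli_mf_assignment`: tibble with columns `mf`, `role`
#'   (`background`, `phasic_cs`, `tonic_cs`, `dcn_collateral`),
#'   `background_rate`, `tonic_rate` (NA except tonic fibers).
#' @export
assign_mf_roles <- function(config, seed = config$seed,
                            protocol = protocol_config()) {
  n <- config$n_mf
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n_ph <- round(protocol$phasic_frac * n)
  n_to <- round(protocol$tonic_frac * n)
  n_co <- round(protocol$coll_frac * n)
  pick <- sample(n, n_ph + n_to + n_co)
  role <- rep("background", n)
  role[pick[seq_len(n_ph)]] <- "phasic_cs"
  role[pick[n_ph + seq_len(n_to)]] <- "tonic_cs"
  role[pick[n_ph + n_to + seq_len(n_co)]] <- "dcn_collateral"
  out <- tibble::tibble(
    mf = seq_len(n), role = role,
    background_rate = runif(n, protocol$background_range[1],
                            protocol$background_range[2]),
    tonic_rate = ifelse(role == "tonic_cs",
                        runif(n, protocol$tonic_range[1],
                              protocol$tonic_range[2]), NA_real_))
  class(out) <- c("pcmli_mf_assignment", class(out))
  out
}

#' Specify one conditioning trial
#'
#' Paired trials co-terminate the CS with the `us_duration`-ms US, so the CS
#' lasts `isi + us_duration` ms; CS-alone trials present the same CS with no
#' US.
#'
#' @param type `"paired"` or `"cs_alone"`.
#' @param isi CS-onset to US-onset interval (ms).
#' @param protocol A [protocol_config()].
#' @return A `pcmli_trial` list with `type`, `isi`, `cs_duration`,
#'   `us_duration`, `pre_ms`, `post_ms`, `n_steps`, `cs_onset`, `us_onset`
#'   (0-based ms within the trial; `us_onset` is NA on CS-alone trials).
#' @export
trial_spec <- function(type = c("paired", "cs_alone"), isi = 500,
                       protocol = protocol_config()) {
  type <- match.arg(type)
  stopifnot(isi > 0)
  cs_dur <- isi + protocol$us_duration
  n_steps <- protocol$pre_ms + cs_dur + protocol$post_ms
  structure(list(type = type, isi = isi, cs_duration = cs_dur,
                 us_duration = protocol$us_duration,
                 pre_ms = protocol$pre_ms, post_ms = protocol$post_ms,
                 n_steps = n_steps, cs_onset = protocol$pre_ms,
                 us_onset = if (type == "paired") protocol$pre_ms + isi else NA_real_),
            class = "pcmli_trial")
}

#' Per-mossy-fiber spike probability at one millisecond
#'
#' Converts each fiber's target rate at trial time `t` into a per-ms Bernoulli
#' probability (`rate x dt`, capped at 1). Phasic CS fibers are elevated for
#' exactly 100 ms from CS onset; tonic CS fibers hold their CS rate for the CS
#' duration; collateral fibers follow the smoothed DCN rate; everything else
#' (and CS fibers outside the CS) fires at its background rate.
#'
#' @param assignment From [assign_mf_roles()].
#' @param trial A [trial_spec()].
#' @param t Trial time (ms, 0-based scalar).
#' @param dcn_feedback_rate Smoothed DCN population rate (Hz) at `t`.
#' @param protocol A [protocol_config()].
#' @return Numeric vector of probabilities, one per mossy fiber.
#' @export
mf_drive <- function(assignment, trial, t, dcn_feedback_rate = 0,
                     protocol = protocol_config()) {
  stopifnot(t >= 0, t < trial$n_steps)
  rate <- assignment$background_rate
  in_cs <- t >= trial$cs_onset & t < trial$cs_onset + trial$cs_duration
  if (in_cs) {
    ph <- assignment$role == "phasic_cs" & t < trial$cs_onset + 100
    rate[ph] <- protocol$phasic_rate
    to <- assignment$role == "tonic_cs"
    rate[to] <- assignment$tonic_rate[to]
  }
  co <- assignment$role == "dcn_collateral"
  rate[co] <- pmin(protocol$coll_cap,
                   protocol$coll_base + protocol$coll_gain * dcn_feedback_rate)
  pmin(1, rate * 1e-3)
}

# rate matrix (Hz) for all non-collateral roles over the whole trial;
# collateral rows are computed online in the compiled core
.mf_rate_matrix <- function(assignment, trial, protocol) {
  n <- nrow(assignment); T <- trial$n_steps
  m <- matrix(assignment$background_rate, n, T)
  cs0 <- trial$cs_onset
  cs_cols <- (cs0 + 1):(cs0 + trial$cs_duration)
  ph <- which(assignment$role == "phasic_cs")
  m[ph, (cs0 + 1):(cs0 + min(100, trial$cs_duration))] <- protocol$phasic_rate
  to <- which(assignment$role == "tonic_cs")
  m[to, cs_cols] <- assignment$tonic_rate[to]
  m
}

# pack network + current weights for the compiled runner
.pack_network <- function(network) {
  pop_order <- c("grc", "goc", "pc", "bc", "sc", "dcn", "mf", "cf")
  pid <- stats::setNames(seq_along(pop_order) - 1L, pop_order)
  pops <- lapply(.dyn_pops, function(pop) {
    pr <- network$params[[pop]]
    list(n = network$pops[[pop]], e_leak = pr$e_leak, g_leak = pr$g_leak,
         theta0 = pr$theta0, d_theta = pr$d_theta, tau_theta = pr$tau_theta,
         e_reset = pr$e_reset,
         slot_tau = vapply(pr$slots, `[[`, 1, "tau"),
         slot_e = vapply(pr$slots, `[[`, 1, "e"),
         slot_gain = vapply(pr$slots, `[[`, 1, "gain"))
  })
  projections <- lapply(network$projections, function(p) {
    slot_idx <- match(p$slot, names(network$params[[p$tgt_pop]]$slots)) - 1L
    list(src_pop = unname(pid[p$src_pop]), tgt_pop = unname(pid[p$tgt_pop]),
         slot = slot_idx, src = p$src - 1L, tgt = p$tgt - 1L,
         weight = p$weight)
  })
  list(pops = pops, projections = unname(projections),
       n_mf = network$pops[["mf"]], n_cf = network$pops[["cf"]])
}

.state_to_cpp <- function(state) {
  if (is.null(state)) return(list())
  unname(lapply(.dyn_pops, function(p) state[[p]][c("V", "theta", "g", "pending")]))
}

.state_from_cpp <- function(cst, network) {
  st <- lapply(seq_along(.dyn_pops), function(k) {
    x <- cst[[k]]
    slots <- names(network$params[[.dyn_pops[k]]]$slots)
    colnames(x$g) <- slots; colnames(x$pending) <- slots
    x$spiked <- logical(length(x$V))
    x
  })
  names(st) <- .dyn_pops
  structure(st, class = "pcmli_state")
}

.run_segment <- function(packed, state, mf_rate, coll_idx, cf_id, cf_t,
                         protocol, dcn_smooth0, log_pops, mf_spikes = NULL) {
  log_flags <- stats::setNames(
    c("grc", "goc", "pc", "bc", "sc", "dcn", "mf", "cf") %in% log_pops,
    c("grc", "goc", "pc", "bc", "sc", "dcn", "mf", "cf"))
  .sim_run_trial_cpp(
    packed, state,
    list(mf_rate = mf_rate, coll_idx = coll_idx - 1L,
         coll_base = protocol$coll_base, coll_gain = protocol$coll_gain,
         coll_cap = protocol$coll_cap, cf_id = cf_id - 1L, cf_t = cf_t,
         mf_spikes = mf_spikes),
    list(dcn_tau = protocol$dcn_tau, dcn_smooth0 = dcn_smooth0,
         log = log_flags))
}

.spikes_tbl <- function(sp) tibble::tibble(unit = sp$id, t = as.numeric(sp$t))

# causal single-pole low-pass with unit DC gain, carried initial state
.exp_filter <- function(x, tau, init = 0) {
  d <- exp(-1 / tau)
  as.numeric(stats::filter(x * (1 - d), d, method = "recursive",
                           init = init))
}

#' Convert deep-nucleus spike trains into the virtual eyelid trace
#'
#' Averages the per-ms population rate over the deep-nucleus cells, smooths
#' it with a causal exponential kernel (time constant `dcn_tau`, unit DC
#' gain), passes it through the eyelid plant (a second causal exponential,
#' `plant_tau`), subtracts the pre-CS baseline and scales to millimetres of
#' eyelid closure (capped at full closure).
#'
#' @param dcn_spikes Spike times: a tibble with columns `unit`,`t` (ms,
#'   0-based) or a list of per-cell spike-time vectors.
#' @param n_dcn Number of deep-nucleus cells (must be >= 1).
#' @param n_steps Trace length (ms).
#' @param protocol A [protocol_config()] (supplies `dcn_tau`, `plant_tau`,
#'   `eyelid_gain`, `eyelid_max`).
#' @param baseline_window Samples over which the baseline is averaged
#'   (default the 200-ms pre-CS segment).
#' @param init Initial value of the smoothed rate (Hz), for continuing from
#'   a previous segment.
#' @return Numeric eyelid trace (mm relative to baseline), with the smoothed
#'   DCN rate (Hz) as attribute `"dcn_rate"`.
#' @export
dcn_output_to_eyelid <- function(dcn_spikes, n_dcn, n_steps,
                                 protocol = protocol_config(),
                                 baseline_window = protocol$pre_ms, init = 0) {
  if (missing(dcn_spikes) || is.null(dcn_spikes) || n_dcn < 1) {
    stop("input error: at least one deep-nucleus train required",
         call. = FALSE)
  }
  ts <- if (is.data.frame(dcn_spikes)) dcn_spikes$t else
    unlist(dcn_spikes, use.names = FALSE)
  counts <- tabulate(floor(ts) + 1L, n_steps)
  inst <- 1000 * counts / n_dcn
  rate <- .exp_filter(inst, protocol$dcn_tau, init)
  drive <- .exp_filter(rate, protocol$plant_tau, init)
  base <- mean(drive[seq_len(min(baseline_window, n_steps))])
  eyelid <- pmin(protocol$eyelid_gain * (drive - base), protocol$eyelid_max)
  attr(eyelid, "dcn_rate") <- rate
  eyelid
}

# population rate (Hz) from a spike tibble, causal exponential smoothing
.pop_rate <- function(spikes, n_units, n_steps, tau = 20) {
  counts <- tabulate(floor(spikes$t) + 1L, n_steps)
  inst <- 1000 * counts / n_units
  as.numeric(stats::filter(inst * (1 - exp(-1 / tau)), exp(-1 / tau),
                           method = "recursive"))
}

#' Run one conditioning trial
#'
#' Steps the network over the pre-CS, CS and post windows, logging all
#' spikes; on paired trials the climbing fibers respond to the US with a
#' probability that declines with the expressed CR amplitude (nucleo-olivary
#' feedback). If `plasticity_on`, the granule->PC (and/or granule->MLI,
#' depending on `plast$locus`) and mossy-fiber->DCN rules are applied to the
#' network's weights after the trial.
#'
#' @param network A `pcmli_network` (carries current plastic weights).
#' @param assignment From [assign_mf_roles()].
#' @param trial A [trial_spec()].
#' @param plasticity_on Logical.
#' @param state Carried `pcmli_state` or `NULL` (fresh).
#' @param plast A [plasticity_config()].
#' @param protocol A [protocol_config()].
#' @param dcn_smooth0 Carried smoothed DCN rate (Hz).
#' @param plant0 Carried eyelid-plant state (Hz).
#' @param log_grc Keep granule/mossy spike logs in the returned record
#'   (they are always logged internally when plasticity is on).
#' @return List with `record` (trial record: `trial`, `spikes` per population,
#'   `eyelid`, `dcn_rate`, `cr`, `cf_times`, `iti_s`), `network` (updated
#'   weights), `state`, `dcn_smooth`.
#' @export
run_trial <- function(network, assignment, trial, plasticity_on = TRUE,
                      state = NULL, plast = plasticity_config(),
                      protocol = protocol_config(), dcn_smooth0 = 0,
                      plant0 = 0, log_grc = FALSE) {
  packed <- .pack_network(network)
  n_cf <- network$pops[["cf"]]
  T <- trial$n_steps
  mf_rate <- .mf_rate_matrix(assignment, trial, protocol)
  coll_idx <- which(assignment$role == "dcn_collateral")
  log_pops <- c("pc", "bc", "sc", "dcn", "cf",
                if (plasticity_on || log_grc) c("grc", "mf"))

  # spontaneous climbing-fiber activity over the whole trial
  sp_n <- stats::rpois(n_cf, protocol$cf_spont_hz * T * 1e-3)
  cf_id <- rep(seq_len(n_cf), sp_n)
  cf_t <- floor(runif(sum(sp_n), 0, T))

  run_to <- if (trial$type == "paired") trial$us_onset else T
  seg1 <- .run_segment(packed, .state_to_cpp(state),
                       mf_rate[, seq_len(run_to), drop = FALSE], coll_idx,
                       cf_id[cf_t < run_to], as.integer(cf_t[cf_t < run_to]),
                       protocol, dcn_smooth0, log_pops)
  spikes <- seg1$spikes
  dcn_trace <- seg1$dcn_trace

  if (trial$type == "paired") {
    plant_seg <- .exp_filter(dcn_trace, protocol$plant_tau, plant0)
    base <- mean(plant_seg[seq_len(trial$pre_ms)])
    amp <- protocol$eyelid_gain * (plant_seg[run_to] - base)
    p_fire <- max(protocol$cf_min_p, 1 - max(0, amp) / protocol$cf_suppress_scale)
    us_fires <- runif(1) < p_fire
    cf2_sel <- cf_t >= run_to
    cf2_id <- cf_id[cf2_sel]; cf2_t <- cf_t[cf2_sel] - run_to
    if (us_fires) { cf2_id <- c(seq_len(n_cf), cf2_id); cf2_t <- c(rep(0L, n_cf), cf2_t) }
    ord <- order(cf2_t)
    seg2 <- .run_segment(packed, seg1$state,
                         mf_rate[, (run_to + 1):T, drop = FALSE], coll_idx,
                         cf2_id[ord], as.integer(cf2_t[ord]), protocol,
                         seg1$dcn_smooth, log_pops)
    spikes <- purrr::map2(spikes, seg2$spikes, function(a, b)
      list(id = c(a$id, b$id), t = c(a$t, b$t + run_to)))
    dcn_trace <- c(dcn_trace, seg2$dcn_trace)
    out_state <- seg2$state
    dcn_smooth <- seg2$dcn_smooth
  } else {
    out_state <- seg1$state
    dcn_smooth <- seg1$dcn_smooth
  }

  plant <- .exp_filter(dcn_trace, protocol$plant_tau, plant0)
  base <- mean(plant[seq_len(trial$pre_ms)])
  eyelid <- pmin(protocol$eyelid_gain * (plant - base), protocol$eyelid_max)
  attr(eyelid, "dcn_rate") <- dcn_trace
  cf_times <- sort(spikes$cf$t)
  cr <- cr_measures(eyelid, cs_onset = trial$cs_onset,
                    us_onset = if (trial$type == "paired") trial$us_onset else
                      trial$cs_onset + trial$isi,
                    already_filtered = TRUE)

  if (plasticity_on) {
    grc_tbl <- .spikes_tbl(spikes$grc)
    bursts <- vector("list", network$pops[["grc"]])
    if (nrow(grc_tbl)) {
      by_unit <- split(grc_tbl$t, grc_tbl$unit)
      bt <- lapply(by_unit, detect_bursts, threshold = plast$burst_threshold,
                   window = plast$burst_window)
      bursts[as.integer(names(bt))] <- bt
    }
    empty <- numeric(0)
    bursts[vapply(bursts, is.null, TRUE)] <- list(empty)
    if (plast$locus %in% c("pf_pc", "both")) {
      w <- network$projections$grc_pc$weight
      for (i in seq_len(network$pops[["pc"]])) {
        syn <- which(network$pc_of_grc == i)
        cf_i <- sort(spikes$cf$t[spikes$cf$id == network$cf_of_pc[i]])
        w[syn] <- apply_pf_pc_plasticity(w[syn], bursts[syn], cf_i, plast)
      }
      network$projections$grc_pc$weight <- w
    }
    if (plast$locus %in% c("pf_mli", "both")) {
      cf_all <- sort(spikes$cf$t)
      for (nm in c("grc_bc", "grc_sc")) {
        p <- network$projections[[nm]]
        network$projections[[nm]]$weight <-
          apply_pf_pc_plasticity(p$weight, bursts[p$src], cf_all, plast,
                                 sign = -1)
      }
    }
    pc_rate <- .pop_rate(.spikes_tbl(spikes$pc), network$pops[["pc"]], T)
    mf_tbl <- .spikes_tbl(spikes$mf)
    mf_act <- split(mf_tbl$t + 1, factor(mf_tbl$unit, levels = seq_len(network$pops[["mf"]])))
    w_mf <- attr(network$projections$mf_dcn, "w_mf")
    if (is.null(w_mf)) w_mf <- rep(0.5, network$pops[["mf"]])
    w_mf <- apply_mf_dcn_plasticity(w_mf, mf_act, pc_rate, plast)
    attr(network$projections$mf_dcn, "w_mf") <- w_mf
    network$projections$mf_dcn$weight <- w_mf[network$projections$mf_dcn$src]
  }

  keep <- c("pc", "bc", "sc", "dcn", "cf", if (log_grc) c("grc", "mf"))
  record <- list(
    trial = trial,
    spikes = lapply(spikes[keep], .spikes_tbl),
    eyelid = eyelid, dcn_rate = dcn_trace, cr = cr,
    cf_times = cf_times, iti_s = runif(1, protocol$iti_range_s[1],
                                       protocol$iti_range_s[2]))
  list(record = record, network = network,
       state = .state_from_cpp(out_state, network), dcn_smooth = dcn_smooth,
       plant = plant[length(plant)])
}

#' Run one training session (12 blocks of 9 trials)
#'
#' Each block starts with a CS-alone trial followed by eight paired trials:
#' 108 trials per session, 12 of them CS-alone.
#'
#' @param network A `pcmli_network`.
#' @param assignment From [assign_mf_roles()].
#' @param isi Interstimulus interval (ms).
#' @param plasticity_on Logical.
#' @param state,dcn_smooth0 Carried dynamical state.
#' @param plast,protocol Configurations.
#' @param n_blocks,trials_per_block Session layout.
#' @param keep_records Keep full per-trial records (otherwise only the CR
#'   table).
#' @return List with `records` (if kept), `cr_table` (one row per trial:
#'   `trial_idx`, `type`, `is_cr`, `amplitude_mm`, `onset_ms`,
#'   `criterion_ms`, `iti_s`), `network`, `state`, `dcn_smooth`, `weights`
#'   (end-of-session granule->PC weight snapshot).
#' @export
run_session <- function(network, assignment, isi = 500, plasticity_on = TRUE,
                        state = NULL, dcn_smooth0 = 0, plant0 = 0,
                        plast = plasticity_config(),
                        protocol = protocol_config(), n_blocks = 12,
                        trials_per_block = 9, keep_records = FALSE) {
  n_trials <- n_blocks * trials_per_block
  records <- if (keep_records) vector("list", n_trials)
  cr_rows <- vector("list", n_trials)
  k <- 0L
  for (b in seq_len(n_blocks)) {
    for (j in seq_len(trials_per_block)) {
      k <- k + 1L
      tr <- trial_spec(if (j == 1) "cs_alone" else "paired", isi = isi,
                       protocol = protocol)
      res <- run_trial(network, assignment, tr, plasticity_on, state, plast,
                       protocol, dcn_smooth0, plant0)
      network <- res$network; state <- res$state
      dcn_smooth0 <- res$dcn_smooth; plant0 <- res$plant
      if (keep_records) records[[k]] <- res$record
      cr_rows[[k]] <- dplyr::mutate(res$record$cr, trial_idx = k,
                                    type = tr$type,
                                    iti_s = res$record$iti_s)
    }
  }
  list(records = records, cr_table = dplyr::bind_rows(cr_rows),
       network = network, state = state, dcn_smooth = dcn_smooth0,
       plant = plant0, weights = network$projections$grc_pc$weight)
}

#' Run a multi-session conditioning experiment
#'
#' Builds the network from `config`, assigns mossy-fiber roles, and runs
#' `n_sessions` training sessions at the given ISI, carrying neuronal state
#' and plastic weights across sessions. Stimulus randomness is governed by
#' `seed` (independent of the wiring seed in `config`).
#'
#' @param config A [sim_config()].
#' @param n_sessions Number of 108-trial sessions.
#' @param isi Interstimulus interval (ms).
#' @param seed Stimulus-stream seed.
#' @param plast,protocol Configurations.
#' @param keep_last_records Keep full trial records for the final session.
#' @return A `pcmli_training` object: list with `sessions` (tibble of
#'   per-session CR summaries), `last_session` (records + CR table),
#'   `network`, `assignment`, `initial_weights`, `final_weights`,
#'   `weight_snapshots` (per session), `config`, `plast`, `protocol`.
#' @export
run_training <- function(config, n_sessions = 10, isi = 500, seed = 1,
                         plast = plasticity_config(),
                         protocol = protocol_config(),
                         keep_last_records = TRUE) {
  network <- build_network(config)
  assignment <- assign_mf_roles(config, seed = config$seed, protocol = protocol)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  w0 <- network$projections$grc_pc$weight
  state <- NULL; dcn_smooth <- 0; plant <- 0
  sess_rows <- vector("list", n_sessions)
  snapshots <- vector("list", n_sessions)
  last <- NULL
  for (s in seq_len(n_sessions)) {
    keep <- keep_last_records && s == n_sessions
    res <- run_session(network, assignment, isi = isi, plasticity_on = TRUE,
                       state = state, dcn_smooth0 = dcn_smooth,
                       plant0 = plant, plast = plast,
                       protocol = protocol, keep_records = keep)
    network <- res$network; state <- res$state; dcn_smooth <- res$dcn_smooth
    plant <- res$plant
    paired <- dplyr::filter(res$cr_table, .data$type == "paired")
    sess_rows[[s]] <- tibble::tibble(
      session = s, n_trials = nrow(res$cr_table),
      cr_rate = mean(paired$is_cr),
      mean_cr_amplitude = mean(paired$amplitude_mm),
      mean_onset_ms = mean(paired$onset_ms[paired$is_cr], na.rm = TRUE))
    snapshots[[s]] <- res$weights
    if (keep) last <- res[c("records", "cr_table")]
  }
  structure(list(sessions = dplyr::bind_rows(sess_rows), last_session = last,
                 network = network, assignment = assignment,
                 initial_weights = w0,
                 final_weights = network$projections$grc_pc$weight,
                 weight_snapshots = snapshots, config = config, plast = plast,
                 protocol = protocol, isi = isi, seed = seed),
            class = "pcmli_training")
}

#' @export
print.pcmli_training <- function(x, ...) {
  cat("<pcmli_training> ISI", x$isi, "ms,",
      nrow(x$sessions), "sessions, feedback",
      if (x$config$feedback_enabled) "on" else "off", "\n")
  print(x$sessions)
  invisible(x)
}

#' Simulate inter-trial baseline activity
#'
#' Runs the network under background mossy-fiber drive only (no CS, no US;
#' spontaneous climbing-fiber activity retained), returning the spike logs.
#' Used to generate the 10-s pre-trial epochs consumed by the correlogram
#' analyses.
#'
#' @param network A `pcmli_network`.
#' @param assignment From [assign_mf_roles()].
#' @param duration_s Epoch duration (s).
#' @param state,dcn_smooth0 Carried state.
#' @param protocol A [protocol_config()].
#' @return List with `spikes` (tibbles per population), `state`,
#'   `dcn_smooth`.
#' @export
run_baseline <- function(network, assignment, duration_s = 10, state = NULL,
                         dcn_smooth0 = 0, protocol = protocol_config()) {
  T <- as.integer(duration_s * 1000)
  n_cf <- network$pops[["cf"]]
  mf_rate <- matrix(assignment$background_rate, nrow(assignment), T)
  sp_n <- stats::rpois(n_cf, protocol$cf_spont_hz * duration_s)
  cf_id <- rep(seq_len(n_cf), sp_n)
  cf_t <- as.integer(floor(runif(sum(sp_n), 0, T)))
  ord <- order(cf_t)
  res <- .run_segment(.pack_network(network), .state_to_cpp(state), mf_rate,
                      which(assignment$role == "dcn_collateral"),
                      cf_id[ord], cf_t[ord], protocol, dcn_smooth0,
                      c("pc", "bc", "sc", "dcn", "cf"))
  list(spikes = lapply(res$spikes[c("pc", "bc", "sc", "dcn", "cf")],
                       .spikes_tbl),
       state = .state_from_cpp(res$state, network), dcn_smooth = res$dcn_smooth)
}
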