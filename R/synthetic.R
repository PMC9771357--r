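# Seeded generators for every input the analysis stack consumes, with the
# generating parameters (ground truth) carried alongside the data.

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  force(expr)
}

.logistic <- function(t, center, scale) 1 / (1 + exp(-(t - center) / scale))

# thin an inhomogeneous Poisson rate (Hz, one sample per ms) into spike times
.thin_spikes <- function(rate_hz) {
  p <- pmin(1, rate_hz * 1e-3)
  which(runif(length(p)) < p) - 1
}

#' Specification for a synthetic conditioning-session dataset
#'
#' Defines the statistical structure of coupled PC/MLI spike trains and
#' eyelid traces around conditioned responses: on CR trials the eyelid rises
#' sigmoidally to the drawn amplitude from the drawn onset, the PC rate drops
#' (by `pause_depth`) starting `lead_ms` before the MLI rate rises (by
#' `burst_height`-fold), and inter-trial 10-s baseline epochs carry a
#' per-spike inhibitory coupling from PC to MLI.
#'
#' @param n_trials Trials per dataset.
#' @param isi Interstimulus interval (ms).
#' @param cr_prob Probability a trial is a CR.
#' @param onset_mean,onset_sd CR-onset distribution (ms from CS onset).
#' @param amp_mean,amp_sd CR-amplitude distribution (mm).
#' @param pc_base PC baseline simple-spike rate (Hz).
#' @param pause_depth Fractional PC rate decrease during the CR (0-1).
#' @param mli_base MLI baseline rate (Hz).
#' @param burst_height MLI CR-related rate increase (fold over baseline).
#' @param lead_ms PC lead over the MLI (ms): the PC decrease starts this
#'   long before the MLI increase.
#' @param coupling,coupling_lag,coupling_dur Per-spike inhibitory coupling in
#'   baseline epochs: MLI rate is multiplied by `1 - coupling` for
#'   `coupling_dur` ms starting `coupling_lag` ms after each PC spike.
#' @param rate_noise Trial-to-trial multiplicative rate jitter (SD,
#'   fraction).
#' @param eyelid_noise Additive white noise on the eyelid trace (mm SD).
#' @param n_baseline_epochs,baseline_s Baseline epochs (count, seconds each).
#' @param seed Integer seed.
#' @return A `pcmli_session_spec` list.
#' @export
session_gen_spec <- function(n_trials = 100, isi = 500, cr_prob = 0.8,
                             onset_mean = 250, onset_sd = 50, amp_mean = 4,
                             amp_sd = 1, pc_base = 70, pause_depth = 0.6,
                             mli_base = 15, burst_height = 4, lead_ms = 50,
                             coupling = 0.5, coupling_lag = 1,
                             coupling_dur = 4, rate_noise = 0.1,
                             eyelid_noise = 0.02, n_baseline_epochs = 5,
                             baseline_s = 10, seed = 1) {
  stopifnot(cr_prob >= 0, cr_prob <= 1, pc_base > 0, mli_base > 0,
            pause_depth >= 0, pause_depth <= 1, coupling >= 0, coupling <= 1)
  if (onset_mean + 160 > isi) {
    stop("spec error: CR onsets this late would overlap the US analysis window",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "pcmli_session_spec")
}

#' Generate a synthetic conditioning session with ground truth
#'
#' @param spec A [session_gen_spec()].
#' @return A `pcmli_session_gen`: list with `trials` (tibble `trial`,
#'   `is_cr`, `onset_ms`, `amplitude_mm`), per-trial list-columns inside
#'   `trials` (`eyelid`, `pc_spikes`, `mli_spikes`, `pc_rate_true`,
#'   `mli_rate_true`), `baseline` (list with per-epoch `pc`/`mli` spike
#'   vectors), `cs_onset`, `us_onset`, `n_steps` and `ground_truth`.
#' @export
gen_session_data <- function(spec = session_gen_spec()) {
  stopifnot(inherits(spec, "pcmli_session_spec"))
  .with_seed(spec$seed, {
    cs <- 200
    us <- cs + spec$isi
    T <- cs + spec$isi + 50 + 200
    tt <- seq_len(T) - 1
    rows <- purrr::map_dfr(seq_len(spec$n_trials), function(i) {
      is_cr <- runif(1) < spec$cr_prob
      onset <- if (is_cr)
        min(max(rnorm(1, spec$onset_mean, spec$onset_sd), 50),
            spec$isi - 160) else NA_real_
      amp <- if (is_cr) max(rnorm(1, spec$amp_mean, spec$amp_sd), 0.5) else 0
      if (is_cr) {
        eyelid <- amp * .logistic(tt, cs + onset + 60, 20)
        g1 <- max(1 + rnorm(1, 0, spec$rate_noise), 0.2)
        g2 <- max(1 + rnorm(1, 0, spec$rate_noise), 0.2)
        pc_rate <- spec$pc_base * g1 *
          (1 - spec$pause_depth * .logistic(tt, cs + onset - spec$lead_ms + 60,
                                            20))
        mli_rate <- spec$mli_base * g2 *
          (1 + (spec$burst_height - 1) * .logistic(tt, cs + onset + 60, 20))
      } else {
        eyelid <- numeric(T)
        pc_rate <- rep(spec$pc_base, T)
        mli_rate <- rep(spec$mli_base, T)
      }
      eyelid <- eyelid + rnorm(T, 0, spec$eyelid_noise)
      tibble::tibble(
        trial = i, is_cr = is_cr, onset_ms = onset, amplitude_mm = amp,
        eyelid = list(eyelid), pc_rate_true = list(pc_rate),
        mli_rate_true = list(mli_rate),
        pc_spikes = list(.thin_spikes(pc_rate)),
        mli_spikes = list(.thin_spikes(mli_rate)))
    })
    baseline <- gen_coupled_trains(
      duration_s = spec$baseline_s, n_epochs = spec$n_baseline_epochs,
      pc_rate = spec$pc_base, mli_rate = spec$mli_base,
      coupling = spec$coupling, lag = spec$coupling_lag,
      dur = spec$coupling_dur, seed = NULL)
    structure(list(trials = rows, baseline = baseline, cs_onset = cs,
                   us_onset = us, n_steps = T,
                   ground_truth = spec[setdiff(names(spec), "seed")],
                   spec = spec),
              class = "pcmli_session_gen")
  })
}

#' Generate coupled (or independent) PC/MLI baseline spike trains
#'
#' Homogeneous Poisson PC train; the MLI rate is multiplied by
#' `1 - coupling` for `dur` ms starting `lag` ms after every PC spike, then
#' thinned into spikes. With `coupling = 0` the trains are independent.
#' Because suppression is tied to PC spikes, long PC inter-spike intervals
#' (pauses) leave the MLI un-suppressed, so pause-triggered MLI rate
#' increases emerge from the same mechanism.
#'
#' @param duration_s Epoch length (s).
#' @param n_epochs Number of epochs.
#' @param pc_rate,mli_rate Baseline rates (Hz).
#' @param coupling Fractional MLI suppression per PC spike (0-1).
#' @param lag,dur Suppression latency and duration (ms).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return List with `pc`, `mli` (lists of per-epoch spike-time vectors, ms
#'   within epoch) and `ground_truth`.
#' @export
gen_coupled_trains <- function(duration_s = 10, n_epochs = 5, pc_rate = 60,
                               mli_rate = 20, coupling = 0.5, lag = 1,
                               dur = 4, seed = 1) {
  gen <- function() {
    T <- as.integer(duration_s * 1000)
    pc <- lapply(seq_len(n_epochs), function(e)
      .thin_spikes(rep(pc_rate, T)))
    mli <- lapply(pc, function(ps) {
      rate <- rep(mli_rate, T)
      if (coupling > 0 && length(ps)) {
        idx <- unlist(lapply(ps, function(s) (s + lag):(s + lag + dur - 1)))
        idx <- idx[idx >= 0 & idx < T] + 1L
        rate[unique(idx)] <- rate[unique(idx)] * (1 - coupling)
      }
      .thin_spikes(rate)
    })
    list(pc = pc, mli = mli,
         ground_truth = list(pc_rate = pc_rate, mli_rate = mli_rate,
                             coupling = coupling, lag = lag, dur = dur,
                             duration_s = duration_s, n_epochs = n_epochs))
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Specification for synthetic IPSC trains from a two-pool vesicle model
#'
#' Per stimulus, a binomial fraction of the current readily releasable pool
#' is released; the pool is then replenished from the reserve at a baseline
#' rate (quanta/s) plus an activity-dependent amount per stimulus (the
#' mobilization acceleration that makes steady-state amplitude
#' frequency-independent), capped at the pool capacity.
#'
#' Two presets: `"pc_mli"` reproduces the target synapse's behavior (release
#' fraction 0.07, strong activity-dependent mobilization, steady state near
#' half the initial amplitude at 10-100 Hz); `"depleting"` is a
#' conventional depleting synapse (release fraction 0.35, weak mobilization)
#' on which the cumulative-charge method recovers the planted pool size
#' accurately.
#'
#' @param n_quanta RRP capacity (quanta).
#' @param release_frac Release fraction per stimulus.
#' @param mobil_base Baseline mobilization (quanta/s).
#' @param mobil_act Activity-dependent mobilization (quanta per stimulus).
#' @param q_charge Mean quantal charge (pC).
#' @param q_amp Mean quantal amplitude (pA).
#' @param q_cv Quantal coefficient of variation.
#' @param frequency Stimulus frequency (Hz).
#' @param n_stim Train length.
#' @param n_sweeps Independent sweeps averaged into the reported train (the
#'   recorded trains are averages of repeated trials).
#' @param preset `"pc_mli"`, `"depleting"` or `NULL` (use the arguments as
#'   given).
#' @param seed Integer seed.
#' @return A `pcmli_ipsc_spec` list.
#' @export
ipsc_gen_spec <- function(n_quanta = 100, release_frac = 0.07,
                          mobil_base = 1, mobil_act = 3.47, q_charge = 0.18,
                          q_amp = 18, q_cv = 0.3, frequency = 50,
                          n_stim = 60, n_sweeps = 12, preset = NULL,
                          seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("pc_mli", "depleting"))
    if (preset == "depleting") {
      release_frac <- 0.35; mobil_base <- 2; mobil_act <- 1.0
    } else {
      release_frac <- 0.07; mobil_base <- 0; mobil_act <- 3.5
    }
  }
  stopifnot(release_frac > 0, release_frac <= 1, n_quanta >= 1)
  structure(list(n_quanta = n_quanta, release_frac = release_frac,
                 mobil_base = mobil_base, mobil_act = mobil_act,
                 q_charge = q_charge, q_amp = q_amp, q_cv = q_cv,
                 frequency = frequency, n_stim = n_stim, n_sweeps = n_sweeps,
                 preset = preset, seed = seed),
            class = "pcmli_ipsc_spec")
}

#' Generate a synthetic IPSC train with ground truth
#'
#' @param spec An [ipsc_gen_spec()].
#' @return A `pcmli_ipsc_train` (averaged over `n_sweeps` sweeps) with the
#'   generating parameters in `attr(, "ground_truth")`.
#' @export
gen_ipsc_trains <- function(spec = ipsc_gen_spec()) {
  stopifnot(inherits(spec, "pcmli_ipsc_spec"))
  .with_seed(spec$seed, {
    isi_mobil <- spec$mobil_base / spec$frequency + spec$mobil_act
    one_sweep <- function() {
      N <- spec$n_quanta
      rel <- numeric(spec$n_stim)
      for (k in seq_len(spec$n_stim)) {
        r <- rbinom(1, round(N), spec$release_frac)
        rel[k] <- r
        N <- min(N - r + isi_mobil, spec$n_quanta)
      }
      rel
    }
    rel <- rowMeans(vapply(seq_len(spec$n_sweeps), function(s) one_sweep(),
                           numeric(spec$n_stim)))
    qnoise <- function(n_rel) {
      1 + rnorm(length(n_rel), 0,
                spec$q_cv / sqrt(pmax(n_rel * spec$n_sweeps, 1)))
    }
    amp <- pmax(rel * spec$q_amp * qnoise(rel), 0)
    chg <- pmax(rel * spec$q_charge * qnoise(rel), 0)
    out <- ipsc_train(spec$frequency, amp, charge = chg)
    attr(out, "ground_truth") <- list(
      rrp_quanta = spec$n_quanta, release_frac = spec$release_frac,
      mobil_quanta_per_stim = isi_mobil,
      mobil_quanta_per_s = isi_mobil * spec$frequency,
      q_charge = spec$q_charge,
      expected_plateau = min(1, isi_mobil / (spec$release_frac * spec$n_quanta)))
    out
  })
}

#' Generate synthetic photostimulation map repeats
#'
#' Planted pixels respond with probability `response_prob`; spontaneous
#' events contaminate random pixels independently at `spont_prob` per pixel
#' per repeat.
#'
#' @param planted Tibble with `row`, `col` of planted responsive pixels
#'   (within the 32 x 32 grid).
#' @param repeats Number of repeated maps.
#' @param response_prob Response probability of planted pixels.
#' @param amplitude_pA Mean evoked IPSC amplitude for responsive pixels.
#' @param spont_prob Per-pixel spontaneous-event probability.
#' @param spike Generate a spike map (logical `spike` column) instead of an
#'   IPSC amplitude map.
#' @param seed Integer seed.
#' @return Tibble (`row`, `col`, `rep`, and `amplitude_pA` or `spike`) with
#'   `attr(, "ground_truth")` holding the planted set.
#' @export
gen_map_trials <- function(planted, repeats = 3, response_prob = 1,
                           amplitude_pA = 40, spont_prob = 0, spike = FALSE,
                           seed = 1) {
  stopifnot(all(planted$row >= 1), all(planted$row <= 32),
            all(planted$col >= 1), all(planted$col <= 32))
  .with_seed(seed, {
    grid <- tidyr::expand_grid(row = 1:32, col = 1:32)
    key <- paste(grid$row, grid$col)
    is_planted <- key %in% paste(planted$row, planted$col)
    out <- purrr::map_dfr(seq_len(repeats), function(rp) {
      evoked <- is_planted & runif(nrow(grid)) < response_prob
      spont <- runif(nrow(grid)) < spont_prob
      hit <- evoked | spont
      g <- dplyr::mutate(grid, rep = rp)
      if (spike) {
        g$spike <- hit
      } else {
        g$amplitude_pA <- ifelse(hit, pmax(amplitude_pA *
                                             (1 + rnorm(nrow(grid), 0, 0.2)),
                                           16), 0)
      }
      g
    })
    attr(out, "ground_truth") <- list(planted = planted,
                                      response_prob = response_prob,
                                      spont_prob = spont_prob,
                                      repeats = repeats)
    out
  })
}

#' Generate a labeled sample from a two-Gaussian mixture
#'
#' Emulates the distribution of per-unit CR correlations: a large
#' near-zero component and a minority high-correlation component. Draws are
#' clipped to `[-1, 1]`.
#'
#' @param means,sds,weights Component parameters (low component first;
#'   weights sum to 1).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Tibble (`r`, `component`) with `attr(, "ground_truth")`.
#' @export
gen_mixture_sample <- function(means = c(-0.05, 0.43), sds = c(0.15, 0.15),
                               weights = c(0.9, 0.1), n = 800, seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(sds > 0))
  .with_seed(seed, {
    comp <- sample(seq_along(weights), n, replace = TRUE, prob = weights)
    r <- pmin(pmax(rnorm(n, means[comp], sds[comp]), -1), 1)
    out <- tibble::tibble(r = r, component = comp)
    attr(out, "ground_truth") <- list(means = means, sds = sds,
                                      weights = weights, n = n)
    out
  })
}

#' Write a generator's ground truth as a sidecar JSON file
#'
#' @param x An object produced by one of the generators (carrying a
#'   `ground_truth` element or attribute).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- if (!is.null(attr(x, "ground_truth"))) attr(x, "ground_truth") else
    x$ground_truth
  if (is.null(gt)) stop("no ground truth attached", call. = FALSE)
  gt <- purrr::map(gt, function(v) if (is.data.frame(v)) as.list(v) else v)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
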