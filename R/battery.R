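# Analyses that consume a trained simulation: per-MLI CR correlations and
# the PC/PC-MLI lead-lag distribution.

# causal half-Gaussian rates for every unit of one trial at once
# (columns = units); identical math to instantaneous_rate()
.rate_matrix <- function(spikes_tbl, units, n_steps, kernel_sd) {
  support <- ceiling(7 * kernel_sd)
  u <- 0:support
  k <- 2 / (kernel_sd * sqrt(2 * pi)) * exp(-u^2 / (2 * kernel_sd^2))
  sel <- spikes_tbl$unit %in% units
  col <- match(spikes_tbl$unit[sel], units)
  t_idx <- floor(spikes_tbl$t[sel]) + 1L
  counts <- matrix(0, n_steps, length(units))
  if (any(sel)) {
    tab <- tabulate((col - 1L) * n_steps + t_idx, n_steps * length(units))
    counts[] <- tab
  }
  padded <- rbind(matrix(0, support, length(units)), counts)
  full <- stats::filter(padded, k, method = "convolution", sides = 1)
  r <- full[support + seq_len(n_steps), , drop = FALSE] * 1000
  r[r < 0] <- 0
  r
}

#' Per-MLI correlation with the virtual conditioned response
#'
#' For every molecular-layer interneuron (basket and stellate cells) in a
#' trained simulation, computes the trial-wise correlation between its
#' instantaneous firing rate and the virtual eyelid trace over CR trials of
#' the final session ([cr_correlation()]), returning the per-unit means that
#' feed the two-Gaussian classification.
#'
#' @param training A `pcmli_training` from [run_training()] (with
#'   `keep_last_records = TRUE`).
#' @param kernel_sd Rate-kernel SD (ms).
#' @param min_amplitude Restrict to CR trials of at least this amplitude
#'   (mm); 0 keeps every CR trial.
#' @return Tibble with `unit` (population-local index), `pop` (`bc`/`sc`),
#'   `is_pcmli`, `r` (mean over CR trials), `n_used`.
#' @export
mli_cr_correlations <- function(training, kernel_sd = 25,
                                min_amplitude = 0) {
  stopifnot(inherits(training, "pcmli_training"),
            !is.null(training$last_session$records))
  recs <- training$last_session$records
  crt <- training$last_session$cr_table
  net <- training$network
  paired <- which(crt$type == "paired")
  cr_flags <- crt$is_cr[paired] & crt$amplitude_mm[paired] >= min_amplitude
  n_steps <- length(recs[[paired[1]]]$eyelid)
  cs <- recs[[paired[1]]]$trial$cs_onset
  us <- recs[[paired[1]]]$trial$us_onset
  eyelids <- lapply(recs[paired], function(r) as.numeric(r$eyelid))
  idx <- (cs - 150 + 1):us # same window as cr_correlation()
  one_pop <- function(pop) {
    n_units <- net$pops[[pop]]
    r_sum <- numeric(n_units)
    n_used <- integer(n_units)
    for (k in which(cr_flags)) {
      rm <- .rate_matrix(recs[[paired[k]]]$spikes[[pop]], seq_len(n_units),
                         n_steps, kernel_sd)[idx, , drop = FALSE]
      e <- eyelids[[k]][idx]
      if (sd(e) == 0) next
      ok <- apply(rm, 2, sd) > 0
      rr <- suppressWarnings(as.numeric(cor(rm, e)))
      r_sum[ok] <- r_sum[ok] + rr[ok]
      n_used[ok] <- n_used[ok] + 1L
    }
    tibble::tibble(unit = seq_len(n_units), pop = pop,
                   is_pcmli = pop == "bc" & seq_len(n_units) %in% net$pcmli_idx,
                   r = ifelse(n_used > 0, r_sum / n_used, NA_real_),
                   n_used = n_used)
  }
  dplyr::bind_rows(one_pop("bc"), one_pop("sc"))
}

#' Lead-lag distribution over PC / PC-MLI pairs of a trained simulation
#'
#' For each wired PC -> PC-MLI pair, computes on every usable CR trial of the
#' final session the pre-CR fraction of the PC's full decrease and of the
#' PC-MLI's full increase relative to CR onset ([pre_cr_fraction()]), and
#' averages the per-trial differences within the pair. Positive differences
#' mean the PC leads. Trials whose CR onset sits too close to the US (the
#' 100- or 150-ms post-onset window would overlap it) are excluded.
#'
#' Fractions are computed trial by trial and then averaged, rather than on
#' rates averaged after aligning trials at CR onset: onset-aligned averaging
#' presumes the cells' responses track CR onset trial by trial, and when
#' responses are partly stimulus-locked it inflates the pre-onset fraction
#' of whichever cell's response is more step-like.
#'
#' @param training A `pcmli_training`.
#' @param kernel_sd Rate-kernel SD (ms).
#' @param min_amplitude Minimum CR amplitude (mm) for a trial to be used.
#' @return Tibble with one row per pair: `pc`, `pcmli`, `delta_pc`,
#'   `delta_mli`, `difference` (per-trial means), `n_trials`.
#' @export
leadlag_distribution <- function(training, kernel_sd = 25,
                                 min_amplitude = 0.3) {
  stopifnot(inherits(training, "pcmli_training"),
            !is.null(training$last_session$records))
  recs <- training$last_session$records
  crt <- training$last_session$cr_table
  net <- training$network
  isi <- training$isi
  window <- if (isi <= 250) 100 else 150
  paired <- which(crt$type == "paired")
  cs <- recs[[paired[1]]]$trial$cs_onset
  usable <- paired[crt$is_cr[paired] &
                     crt$amplitude_mm[paired] >= min_amplitude &
                     is.finite(crt$onset_ms[paired]) &
                     crt$onset_ms[paired] + window <= isi]
  if (!length(usable)) {
    return(tibble::tibble(pc = integer(0), pcmli = integer(0),
                          delta_pc = numeric(0), delta_mli = numeric(0),
                          difference = numeric(0), n_trials = integer(0)))
  }
  n_steps <- length(recs[[usable[1]]]$eyelid)
  fb <- training$network$projections$pc_bc
  pairs <- unique(tibble::tibble(pc = fb$src, pcmli = fb$tgt))
  pc_units <- sort(unique(pairs$pc))
  mli_units <- sort(unique(pairs$pcmli))
  pc_rates <- lapply(usable, function(i)
    .rate_matrix(recs[[i]]$spikes$pc, pc_units, n_steps, kernel_sd))
  mli_rates <- lapply(usable, function(i)
    .rate_matrix(recs[[i]]$spikes$bc, mli_units, n_steps, kernel_sd))
  purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
    jp <- match(pairs$pc[j], pc_units)
    jm <- match(pairs$pcmli[j], mli_units)
    per_trial <- purrr::map_dfr(seq_along(usable), function(k)
      pre_cr_fraction(pc_rates[[k]][, jp], mli_rates[[k]][, jm],
                      crt$onset_ms[usable[k]], isi = isi, cs_onset = cs,
                      window = window))
    ok <- !per_trial$excluded & is.finite(per_trial$difference)
    tibble::tibble(pc = pairs$pc[j], pcmli = pairs$pcmli[j],
                   delta_pc = mean(per_trial$delta_pc[ok]),
                   delta_mli = mean(per_trial$delta_mli[ok]),
                   difference = mean(per_trial$difference[ok]),
                   n_trials = sum(ok))
  })
}
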