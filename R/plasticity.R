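# Learning rules: parallel-fiber -> PC LTD/LTP gated by climbing-fiber timing,
# and mossy-fiber -> DCN LTD/LTP gated by pauses/bursts in the PC population
# rate, plus weight-change summaries.

#' Plasticity configuration
#'
#' @param ltd_window Eligibility window relative to a climbing-fiber spike
#'   (ms): a granule-cell burst at time `t` is depressed when a climbing-fiber
#'   spike occurs at `t + 100 .. t + 300` ms (i.e. the burst fell 300-100 ms
#'   *before* the climbing-fiber input); otherwise the synapse potentiates.
#' @param ltd_step,ltp_step Weight decrements/increments per burst
#'   (dimensionless; `ltd_step` exceeds `ltp_step` in magnitude).
#' @param w_max Upper weight bound; weights live in `[0, w_max]`.
#' @param burst_threshold,burst_window A granule-cell "threshold burst" is
#'   `burst_threshold` or more spikes within a `burst_window`-ms sliding
#'   window; the burst time is its first spike.
#' @param dcn_pause_frac,dcn_strong_frac PC-population-rate thresholds for the
#'   nuclear rule, as fractions of the baseline rate.
#' @param dcn_window Minimum episode duration (ms) for the nuclear rule.
#' @param dcn_ltd_step,dcn_ltp_step Mossy-fiber -> DCN weight steps.
#' @param locus Where timing-gated parallel-fiber plasticity acts:
#'   `"pf_pc"` (granule->PC, the default), `"pf_mli"` (granule->MLI only;
#'   the rule's sign is inverted there, potentiating inside the window, since
#'   MLIs must increase CS-driven firing to drive PCs down), or `"both"`.
#' @return A `pcmli_plasticity` list.
#' @export
plasticity_config <- function(ltd_window = c(-300, -100), ltd_step = 0.035,
                              ltp_step = 0.011, w_max = 1,
                              burst_threshold = 2, burst_window = 10,
                              dcn_pause_frac = 0.25, dcn_strong_frac = 1.5,
                              dcn_window = 50, dcn_ltd_step = 0.01,
                              dcn_ltp_step = 0.004,
                              locus = c("pf_pc", "pf_mli", "both")) {
  stopifnot(ltd_window[1] < ltd_window[2], ltd_window[2] < 0,
            ltd_step > 0, ltp_step > 0, ltd_step > ltp_step,
            w_max > 0, burst_threshold >= 1, burst_window > 0,
            dcn_window > 0)
  structure(list(ltd_window = ltd_window, ltd_step = ltd_step,
                 ltp_step = ltp_step, w_max = w_max,
                 burst_threshold = burst_threshold,
                 burst_window = burst_window,
                 dcn_pause_frac = dcn_pause_frac,
                 dcn_strong_frac = dcn_strong_frac, dcn_window = dcn_window,
                 dcn_ltd_step = dcn_ltd_step, dcn_ltp_step = dcn_ltp_step,
                 locus = match.arg(locus)),
            class = "pcmli_plasticity")
}

#' Detect threshold bursts in a spike train
#'
#' A burst is `threshold` or more spikes within a `window`-ms span; bursts are
#' taken greedily left to right and do not share spikes. The burst time is the
#' time of its first spike.
#'
#' @param spike_times Sorted numeric spike times (ms).
#' @param threshold Minimum spikes per burst.
#' @param window Span (ms).
#' @return Numeric vector of burst onset times.
#' @export
detect_bursts <- function(spike_times, threshold = 2, window = 10) {
  n <- length(spike_times)
  if (n < threshold) return(numeric(0))
  if (is.unsorted(spike_times)) {
    stop("input error: spike times must be sorted", call. = FALSE)
  }
  out <- numeric(0)
  i <- 1L
  while (i + threshold - 1L <= n) {
    if (spike_times[i + threshold - 1L] - spike_times[i] <= window) {
      out <- c(out, spike_times[i])
      i <- i + threshold
    } else {
      i <- i + 1L
    }
  }
  out
}

# count, for each burst time t, whether any CF spike falls in [t+lo, t+hi]
.has_cf_in_window <- function(burst_times, cf_times, lo, hi) {
  if (!length(cf_times)) return(rep(FALSE, length(burst_times)))
  hi_idx <- findInterval(burst_times + hi, cf_times)
  lo_idx <- findInterval(burst_times + lo - 1e-9, cf_times)
  hi_idx > lo_idx
}

#' Apply timing-gated parallel-fiber plasticity
#'
#' For every granule-cell threshold burst at time `t`: if any climbing-fiber
#' spike occurs between 100 and 300 ms after the burst (so the burst fell in
#' the 300-100 ms window before the climbing-fiber input), the synapse is
#' depressed by `ltd_step`; otherwise it is potentiated by `ltp_step`.
#' Weights are clipped to `[0, w_max]`.
#'
#' @param weights Numeric weight vector, one per granule-cell synapse.
#' @param granule_burst_times List (same length as `weights`) of sorted burst
#'   times (ms) for each synapse's granule cell.
#' @param cf_spike_times Sorted climbing-fiber spike times (ms) for the
#'   postsynaptic cell.
#' @param config A [plasticity_config()].
#' @param sign `+1` for the canonical granule->PC rule (LTD inside the
#'   window); `-1` inverts it (used for the granule->MLI locus variant).
#' @return Updated weight vector.
#' @export
#' @examples
#' cfg <- plasticity_config()
#' # burst at 1000 ms, climbing fiber at 1200 ms: lag inside the window -> LTD
#' apply_pf_pc_plasticity(0.5, list(1000), 1200, cfg)
apply_pf_pc_plasticity <- function(weights, granule_burst_times,
                                   cf_spike_times, config = plasticity_config(),
                                   sign = 1) {
  stopifnot(length(weights) == length(granule_burst_times))
  if (is.unsorted(cf_spike_times)) {
    stop("input error: climbing-fiber spike times must be sorted",
         call. = FALSE)
  }
  lo <- -config$ltd_window[2]   # 100 ms
  hi <- -config$ltd_window[1]   # 300 ms
  nb <- lengths(granule_burst_times)
  idx <- rep.int(seq_along(weights), nb)
  bt <- unlist(granule_burst_times, use.names = FALSE)
  if (length(bt)) {
    if (any(vapply(granule_burst_times, is.unsorted, TRUE))) {
      stop("input error: burst times must be sorted", call. = FALSE)
    }
    ltd <- .has_cf_in_window(bt, cf_spike_times, lo, hi)
    dw <- ifelse(ltd, -config$ltd_step, config$ltp_step) * sign
    delta <- rowsum(dw, idx)
    weights[as.integer(rownames(delta))] <-
      weights[as.integer(rownames(delta))] + delta[, 1]
  }
  pmin(pmax(weights, 0), config$w_max)
}

# episodes where `cond` holds for at least `min_len` consecutive samples
.episodes <- function(cond, min_len) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

#' Apply the mossy-fiber -> deep-nucleus plasticity rule
#'
#' Mossy-fiber synapses active during an abrupt pause in the PC population
#' rate (rate below `dcn_pause_frac` x baseline for at least `dcn_window` ms)
#' are depressed; those active during strong PC activity (above
#' `dcn_strong_frac` x baseline for at least `dcn_window` ms) are potentiated.
#'
#' @param weights Numeric vector, one weight per mossy fiber.
#' @param mf_activity List (one entry per mossy fiber) of spike times (ms,
#'   indexed on the same clock as `pc_population_rate`, first sample = 1 ms).
#' @param pc_population_rate PC population rate (Hz), one sample per ms.
#' @param config A [plasticity_config()].
#' @param baseline Baseline rate (Hz); default: mean over the first 200 ms.
#' @return Updated weight vector.
#' @export
apply_mf_dcn_plasticity <- function(weights, mf_activity, pc_population_rate,
                                    config = plasticity_config(),
                                    baseline = NULL) {
  stopifnot(length(weights) == length(mf_activity))
  nT <- length(pc_population_rate)
  if (config$dcn_window > nT) {
    stop("input error: criterion window longer than record", call. = FALSE)
  }
  if (is.null(baseline)) baseline <- mean(pc_population_rate[seq_len(min(200, nT))])
  apply_epi <- function(w, epi, step) {
    if (!nrow(epi)) return(w)
    for (k in seq_len(nrow(epi))) {
      active <- vapply(mf_activity, function(ts)
        any(ts >= epi[k, "start"] & ts <= epi[k, "end"]), TRUE)
      w[active] <- w[active] + step
    }
    w
  }
  weights <- apply_epi(weights,
                       .episodes(pc_population_rate < config$dcn_pause_frac * baseline,
                                 config$dcn_window),
                       -config$dcn_ltd_step)
  weights <- apply_epi(weights,
                       .episodes(pc_population_rate > config$dcn_strong_frac * baseline,
                                 config$dcn_window),
                       config$dcn_ltp_step)
  pmin(pmax(weights, 0), config$w_max)
}

#' Summarize net synaptic weight changes
#'
#' Computes per-synapse net change (final minus initial), a binned histogram
#' (LTD negative, LTP positive; bins are `[bin_left, bin_left + bin_width)`)
#' and the cumulative distribution.
#'
#' @param initial_weights,final_weights Equal-length numeric vectors.
#' @param bin_width Histogram bin width.
#' @return A `pcmli_weight_summary`: list with `changes`, `histogram`
#'   (tibble: `bin_left`, `count`) and `cumulative` (tibble: `bin_left`,
#'   `cum_fraction`).
#' @export
weight_change_summary <- function(initial_weights, final_weights,
                                  bin_width = 0.02) {
  if (length(initial_weights) != length(final_weights)) {
    stop("input error: weight vectors must have equal length", call. = FALSE)
  }
  ch <- final_weights - initial_weights
  bin_left <- floor(ch / bin_width + 1e-9) * bin_width
  tab <- table(factor(format(bin_left, nsmall = 10)))
  hist <- tibble::tibble(bin_left = as.numeric(names(tab)),
                         count = as.integer(tab)) |>
    dplyr::arrange(.data$bin_left)
  cum <- dplyr::mutate(hist,
                       cum_fraction = cumsum(.data$count) / sum(.data$count))
  structure(list(changes = ch, bin_width = bin_width, histogram = hist,
                 cumulative = cum[, c("bin_left", "cum_fraction")]),
            class = "pcmli_weight_summary")
}

#' Bin-wise difference between two weight-change summaries
#'
#' Aligns the two histograms on the union of their bins and subtracts counts
#' (`a - b`); the cumulative form of the difference is also returned.
#'
#' @param a,b `pcmli_weight_summary` objects with equal `bin_width`.
#' @return Tibble with `bin_left`, `count_diff`, `cum_diff`.
#' @export
weight_summary_difference <- function(a, b) {
  stopifnot(inherits(a, "pcmli_weight_summary"),
            inherits(b, "pcmli_weight_summary"),
            a$bin_width == b$bin_width)
  m <- dplyr::full_join(
    dplyr::rename(a$histogram, count_a = "count"),
    dplyr::rename(b$histogram, count_b = "count"), by = "bin_left") |>
    dplyr::arrange(.data$bin_left) |>
    dplyr::mutate(dplyr::across(c("count_a", "count_b"),
                                ~ tidyr::replace_na(.x, 0L)),
                  count_diff = .data$count_a - .data$count_b,
                  cum_diff = cumsum(.data$count_diff))
  m[, c("bin_left", "count_diff", "cum_diff")]
}
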