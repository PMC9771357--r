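# Spike- and event-triggered cross-correlograms with inter-spike-interval
# shuffle nulls, computed on inter-trial baseline epochs.

# counts of target spikes in 1-ms lag bins centred on -lag_max..lag_max
.count_lags <- function(trigger, target, lag_max) {
  nb <- 2L * lag_max + 1L
  counts <- numeric(nb)
  if (!length(trigger) || !length(target)) return(counts)
  lo <- findInterval(trigger - lag_max - 0.5, target)
  hi <- findInterval(trigger + lag_max + 0.5 - 1e-9, target)
  n_pairs <- hi - lo
  keep <- n_pairs > 0
  if (!any(keep)) return(counts)
  trg <- rep.int(trigger[keep], n_pairs[keep])
  idx <- sequence(n_pairs[keep], from = lo[keep] + 1L)
  delta <- target[idx] - trg
  bin <- floor(delta + 0.5) + lag_max + 1L
  ok <- bin >= 1L & bin <= nb
  tabulate(bin[ok], nb)
}

.shuffle_train <- function(times) {
  if (length(times) < 3) return(times)
  isi <- diff(times)
  times[1] + c(0, cumsum(sample(isi)))
}

.correlogram_core <- function(trigger_epochs, target_epochs, n_shuffles,
                              lag_max) {
  counts <- numeric(2L * lag_max + 1L)
  shuf <- matrix(0, n_shuffles, 2L * lag_max + 1L)
  for (e in seq_along(trigger_epochs)) {
    tr <- trigger_epochs[[e]]; tg <- target_epochs[[e]]
    counts <- counts + .count_lags(tr, tg, lag_max)
    for (s in seq_len(n_shuffles)) {
      shuf[s, ] <- shuf[s, ] + .count_lags(.shuffle_train(tr), tg, lag_max)
    }
  }
  list(counts = counts, shuffle_mean = colMeans(shuf),
       shuffle_sd = apply(shuf, 2, sd))
}

.correlogram_result <- function(core, lag_max, trigger_type, n_triggers,
                                same_tetrode, z_crit, post_pre_rule) {
  lags <- -lag_max:lag_max
  sm <- core$shuffle_mean
  ssd <- core$shuffle_sd
  norm_count <- ifelse(sm > 0, core$counts / sm, NA_real_)
  z <- ifelse(ssd > 0, (core$counts - sm) / ssd, 0)
  usable <- lags != 0 | !same_tetrode
  bins <- tibble::tibble(lag = lags, count = core$counts, shuffle_mean = sm,
                         shuffle_sd = ssd, norm_count = norm_count, z = z,
                         usable = usable)
  sig_bins <- abs(z) >= z_crit & lags != 0
  significant <- if (post_pre_rule) {
    sum(sig_bins[lags > 0]) >= sum(sig_bins[lags < 0]) + 2L
  } else {
    sum(sig_bins) >= 2L
  }
  structure(list(bins = bins, significant = significant, z_crit = z_crit,
                 trigger_type = trigger_type, n_triggers = n_triggers,
                 same_tetrode = same_tetrode),
            class = "pcmli_correlogram")
}

#' Spike-triggered cross-correlogram with a shuffle null
#'
#' Aligns target-unit spike times onto every trigger-unit spike within the
#' supplied baseline epochs (1-ms bins over +/-30 ms), normalizes the counts
#' by the mean of `n_shuffles` surrogates in which the trigger train's
#' inter-spike intervals are permuted within each epoch (preserving rate and
#' the ISI marginal while destroying timing), and computes per-bin Z scores.
#' A pair is significantly modulated when at least 2 bins (excluding lag 0)
#' reach `|Z| >= 3.34`, the 95% threshold Bonferroni-corrected over the 60
#' usable bins.
#'
#' For pairs recorded on the same tetrode the lag-0 bin is flagged unusable
#' (coincident waveforms merge during sorting).
#'
#' @param trigger,target Spike-time vectors (ms) or lists of per-epoch
#'   vectors. When plain vectors are given, `epochs` must supply the epoch
#'   bounds used to split them.
#' @param epochs Two-column matrix or list of `c(start, end)` times (ms);
#'   one 10-s pre-trial epoch per trial in the reference protocol.
#' @param n_shuffles Number of ISI-shuffled surrogates (>= 100).
#' @param lag_max Maximum lag (ms).
#' @param same_tetrode Flag the lag-0 bin unusable.
#' @param z_crit Per-bin significance threshold.
#' @return A `pcmli_correlogram`: `bins` tibble (`lag`, `count`,
#'   `shuffle_mean`, `shuffle_sd`, `norm_count`, `z`, `usable`),
#'   `significant`, `trigger_type`, `n_triggers`.
#' @export
spike_triggered_correlogram <- function(trigger, target, epochs = NULL,
                                        n_shuffles = 100, lag_max = 30,
                                        same_tetrode = TRUE, z_crit = 3.34) {
  ep <- .split_epochs(trigger, target, epochs)
  n_trig <- sum(lengths(ep$trigger))
  if (n_trig < 2) {
    stop("insufficient data: fewer than 2 trigger spikes", call. = FALSE)
  }
  core <- .correlogram_core(ep$trigger, ep$target, n_shuffles, lag_max)
  .correlogram_result(core, lag_max, "spike", n_trig, same_tetrode, z_crit,
                      post_pre_rule = FALSE)
}

.split_epochs <- function(trigger, target, epochs) {
  if (is.list(trigger) && is.null(epochs)) {
    stopifnot(is.list(target), length(trigger) == length(target))
    return(list(trigger = trigger, target = target))
  }
  if (is.null(epochs)) {
    return(list(trigger = list(sort(trigger)), target = list(sort(target))))
  }
  if (is.matrix(epochs)) epochs <- asplit(epochs, 1)
  list(
    trigger = lapply(epochs, function(e)
      sort(trigger[trigger >= e[1] & trigger <= e[2]])),
    target = lapply(epochs, function(e)
      sort(target[target >= e[1] & target <= e[2]])))
}

#' Select pause or burst trigger times from inter-spike intervals
#'
#' Pauses are the starts of the largest `percentile` fraction of the trigger
#' train's inter-spike intervals; bursts are the starts of the smallest
#' fraction. The count is `ceiling(percentile x n_isi)`; intervals tied with
#' the threshold interval are all included. A selection that cannot
#' discriminate (every interval selected at `percentile < 1`, as with a
#' constant-ISI train) is an error.
#'
#' @param times Sorted spike times (ms) of one epoch.
#' @param event `"pause"` or `"burst"`.
#' @param percentile Fraction of intervals to select (0.35 for recordings,
#'   0.5 for simulations).
#' @return Times of the spikes that begin the selected intervals.
#' @export
select_isi_events <- function(times, event = c("pause", "burst"),
                              percentile = 0.35) {
  event <- match.arg(event)
  isi <- diff(times)
  if (length(isi) < 1) return(numeric(0))
  k <- ceiling(percentile * length(isi))
  thr <- if (event == "pause") sort(isi, decreasing = TRUE)[k] else
    sort(isi)[k]
  sel <- if (event == "pause") isi >= thr else isi <= thr
  if (all(sel) && percentile < 1) {
    stop("insufficient data: interval percentile cannot discriminate ",
         "(tied inter-spike intervals)", call. = FALSE)
  }
  times[which(sel)]
}

#' Pause- or burst-triggered cross-correlogram
#'
#' Like [spike_triggered_correlogram()] but aligned only to the starts of
#' the largest (`"pause"`) or smallest (`"burst"`) `percentile` fraction of
#' the trigger train's inter-spike intervals. Significance uses the
#' post-versus-pre rule: at least 2 more significant bins after lag 0 than
#' before.
#'
#' @inheritParams spike_triggered_correlogram
#' @param event `"pause"` or `"burst"`.
#' @param percentile Fraction of inter-spike intervals selected.
#' @return A `pcmli_correlogram` with `trigger_type` set to the event.
#' @export
event_triggered_correlogram <- function(trigger, target, event = c("pause",
                                                                   "burst"),
                                        percentile = 0.35, epochs = NULL,
                                        n_shuffles = 100, lag_max = 30,
                                        same_tetrode = TRUE, z_crit = 3.34) {
  event <- match.arg(event)
  ep <- .split_epochs(trigger, target, epochs)
  n_isi <- sum(pmax(lengths(ep$trigger) - 1L, 0L))
  if (n_isi < 10) {
    stop("insufficient data: fewer than 10 inter-spike intervals",
         call. = FALSE)
  }
  ev <- lapply(ep$trigger, function(ts) {
    if (length(ts) < 2) return(numeric(0))
    select_isi_events(ts, event, percentile)
  })
  n_trig <- sum(lengths(ev))
  if (n_trig < 2) {
    stop("insufficient data: fewer than 2 event triggers", call. = FALSE)
  }
  # shuffle permutes the *event-trigger* ISIs within each epoch, as for
  # spike triggers
  core <- .correlogram_core(ev, ep$target, n_shuffles, lag_max)
  .correlogram_result(core, lag_max, event, n_trig, same_tetrode, z_crit,
                      post_pre_rule = TRUE)
}

#' @export
print.pcmli_correlogram <- function(x, ...) {
  cat("<pcmli_correlogram>", x$trigger_type, "-triggered,", x$n_triggers,
      "triggers;", if (x$significant) "SIGNIFICANT" else "not significant",
      sprintf("(|Z| >= %.2f)\n", x$z_crit))
  invisible(x)
}
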