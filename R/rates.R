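# Kernel firing-rate estimation and the PC/MLI normalization conventions.

#' Instantaneous firing rate with a causal (one-sided) Gaussian kernel
#'
#' Each spike contributes a half-Gaussian extending only forward in time
#' (support at and after the spike), normalized to unit area so the rate
#' integral equals the spike count. The one-sided kernel guarantees the
#' estimate at time t depends only on spikes at or before t, preventing
#' US-evoked activity from bleeding backward into the CS period.
#'
#' The kernel peak (at the spike time) is `2/(sigma*sqrt(2*pi))` per ms,
#' i.e. about 31.9 Hz for a single spike at the default 25-ms SD.
#'
#' @param spike_times Numeric spike times (ms), sorted, on the trace clock
#'   (t = 0 is the first sample).
#' @param n_steps Output length (ms).
#' @param kernel_sd Kernel standard deviation (ms).
#' @return A `pcmli_rate`: list with `rate` (Hz, one sample per ms, sample i
#'   is t = i - 1), `kernel_sd`, `normalization` (`"none"`), `normalizer`.
#' @export
instantaneous_rate <- function(spike_times, n_steps, kernel_sd = 25) {
  if (length(spike_times) && is.unsorted(spike_times)) {
    stop("input error: spike times must be sorted", call. = FALSE)
  }
  support <- ceiling(7 * kernel_sd)
  u <- 0:support
  k <- 2 / (kernel_sd * sqrt(2 * pi)) * exp(-u^2 / (2 * kernel_sd^2))
  counts <- tabulate(floor(spike_times) + 1L, n_steps)
  r <- numeric(n_steps)
  if (any(counts > 0)) {
    # causal alignment: contribution of kernel[u] to sample t comes from
    # counts[t - u]
    padded <- c(numeric(support), counts)
    full <- stats::filter(padded, k, method = "convolution", sides = 1)
    r <- as.numeric(full[support + seq_len(n_steps)]) * 1000
    r[r < 0] <- 0
  }
  structure(list(rate = r, kernel_sd = kernel_sd, normalization = "none",
                 normalizer = NA_real_), class = "pcmli_rate")
}

#' @export
print.pcmli_rate <- function(x, ...) {
  cat("<pcmli_rate>", length(x$rate), "ms, kernel sd", x$kernel_sd,
      "ms, normalization:", x$normalization,
      if (x$normalization != "none") sprintf("(normalizer %.3g)", x$normalizer),
      "\n")
  invisible(x)
}

#' @export
as.numeric.pcmli_rate <- function(x, ...) x$rate

#' Normalize a firing-rate trace by cell-type convention
#'
#' Purkinje-cell rates are normalized by the baseline rate over the pre-CS
#' window; MLI rates are normalized to the maximum, during the CS, of the
#' session-averaged rate. The MLI convention prevents cells with the largest
#' CR-related increases (2- to 10-fold over baseline) from dominating
#' population averages: after normalization every MLI's session-average CS
#' peak is 1.
#'
#' @param rate A `pcmli_rate` or numeric rate trace.
#' @param label `"PC"` or `"MLI"`.
#' @param normalizer The normalizing constant: for a PC, its pre-CS baseline
#'   rate (use [pc_baseline_rate()]); for an MLI, the CS maximum of its
#'   session-average rate (use [mli_session_cs_max()]).
#' @return A `pcmli_rate` with dimensionless samples and the normalization
#'   recorded.
#' @export
normalize_rate <- function(rate, label = c("PC", "MLI"), normalizer) {
  label <- match.arg(label)
  if (!is.finite(normalizer) || normalizer == 0) {
    stop("undefined normalization: normalizer is zero or not finite",
         call. = FALSE)
  }
  r <- if (inherits(rate, "pcmli_rate")) rate else
    structure(list(rate = as.numeric(rate), kernel_sd = NA_real_,
                   normalization = "none", normalizer = NA_real_),
              class = "pcmli_rate")
  r$rate <- r$rate / normalizer
  r$normalization <- if (label == "PC") "pc_baseline" else "mli_cs_max"
  r$normalizer <- normalizer
  r
}

#' Baseline firing rate of a PC over its pre-CS window
#'
#' @param rate A `pcmli_rate` or numeric trace for one trial.
#' @param cs_onset CS onset (ms from trace start).
#' @param window Baseline window length (ms); the convention is 1500 ms of
#'   pre-CS activity, shortened automatically when less is recorded.
#' @return Mean rate (Hz).
#' @export
pc_baseline_rate <- function(rate, cs_onset, window = 1500) {
  r <- if (inherits(rate, "pcmli_rate")) rate$rate else as.numeric(rate)
  i0 <- max(1, cs_onset - window + 1)
  mean(r[i0:cs_onset])
}

#' CS maximum of an MLI's session-averaged rate
#'
#' @param rates List of per-trial rate traces (`pcmli_rate` or numeric),
#'   aligned on the trial clock.
#' @param cs_onset,cs_end CS window (ms from trace start).
#' @return The maximum of the across-trial mean rate within the CS (Hz).
#' @export
mli_session_cs_max <- function(rates, cs_onset, cs_end) {
  m <- vapply(rates, function(r)
    (if (inherits(r, "pcmli_rate")) r$rate else as.numeric(r)),
    numeric(length(if (inherits(rates[[1]], "pcmli_rate")) rates[[1]]$rate
                   else rates[[1]])))
  avg <- rowMeans(m)
  max(avg[(cs_onset + 1):min(cs_end, length(avg))])
}

#' Convenience unit-type heuristic (non-canonical)
#'
#' Cell identities are inputs to every analysis in this package: in
#' recordings they come from waveform-based classification during sorting,
#' which is out of scope here. This helper only captures the coarse rule of
#' thumb used at recording time — a unit is called a putative PC when its
#' baseline rate exceeds 40 Hz and complex spikes were observed — and is no
#' substitute for the canonical classifier.
#'
#' @param baseline_hz Baseline firing rate (Hz).
#' @param has_complex_spikes Logical: complex spikes confirmed for the unit.
#' @return `"PC"` or `"MLI"`.
#' @export
classify_unit_heuristic <- function(baseline_hz, has_complex_spikes) {
  ifelse(baseline_hz > 40 & has_complex_spikes, "PC", "MLI")
}
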