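# Eyelid-trace processing: low-pass filtering, CR amplitude, criterion
# latency, two-step CR-onset detection and velocity. Applied identically to
# recorded and virtual (simulated) eyelid traces. Traces are sampled at
# 1 kHz; sample i corresponds to t = i - 1 ms.

#' Low-pass filter an eyelid position trace
#'
#' Zero-phase (forward-backward) Butterworth filter. Eyelid kinematics live
#' below ~20 Hz, so the default 4th-order, 50-Hz-cutoff filter removes
#' sensor noise without distorting response onsets; being zero-phase it adds
#' no latency bias.
#'
#' @param raw Numeric trace (mm) at 1 kHz.
#' @param cutoff_hz Cutoff frequency (Hz).
#' @param order Filter order.
#' @param fs Sampling rate (Hz), fixed at 1000.
#' @param expected_length If given, the input length is validated against it
#'   (recorded trials are 2500 ms: 200 ms pre-CS, 2300 ms post-CS).
#' @return Filtered numeric trace.
#' @export
preprocess_eyelid <- function(raw, cutoff_hz = 50, order = 4, fs = 1000,
                              expected_length = NULL) {
  if (!is.null(expected_length) && length(raw) != expected_length) {
    stop("input error: trace has length ", length(raw), ", expected ",
         expected_length, call. = FALSE)
  }
  if (length(raw) < 3 * (order + 1)) {
    stop("input error: trace too short to filter", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, raw))
}

#' Truncate an eyelid trace at US onset
#'
#' Returns the samples strictly before US onset, excluding the reflexive
#' (non-cerebellar) response to the US itself from CR analysis.
#'
#' @param trace Numeric trace; sample i is t = i - 1 ms.
#' @param us_onset US-onset time (ms from trace start).
#' @return The truncated trace (t = 0 .. us_onset - 1).
#' @export
truncate_at_us <- function(trace, us_onset) {
  stopifnot(us_onset >= 1, us_onset <= length(trace))
  trace[seq_len(us_onset)]
}

#' Conditioned-response measures for one trial
#'
#' Baseline is the mean of the pre-CS segment. CR amplitude is eyelid
#' position relative to baseline at the time of US onset; a trial is a CR
#' when the response reaches the 0.3-mm criterion before US onset.
#' Criterion latency is the first crossing of baseline + 0.3 mm within the
#' CS. Onset latency uses a two-step algorithm: (1) find the first sample in
#' the CS exceeding baseline + `onset_k_sd` pre-CS standard deviations and
#' staying above for `onset_sustain` ms; (2) fit a line to the
#' `onset_fit` ms after that sample and report where it crosses the
#' baseline.
#'
#' @param trace Numeric eyelid trace (mm); sample i is t = i - 1 ms.
#' @param cs_onset CS-onset time (ms from trace start; 200 for recorded
#'   trials).
#' @param us_onset US-onset time (ms from trace start).
#' @param criterion_mm CR criterion (mm).
#' @param onset_k_sd,onset_sustain,onset_fit Two-step onset parameters.
#' @param already_filtered Set when the trace needs no low-pass step
#'   (virtual eyelid traces are already smooth).
#' @return One-row tibble: `is_cr`, `amplitude_mm`, `criterion_ms`,
#'   `onset_ms` (latencies in ms from CS onset; NA when not a CR),
#'   `baseline_mm`.
#' @export
#' @examples
#' x <- c(rep(0, 500), 0.01 * seq_len(300)) # ramp from 300 ms post-CS
#' cr_measures(x, cs_onset = 200, us_onset = 700, already_filtered = TRUE)
cr_measures <- function(trace, cs_onset = 200, us_onset, criterion_mm = 0.3,
                        onset_k_sd = 4, onset_sustain = 20, onset_fit = 20,
                        already_filtered = FALSE) {
  if (!already_filtered) trace <- preprocess_eyelid(trace)
  stopifnot(cs_onset >= 1, us_onset > cs_onset)
  pre <- trace[seq_len(cs_onset)]
  base <- mean(pre)
  i_us <- min(us_onset + 1, length(trace))
  amplitude <- trace[i_us] - base
  cs_idx <- (cs_onset + 1):min(us_onset, length(trace)) # t in [cs, us)
  is_cr <- max(trace[cs_idx]) - base >= criterion_mm

  criterion_ms <- NA_real_
  onset_ms <- NA_real_
  if (is_cr) {
    cross <- which(trace[cs_idx] - base >= criterion_mm)[1]
    criterion_ms <- (cs_idx[cross] - 1) - cs_onset
    thr <- base + onset_k_sd * sd(pre)
    above <- trace[cs_idx] > thr
    run <- rle(above)
    ends <- cumsum(run$lengths)
    cand <- which(run$values & run$lengths >= onset_sustain)
    if (length(cand)) {
      i0 <- cs_idx[ends[cand[1]] - run$lengths[cand[1]] + 1] # first sustained sample
      seg <- i0:min(i0 + onset_fit - 1, length(trace))
      tt <- seg - 1
      fit <- lm(trace[seg] ~ tt)
      b <- coef(fit)
      onset_ms <- if (abs(b[2]) > 1e-12) (base - b[1]) / b[2] - cs_onset else
        (i0 - 1) - cs_onset
      onset_ms <- min(max(onset_ms, 0), criterion_ms)
    } else {
      onset_ms <- criterion_ms
    }
  }
  tibble::tibble(is_cr = is_cr, amplitude_mm = amplitude,
                 criterion_ms = criterion_ms, onset_ms = onset_ms,
                 baseline_mm = base)
}

#' Eyelid velocity
#'
#' Centered finite difference scaled to mm/s; one-sided at the endpoints.
#'
#' @param trace Numeric eyelid trace (mm) at `fs` Hz.
#' @param fs Sampling rate (Hz).
#' @return Numeric velocity trace (mm/s), same length.
#' @export
eyelid_velocity <- function(trace, fs = 1000) {
  n <- length(trace)
  if (n < 3) stop("input error: trace too short", call. = FALSE)
  v <- numeric(n)
  v[2:(n - 1)] <- (trace[3:n] - trace[1:(n - 2)]) / 2 * fs
  v[1] <- (trace[2] - trace[1]) * fs
  v[n] <- (trace[n] - trace[n - 1]) * fs
  v
}
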