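# In vitro quantitative analyses: IPSC-train depression kinetics, cumulative
# charge RRP/mobilization estimation, quantal metrics, and IPSC detection
# with latency and rise time.

#' Construct an IPSC-train record
#'
#' @param frequency Stimulus frequency (Hz).
#' @param amplitude Per-stimulus IPSC amplitudes (pA, magnitudes >= 0).
#' @param charge Per-stimulus IPSC charges (pC); defaults to amplitudes
#'   scaled by a 10-ms decay if absent.
#' @param times Stimulus times (ms); defaults to regular spacing at
#'   `frequency`.
#' @param holding_mV,reversal_mV Holding and reversal potentials (mV).
#' @return A `pcmli_ipsc_train` tibble with columns `stim`, `t_ms`,
#'   `amplitude_pA`, `charge_pC`.
#' @export
ipsc_train <- function(frequency, amplitude, charge = NULL, times = NULL,
                       holding_mV = -40, reversal_mV = -74) {
  n <- length(amplitude)
  if (any(amplitude < 0)) {
    stop("input error: amplitudes are magnitudes (>= 0)", call. = FALSE)
  }
  if (is.null(times)) times <- (seq_len(n) - 1) * 1000 / frequency
  if (is.null(charge)) charge <- amplitude * 10 * 1e-3 # pA * ms -> pC
  out <- tibble::tibble(stim = seq_len(n), t_ms = times,
                        amplitude_pA = amplitude, charge_pC = charge)
  attr(out, "frequency") <- frequency
  attr(out, "holding_mV") <- holding_mV
  attr(out, "reversal_mV") <- reversal_mV
  class(out) <- c("pcmli_ipsc_train", class(out))
  out
}

#' Fit the time course of synaptic depression in an IPSC train
#'
#' Amplitudes are normalized to the first IPSC and fit with a single
#' exponential decaying to a plateau, `a(t) = ss + (1 - ss) exp(-t / tau)`.
#' A train with no measurable depression returns the plateau with the time
#' constant flagged unidentifiable.
#'
#' @param train A `pcmli_ipsc_train` with at least 20 stimuli.
#' @return A `pcmli_depression`: list with `tau_ms`, `plateau` (steady-state
#'   normalized amplitude), `frequency`, `converged`,
#'   `tau_identifiable`, `residual_sd`, `fitted` tibble.
#' @export
fit_depression_train <- function(train) {
  stopifnot(inherits(train, "pcmli_ipsc_train"))
  if (nrow(train) < 20) {
    stop("input error: at least 20 stimuli required", call. = FALSE)
  }
  a <- train$amplitude_pA / train$amplitude_pA[1]
  t <- train$t_ms - train$t_ms[1]
  freq <- attr(train, "frequency")
  if (diff(range(a)) < 0.02) {
    return(structure(list(tau_ms = NA_real_, plateau = mean(a),
                          frequency = freq, converged = TRUE,
                          tau_identifiable = FALSE,
                          residual_sd = sd(a),
                          fitted = tibble::tibble(t_ms = t, norm = a,
                                                  fit = mean(a))),
                     class = "pcmli_depression"))
  }
  ss0 <- mean(a[(length(a) - 4):length(a)])
  tau0 <- max(t[which(a - ss0 <= (1 - ss0) * exp(-1))[1]], 1000 / freq)
  fit <- tryCatch(
    nls(a ~ ss + (1 - ss) * exp(-t / tau),
        start = list(ss = ss0, tau = tau0),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(a ~ ss + (1 - ss) * exp(-t / tau),
                        start = list(ss = ss0, tau = tau0)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    stop("non-convergent depression fit; residual trace in message: ",
         paste(round(a, 3), collapse = " "), call. = FALSE)
  }
  cf <- coef(fit)
  structure(list(tau_ms = unname(cf["tau"]), plateau = unname(cf["ss"]),
                 frequency = freq, converged = TRUE, tau_identifiable = TRUE,
                 residual_sd = sd(residuals(fit)),
                 fitted = tibble::tibble(t_ms = t, norm = a,
                                         fit = fitted(fit))),
            class = "pcmli_depression")
}

#' @export
print.pcmli_depression <- function(x, ...) {
  cat("<pcmli_depression>", attr(x, "frequency"),
      sprintf("plateau %.3f, tau %s ms (%d Hz)\n", x$plateau,
              if (x$tau_identifiable) sprintf("%.1f", x$tau_ms) else
                "unidentifiable", x$frequency))
  invisible(x)
}

#' Steady-state depression across stimulation frequencies
#'
#' Regresses the steady-state (plateau) normalized amplitude on frequency
#' and tests the slope against zero (F-test); frequency independence of the
#' plateau shows as a non-significant slope. Steady-state charge transfer
#' (plateau x frequency) is fitted the same way: when the plateau is flat,
#' charge transfer rises linearly with frequency.
#'
#' @param fits List of `pcmli_depression` objects (or numeric plateaus).
#' @param frequencies Stimulus frequencies (Hz); taken from the fits when
#'   omitted.
#' @return List with `table` (tibble `frequency`, `plateau`,
#'   `charge_transfer`), `slope`, `slope_p` (F-test), `charge_slope`,
#'   `charge_slope_p`.
#' @export
steady_state_analysis <- function(fits, frequencies = NULL) {
  plateau <- vapply(fits, function(f)
    if (inherits(f, "pcmli_depression")) f$plateau else as.numeric(f), 1)
  if (length(plateau) < 3) {
    stop("input error: at least 3 frequencies required", call. = FALSE)
  }
  if (is.null(frequencies)) {
    frequencies <- vapply(fits, function(f) f$frequency, 1)
  }
  tab <- tibble::tibble(frequency = frequencies, plateau = plateau,
                        charge_transfer = plateau * frequencies)
  m1 <- lm(plateau ~ frequency, data = tab)
  m2 <- lm(charge_transfer ~ frequency, data = tab)
  p_of <- function(m) {
    a <- anova(m)
    a[["Pr(>F)"]][1]
  }
  list(table = tab, slope = unname(coef(m1)[2]), slope_p = p_of(m1),
       charge_slope = unname(coef(m2)[2]), charge_slope_p = p_of(m2))
}

#' Estimate the readily releasable pool from cumulative synaptic charge
#'
#' Plots cumulative IPSC charge against stimulus number and fits the final
#' 20 points by ordinary least squares: the y-intercept estimates the RRP
#' charge (the pool released beyond steady-state mobilization) and the slope
#' the mobilization rate per stimulus; division by the mean quantal charge
#' converts both to quanta, and multiplying the slope by the stimulus
#' frequency gives mobilization per second.
#'
#' @param train A `pcmli_ipsc_train` with at least 40 stimuli (so the last
#'   20 lie on the linear tail).
#' @param mean_quantal_charge Mean spontaneous-event charge (pC).
#' @param n_tail Number of tail points fitted.
#' @return A `pcmli_pool`: list with `rrp_pc`, `rrp_quanta`,
#'   `mobilization_pc_per_stim`, `mobilization_quanta_per_s`, `r_squared`,
#'   `cumulative` tibble, `fit` (the `lm`).
#' @export
estimate_pool <- function(train, mean_quantal_charge = NULL, n_tail = 20) {
  stopifnot(inherits(train, "pcmli_ipsc_train"))
  if (nrow(train) < 2 * n_tail) {
    stop("input error: at least ", 2 * n_tail, " stimuli required",
         call. = FALSE)
  }
  cum <- tibble::tibble(stim = train$stim, cum_charge = cumsum(train$charge_pC))
  tail_idx <- (nrow(cum) - n_tail + 1):nrow(cum)
  fit <- lm(cum_charge ~ stim, data = cum[tail_idx, ])
  rrp_pc <- unname(coef(fit)[1])
  slope <- unname(coef(fit)[2])
  freq <- attr(train, "frequency")
  structure(list(
    rrp_pc = rrp_pc,
    rrp_quanta = if (is.null(mean_quantal_charge)) NA_real_ else
      rrp_pc / mean_quantal_charge,
    mobilization_pc_per_stim = slope,
    mobilization_quanta_per_s = if (is.null(mean_quantal_charge)) NA_real_
      else slope / mean_quantal_charge * freq,
    frequency = freq,
    r_squared = summary(fit)$r.squared, cumulative = cum, fit = fit),
    class = "pcmli_pool")
}

#' @export
print.pcmli_pool <- function(x, ...) {
  cat(sprintf("<pcmli_pool> RRP %.1f pC", x$rrp_pc))
  if (is.finite(x$rrp_quanta)) cat(sprintf(" (%.1f quanta)", x$rrp_quanta))
  cat(sprintf("; mobilization %.2f pC/stimulus", x$mobilization_pc_per_stim))
  if (is.finite(x$mobilization_quanta_per_s)) {
    cat(sprintf(" (%.1f quanta/s at %g Hz)", x$mobilization_quanta_per_s,
                x$frequency))
  }
  cat("\n")
  invisible(x)
}

#' Quantal metrics of unitary transmission
#'
#' Quantal content is the ratio of evoked to spontaneous (miniature) IPSC
#' amplitude; release probability is the integral-based quantal content
#' divided by the RRP size in quanta; synaptic conductance is amplitude over
#' driving force; the coefficient of variation comes from repeated evoked
#' amplitudes when supplied.
#'
#' @param evoked_amp Mean evoked IPSC amplitude (pA).
#' @param spont_amp Mean spontaneous IPSC amplitude (pA, > 0).
#' @param evoked_integral_qc Quantal content computed on the IPSC integral
#'   basis (captures asynchronous release).
#' @param rrp_quanta RRP size (quanta).
#' @param holding_mV,reversal_mV Potentials (mV); must differ.
#' @param repeated_evoked Optional vector of repeated evoked amplitudes.
#' @return One-row tibble: `quantal_content`, `release_probability`,
#'   `conductance_nS`, `cv`.
#' @export
#' @examples
#' quantal_metrics(evoked_amp = 39.1, spont_amp = 18,
#'                 evoked_integral_qc = 6.7, rrp_quanta = 99,
#'                 holding_mV = -40)
quantal_metrics <- function(evoked_amp, spont_amp, evoked_integral_qc = NA,
                            rrp_quanta = NA, holding_mV, reversal_mV = -74,
                            repeated_evoked = NULL) {
  if (spont_amp <= 0) stop("input error: spont_amp must be > 0", call. = FALSE)
  if (holding_mV == reversal_mV) {
    stop("input error: holding equals reversal potential", call. = FALSE)
  }
  tibble::tibble(
    quantal_content = evoked_amp / spont_amp,
    release_probability = evoked_integral_qc / rrp_quanta,
    conductance_nS = evoked_amp / abs(holding_mV - reversal_mV),
    cv = if (is.null(repeated_evoked)) NA_real_ else
      sd(repeated_evoked) / mean(repeated_evoked))
}

#' Detect an IPSC in a post-flash current record
#'
#' An IPSC is detected when the current peak between 4 and 24 ms after the
#' light flash reaches the 15-pA minimum. Onset time is the zero crossing of
#' the line joining the 20% and 80% points of the rising phase; rise time is
#' the 20-80% interval.
#'
#' @param time_ms Sample times (ms, relative to the record start).
#' @param current_pA Current samples (pA, IPSC magnitude positive).
#' @param flash_ms Flash time (ms).
#' @param threshold_pA Detection threshold (pA).
#' @param window_ms Detection window after the flash (ms).
#' @return One-row tibble: `detected`, `amplitude_pA`, `peak_ms`,
#'   `latency_ms` (flash to onset), `rise_time_ms` (20-80%).
#' @export
detect_ipsc <- function(time_ms, current_pA, flash_ms = 0, threshold_pA = 15,
                        window_ms = c(4, 24)) {
  none <- tibble::tibble(detected = FALSE, amplitude_pA = NA_real_,
                         peak_ms = NA_real_, latency_ms = NA_real_,
                         rise_time_ms = NA_real_)
  win <- which(time_ms >= flash_ms + window_ms[1] &
               time_ms <= flash_ms + window_ms[2])
  if (!length(win)) return(none)
  pk <- win[which.max(current_pA[win])]
  amp <- current_pA[pk]
  if (amp < threshold_pA) return(none)
  # rising-phase 20% and 80% crossings before the peak (linear interpolation)
  cross_t <- function(frac) {
    lvl <- frac * amp
    below <- which(current_pA[seq_len(pk)] < lvl)
    if (!length(below)) return(time_ms[1])
    i <- max(below)
    if (i == pk) return(time_ms[pk])
    t0 <- time_ms[i]; t1 <- time_ms[i + 1]
    y0 <- current_pA[i]; y1 <- current_pA[i + 1]
    t0 + (lvl - y0) / (y1 - y0) * (t1 - t0)
  }
  t20 <- cross_t(0.2); t80 <- cross_t(0.8)
  onset <- t20 - (t80 - t20) / 3 # zero crossing of the 20-80% line
  tibble::tibble(detected = TRUE, amplitude_pA = amp,
                 peak_ms = time_ms[pk] - flash_ms,
                 latency_ms = onset - flash_ms, rise_time_ms = t80 - t20)
}
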