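# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.pcmli_mixture <- function(x, ...) {
  if (x$degenerate && length(x$means) < 2) {
    return(tibble::tibble(component = integer(0), mean = numeric(0),
                          sd = numeric(0), weight = numeric(0)))
  }
  tibble::tibble(component = c(1L, 2L), mean = x$means, sd = x$sds,
                 weight = x$weights)
}

#' @export
glance.pcmli_mixture <- function(x, ...) {
  tibble::tibble(skewness = x$skewness, cutoff = x$cutoff, level = x$level,
                 bic_1 = x$bic_1, bic_2 = x$bic_2, bimodal = x$bimodal,
                 degenerate = x$degenerate,
                 n = if (is.null(x$classification)) NA_integer_ else
                   nrow(x$classification))
}

#' @export
tidy.pcmli_pool <- function(x, ...) {
  tibble::tibble(
    quantity = c("rrp_pc", "rrp_quanta", "mobilization_pc_per_stim",
                 "mobilization_quanta_per_s"),
    value = c(x$rrp_pc, x$rrp_quanta, x$mobilization_pc_per_stim,
              x$mobilization_quanta_per_s))
}

#' @export
glance.pcmli_pool <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, frequency = x$frequency,
                 n_points = nrow(x$cumulative))
}

#' @export
tidy.pcmli_depression <- function(x, ...) {
  tibble::tibble(term = c("tau_ms", "plateau"),
                 estimate = c(x$tau_ms, x$plateau))
}

#' @export
glance.pcmli_depression <- function(x, ...) {
  tibble::tibble(frequency = x$frequency, converged = x$converged,
                 tau_identifiable = x$tau_identifiable,
                 residual_sd = x$residual_sd)
}

#' @export
tidy.pcmli_correlogram <- function(x, ...) x$bins

#' @export
glance.pcmli_correlogram <- function(x, ...) {
  tibble::tibble(trigger_type = x$trigger_type, n_triggers = x$n_triggers,
                 significant = x$significant, z_crit = x$z_crit)
}

#' @export
tidy.pcmli_correlation <- function(x, ...) x$per_trial

#' @export
glance.pcmli_correlation <- function(x, ...) {
  tibble::tibble(mean_r = x$mean_r, n_cr = x$n_cr,
                 n_excluded = x$n_excluded)
}

#' @export
tidy.pcmli_training <- function(x, ...) x$sessions

#' @export
glance.pcmli_training <- function(x, ...) {
  last <- x$sessions[nrow(x$sessions), ]
  tibble::tibble(isi = x$isi, n_sessions = nrow(x$sessions),
                 feedback = x$config$feedback_enabled,
                 final_cr_rate = last$cr_rate,
                 final_cr_amplitude = last$mean_cr_amplitude)
}

#' @export
autoplot.pcmli_correlogram <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$lag,
                                            y = .data$norm_count)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "lag (ms)", y = "normalized spike count",
                  title = paste0(object$trigger_type, "-triggered correlogram",
                                 if (object$significant) " (significant)")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pcmli_mixture <- function(object, ...) {
  cl <- object$classification
  grid <- seq(-1, 1, length.out = 400)
  dens <- tibble::tibble(
    r = rep(grid, 2),
    component = rep(c("low", "high"), each = length(grid)),
    density = c(object$weights[1] * dnorm(grid, object$means[1], object$sds[1]),
                object$weights[2] * dnorm(grid, object$means[2], object$sds[2])))
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            binwidth = 0.05, fill = "grey80",
                            colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "correlation with CR", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pcmli_training <- function(object, ...) {
  ggplot2::ggplot(object$sessions,
                  ggplot2::aes(x = .data$session,
                               y = .data$mean_cr_amplitude)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "session", y = "mean CR amplitude (mm)",
                  title = sprintf("Acquisition at ISI %d ms (feedback %s)",
                                  object$isi,
                                  if (object$config$feedback_enabled) "on"
                                  else "off")) +
    ggplot2::theme_minimal()
}

#' Plot one trial's virtual eyelid trace
#'
#' @param record A trial record from [run_trial()]/[run_session()].
#' @return A ggplot object.
#' @export
plot_trial_eyelid <- function(record) {
  tr <- record$trial
  d <- tibble::tibble(t = seq_along(record$eyelid) - 1 - tr$cs_onset,
                      eyelid = as.numeric(record$eyelid))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$eyelid)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from CS onset (ms)", y = "virtual eyelid (mm)") +
    ggplot2::theme_minimal()
  if (tr$type == "paired") {
    p <- p + ggplot2::geom_vline(xintercept = tr$isi, linetype = 3,
                                 colour = "red")
  }
  p
}
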