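# Lead-lag quantification (fraction of the full PC decrease / MLI increase
# completed before CR onset) and trial grouping by CR onset or amplitude.

#' Pre-CR fraction of the full PC decrease and MLI increase
#'
#' On a CR trial, measures for the PC the fraction of its full rate decrease
#' — baseline to the minimum within `[onset, onset + window]` — that occurred
#' by CR onset, and for the MLI the fraction of its full rate increase
#' (baseline to maximum in the same window). A value of 0 means no change
#' before CR onset; 1 means the maximal change happened before onset.
#' `difference` = dPC - dMLI: positive when the PC leads.
#'
#' The post-onset window is 100 ms at ISI 250 and 150 ms at ISIs 500-750.
#' Trials whose CR onset is so late that the window would run past US onset
#' are excluded (US-evoked activity would contaminate the extrema).
#'
#' @param pc_rate,mli_rate Per-trial rate traces (`pcmli_rate` or numeric),
#'   sample i = t = i - 1 ms on the trial clock.
#' @param cr_onset CR onset (ms from CS onset).
#' @param isi Interstimulus interval (ms).
#' @param cs_onset CS onset (ms from trace start).
#' @param window Post-onset window (ms); default chosen from `isi`.
#' @return One-row tibble: `delta_pc`, `delta_mli`, `difference`,
#'   `window_ms`, `excluded`, `reason`.
#' @export
pre_cr_fraction <- function(pc_rate, mli_rate, cr_onset, isi, cs_onset = 200,
                            window = if (isi <= 250) 100 else 150) {
  skip <- function(reason) tibble::tibble(
    delta_pc = NA_real_, delta_mli = NA_real_, difference = NA_real_,
    window_ms = window, excluded = TRUE, reason = reason)
  if (!is.finite(cr_onset)) return(skip("no CR onset"))
  if (cr_onset + window > isi) return(skip("onset too close to US"))
  pc <- if (inherits(pc_rate, "pcmli_rate")) pc_rate$rate else
    as.numeric(pc_rate)
  mli <- if (inherits(mli_rate, "pcmli_rate")) mli_rate$rate else
    as.numeric(mli_rate)
  i_on <- cs_onset + round(cr_onset) + 1L
  i_end <- min(cs_onset + round(cr_onset + window) + 1L, length(pc))
  base_pc <- mean(pc[seq_len(cs_onset)])
  base_mli <- mean(mli[seq_len(cs_onset)])
  full_dec <- base_pc - min(pc[i_on:i_end])
  full_inc <- max(mli[i_on:i_end]) - base_mli
  if (full_dec <= 0 || full_inc <= 0) return(skip("no change in window"))
  d_pc <- (base_pc - pc[i_on]) / full_dec
  d_mli <- (mli[i_on] - base_mli) / full_inc
  d_pc <- min(max(d_pc, 0), 1)
  d_mli <- min(max(d_mli, 0), 1)
  tibble::tibble(delta_pc = d_pc, delta_mli = d_mli,
                 difference = d_pc - d_mli, window_ms = window,
                 excluded = FALSE, reason = NA_character_)
}

#' Divide CR trials into equal subgroups by onset or amplitude
#'
#' Sorts CR trials by the chosen key and splits them into `n_groups`
#' equal-count subgroups (any remainder goes to the last group); non-CR
#' trials form their own group. For every list-column of per-trial traces in
#' `data`, per-group pointwise means with 95% confidence intervals are
#' returned.
#'
#' @param data Tibble with one row per trial: logical `is_cr`, the key
#'   column, and optionally list-columns of numeric traces (eyelid, unit
#'   rates) to average.
#' @param key `"cr_onset"` or `"cr_amplitude"`, or the name of any numeric
#'   column.
#' @param n_groups Number of CR subgroups.
#' @return A tibble with one row per group: `group`, `n`, `key_min`,
#'   `key_max`, and for each trace column `<col>_mean`, `<col>_lo`,
#'   `<col>_hi` list-columns.
#' @export
group_trials <- function(data, key = c("cr_onset", "cr_amplitude"),
                         n_groups = 3) {
  key <- if (length(key) > 1) match.arg(key) else key
  key_col <- switch(key, cr_onset = "onset_ms", cr_amplitude = "amplitude_mm",
                    key)
  stopifnot(key_col %in% names(data), "is_cr" %in% names(data))
  cr <- data[data$is_cr & is.finite(data[[key_col]]), ]
  if (nrow(cr) < n_groups) {
    stop("input error: fewer CR trials than groups", call. = FALSE)
  }
  cr <- cr[order(cr[[key_col]]), ]
  base_n <- nrow(cr) %/% n_groups
  sizes <- rep(base_n, n_groups)
  sizes[n_groups] <- sizes[n_groups] + nrow(cr) %% n_groups
  cr$group <- rep(paste0("G", seq_len(n_groups)), times = sizes)
  non_cr <- data[!data$is_cr, ]
  if (nrow(non_cr)) non_cr$group <- "non_cr"
  all_tr <- dplyr::bind_rows(cr, non_cr)

  trace_cols <- names(data)[vapply(data, is.list, TRUE)]
  summarize_group <- function(g) {
    rows <- all_tr[all_tr$group == g, ]
    out <- tibble::tibble(
      group = g, n = nrow(rows),
      key_min = if (g == "non_cr") NA_real_ else min(rows[[key_col]]),
      key_max = if (g == "non_cr") NA_real_ else max(rows[[key_col]]))
    for (tc in trace_cols) {
      m <- do.call(cbind, lapply(rows[[tc]], as.numeric))
      mu <- rowMeans(m)
      se <- apply(m, 1, sd) / sqrt(ncol(m))
      out[[paste0(tc, "_mean")]] <- list(mu)
      out[[paste0(tc, "_lo")]] <- list(mu - 1.96 * se)
      out[[paste0(tc, "_hi")]] <- list(mu + 1.96 * se)
    }
    out
  }
  purrr::map_dfr(unique(all_tr$group), summarize_group)
}
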