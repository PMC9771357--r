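# Plain-text readers/writers for the formats the analysis stack exchanges.

#' Read or write spike tables
#'
#' Spike CSVs have columns `unit_id`, `trial_id` (or `"baseline"`), `t_ms`.
#'
#' @param spikes Tibble with columns `unit_id`, `trial_id`, `t_ms`.
#' @param path CSV path.
#' @return `read_spike_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  stopifnot(all(c("unit_id", "trial_id", "t_ms") %in% names(spikes)))
  utils::write.csv(spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @export
read_spike_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read or write per-trial eyelid traces
#'
#' Eyelid CSVs have columns `t_ms`, `position_mm` (one trial per file) or
#' additionally `trial_id`.
#'
#' @param trace Numeric eyelid trace (sample i = t = i - 1 ms) or tibble.
#' @param path CSV path.
#' @return `read_eyelid_csv()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_eyelid_csv <- function(trace, path) {
  d <- if (is.data.frame(trace)) trace else
    tibble::tibble(t_ms = seq_along(trace) - 1,
                   position_mm = as.numeric(trace))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_eyelid_csv
#' @export
read_eyelid_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a granule-to-PC weight snapshot
#'
#' Columns: `synapse_id`, `pre_idx` (granule cell), `post_idx` (PC),
#' `weight`; 0-based indices.
#'
#' @param network A `pcmli_network`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_weight_snapshot <- function(network, path) {
  p <- network$projections$grc_pc
  utils::write.csv(
    tibble::tibble(synapse_id = seq_along(p$src) - 1L, pre_idx = p$src - 1L,
                   post_idx = p$tgt - 1L, weight = p$weight),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write IPSC-train tables
#'
#' Columns: `stim_idx`, `t_ms`, `amplitude_pA`, `charge_pC`; the frequency
#' travels in a `# frequency_hz:` header comment.
#'
#' @param train A `pcmli_ipsc_train`.
#' @param path CSV path.
#' @return `read_ipsc_csv()` returns a `pcmli_ipsc_train`; writers return
#'   `path` invisibly.
#' @export
write_ipsc_csv <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frequency_hz: %g", attr(train, "frequency")), con)
  utils::write.csv(
    tibble::tibble(stim_idx = train$stim - 1L, t_ms = train$t_ms,
                   amplitude_pA = train$amplitude_pA,
                   charge_pC = train$charge_pC),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ipsc_csv
#' @export
read_ipsc_csv <- function(path) {
  first <- readLines(path, n = 1)
  freq <- as.numeric(sub("# frequency_hz: ", "", first, fixed = TRUE))
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ipsc_train(freq, d$amplitude_pA, charge = d$charge_pC, times = d$t_ms)
}

#' Write a correlogram result as CSV
#'
#' Columns: `lag_ms`, `count`, `norm_count`, `z`.
#'
#' @param correlogram A `pcmli_correlogram`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_correlogram_csv <- function(correlogram, path) {
  b <- correlogram$bins
  utils::write.csv(
    tibble::tibble(lag_ms = b$lag, count = b$count,
                   norm_count = b$norm_count, z = b$z),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
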