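# Desk-scale training battery shared by the acceptance checks: a 1/6-scale
# granule sheet (2,000 granule cells), 10 sessions of 108 trials, feedback
# on vs off, at ISI 500 (correlation / lead-lag / weight-change analyses)
# and ISI 150 (learning-benefit comparison). Run once and cached.

.battery_env <- new.env(parent = emptyenv())

acceptance_battery <- function() {
  if (!is.null(.battery_env$res)) return(.battery_env$res)
  runs <- list()
  for (fb in c(TRUE, FALSE)) {
    key <- if (fb) "on" else "off"
    cfg <- sim_config(seed = 11, scale_factor = 1 / 6, feedback_enabled = fb)
    runs[[paste0("isi500_", key)]] <-
      run_training(cfg, n_sessions = 10, isi = 500, seed = 21)
    runs[[paste0("isi150_", key)]] <-
      run_training(cfg, n_sessions = 10, isi = 150, seed = 22,
                   keep_last_records = FALSE)
  }
  res <- list(
    runs = runs,
    corr_on = mli_cr_correlations(runs$isi500_on),
    corr_off = mli_cr_correlations(runs$isi500_off),
    leadlag = leadlag_distribution(runs$isi500_on)
  )
  .battery_env$res <- res
  res
}
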