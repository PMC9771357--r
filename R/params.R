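#' Default neuron parameters for each simulated population
#'
#' Each simulated cell is a conductance-based point neuron on a 1 ms clock:
#' membrane potential relaxes toward the leak reversal and is pushed by
#' per-afferent synaptic conductances, a spike is emitted when potential
#' crosses an adaptive threshold, the potential is reset to the leak reversal
#' and the threshold jumps by `d_theta` before decaying back to `theta0` with
#' time constant `tau_theta`. Capacitance is folded into the conductance
#' scale, so conductances are expressed in 1/ms units.
#'
#' Purkinje and deep-nucleus cells are intrinsic pacemakers: their leak
#' reversal sits above the baseline threshold, so they fire tonically at a
#' rate set by the threshold-decay time constant, as these cells do in vivo.
#' Granule cells, Golgi cells and molecular-layer interneurons are driven
#' cells whose leak reversal sits below threshold.
#'
#' Numerical values are this package's calibration: physiology constrains the
#' target firing behavior (Purkinje simple-spike baselines of tens of Hz,
#' sparse granule activity, tonically active nuclear cells) rather than the
#' constants themselves, so these were tuned once to land in those bands and
#' then frozen.
#'
#' @return Named list of per-population parameter lists. Each entry has
#'   `e_leak`, `g_leak`, `theta0`, `d_theta`, `tau_theta`, `e_reset` (mV and
#'   1/ms units) and a `slots` list of afferent conductance definitions, each
#'   with `tau` (ms), `e` (reversal, mV) and `gain` (conductance increment per
#'   presynaptic spike).
#' @export
#' @examples
#' p <- default_neuron_params()
#' names(p)
#' p$pc$slots$pf
default_neuron_params <- function() {
  list(
    grc = list(
      e_leak = -70, g_leak = 0.10, theta0 = -48, d_theta = 2.5, tau_theta = 80,
      e_reset = -70,
      slots = list(
        mf  = list(tau = 6,  e = 0,   gain = 0.13),
        goc = list(tau = 10, e = -80, gain = 0.12)
      )
    ),
    goc = list(
      e_leak = -70, g_leak = 0.08, theta0 = -55, d_theta = 5, tau_theta = 30,
      e_reset = -70,
      slots = list(
        mf  = list(tau = 3, e = 0, gain = 0.015),
        grc = list(tau = 4, e = 0, gain = 0.03)
      )
    ),
    pc = list(
      e_leak = -61, g_leak = 0.10, theta0 = -62, d_theta = 7, tau_theta = 22,
      e_reset = -70,
      slots = list(
        pf  = list(tau = 4,  e = 0,   gain = 0.0102),
        inh = list(tau = 8,  e = -80, gain = 0.030),
        cf  = list(tau = 6,  e = 0,   gain = 2.0)
      )
    ),
    bc = list(
      e_leak = -62, g_leak = 0.10, theta0 = -59.5, d_theta = 2.0, tau_theta = 30,
      e_reset = -70,
      slots = list(
        pf = list(tau = 4, e = 0,   gain = 0.008),
        pc = list(tau = 25, e = -80, gain = 0.052)
      )
    ),
    sc = list(
      e_leak = -62, g_leak = 0.10, theta0 = -58, d_theta = 4, tau_theta = 30,
      e_reset = -70,
      slots = list(
        pf = list(tau = 4, e = 0, gain = 0.008)
      )
    ),
    dcn = list(
      e_leak = -52, g_leak = 0.10, theta0 = -63, d_theta = 7, tau_theta = 26,
      e_reset = -70,
      slots = list(
        mf = list(tau = 4,  e = 0,   gain = 0.0025),
        pc = list(tau = 10, e = -80, gain = 0.0045)
      )
    )
  )
}

.default_counts <- c(
  n_mf = 600L, n_grc = 12000L, n_goc = 900L, n_pc = 24L, n_dcn = 8L,
  n_cf = 4L, n_bc = 96L, n_sc = 240L, n_pcmli = 9L
)

#' Simulation configuration
#'
#' Assembles and validates the configuration of the cerebellar network:
#' population counts, the feedback toggle, the wiring seed and per-population
#' neuron parameters. Default counts follow the reference circuit: 600 mossy
#' fibers, 12,000 granule cells, 900 Golgi cells, 24 Purkinje cells, 8 deep
#' cerebellar nuclei cells, 4 climbing fibers, 96 basket cells (9 of which are
#' designated PC-MLIs, the subset receiving Purkinje-cell feedback) and 240
#' stellate cells.
#'
#' `scale_factor` scales the granule-layer populations (mossy fibers, granule
#' cells, Golgi cells; each rounded, minimum 1) for desk-scale runs while the
#' readout circuit (PCs, MLIs, nuclear cells, climbing fibers) keeps its
#' configured size, so its population statistics are preserved. Convergence
#' ratios (for example the four mossy fiber inputs per granule cell) are
#' preserved by construction, and the per-spike parallel-fiber increment onto
#' PCs is rescaled to compensate the reduced number of granule-to-PC synapses,
#' preserving total mean input conductance.
#'
#' @param n_mf,n_grc,n_goc,n_pc,n_dcn,n_cf,n_bc,n_sc,n_pcmli Population
#'   counts (positive integers); `n_pcmli` must not exceed `n_bc`.
#' @param feedback_enabled Logical; when `FALSE` the Purkinje-to-basket
#'   (PC to PC-MLI) projection is omitted and everything else is identical.
#' @param seed Integer wiring seed; `build_network()` is deterministic given it.
#' @param neuron_params Per-population parameters, see
#'   [default_neuron_params()].
#' @param scale_factor Optional multiplier in (0, 1] applied to all counts.
#' @param dt Time step in ms; fixed at 1.
#' @return An object of class `pcmli_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, scale_factor = 1 / 6)
#' cfg$n_grc # 2000
sim_config <- function(n_mf = 600, n_grc = 12000, n_goc = 900, n_pc = 24,
                       n_dcn = 8, n_cf = 4, n_bc = 96, n_sc = 240,
                       n_pcmli = 9, feedback_enabled = TRUE, seed = 1L,
                       neuron_params = default_neuron_params(),
                       scale_factor = NULL, dt = 1) {
  if (dt != 1) stop("dt is fixed at 1 ms", call. = FALSE)
  counts <- c(n_mf = n_mf, n_grc = n_grc, n_goc = n_goc, n_pc = n_pc,
              n_dcn = n_dcn, n_cf = n_cf, n_bc = n_bc, n_sc = n_sc,
              n_pcmli = n_pcmli)
  if (any(counts <= 0)) {
    stop("configuration error: all population counts must be positive",
         call. = FALSE)
  }
  if (!is.null(scale_factor)) {
    if (scale_factor <= 0 || scale_factor > 1) {
      stop("configuration error: scale_factor must be in (0, 1]", call. = FALSE)
    }
    sheet <- c("n_mf", "n_grc", "n_goc")
    counts[sheet] <- pmax(round(counts[sheet] * scale_factor), 1)
  }
  counts <- setNames(as.integer(round(counts)), names(counts))
  if (counts[["n_pcmli"]] > counts[["n_bc"]]) {
    stop("configuration error: n_pcmli must not exceed n_bc", call. = FALSE)
  }
  cfg <- c(
    as.list(counts),
    list(feedback_enabled = isTRUE(feedback_enabled), seed = as.integer(seed),
         neuron_params = neuron_params,
         scale_factor = if (is.null(scale_factor)) 1 else scale_factor,
         dt = 1)
  )
  # Sampled convergence counts are fixed, so per-target drive is
  # scale-invariant for every projection except granule->PC (one synapse per
  # granule cell): rescale the per-spike parallel-fiber increment so total
  # mean excitation onto each PC is preserved at reduced granule count.
  f_pf <- (counts[["n_grc"]] / counts[["n_pc"]]) /
    (.default_counts[["n_grc"]] / .default_counts[["n_pc"]])
  if (f_pf != 1) {
    cfg$neuron_params$pc$slots$pf$gain <-
      cfg$neuron_params$pc$slots$pf$gain / f_pf
  }
  structure(cfg, class = "pcmli_config")
}

#' Read or write a simulation configuration as JSON
#'
#' The JSON mirrors every `sim_config()` field explicitly; unknown keys are
#' rejected so a typo in a config file fails loudly rather than silently
#' falling back to a default.
#'
#' @param path File path.
#' @param config A `pcmli_config` object.
#' @return `read_sim_config()` returns a `pcmli_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(names(.default_counts), "feedback_enabled", "seed",
             "scale_factor", "dt", "neuron_params")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop("configuration error: unknown config keys: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  x <- x[setdiff(names(x), c("neuron_params", "dt"))]
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "pcmli_config"))
  x <- unclass(config)
  x$neuron_params <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
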