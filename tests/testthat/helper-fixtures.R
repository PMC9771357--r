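# Shared fixtures: a miniature network cheap enough for per-test rebuilds,
# and a scalar reference integrator independent of the package's stepping
# code (used as the oracle for trajectory-equivalence checks).

tiny_config <- function(seed = 1, feedback = TRUE, params = NULL) {
  cfg <- sim_config(n_mf = 12, n_grc = 60, n_goc = 6, n_pc = 2, n_dcn = 2,
                    n_cf = 1, n_bc = 6, n_sc = 6, n_pcmli = 2,
                    feedback_enabled = feedback, seed = seed)
  if (!is.null(params)) cfg$neuron_params <- params
  cfg
}

# forward-Euler scalar integrator for one conductance-based neuron with
# adaptive threshold; written independently of the package's update code
scalar_neuron_reference <- function(n_steps, par, drive_counts, dt = 1) {
  ns <- length(par$slots)
  g <- numeric(ns)
  V <- par$e_leak
  theta <- par$theta0
  Vs <- numeric(n_steps); thetas <- numeric(n_steps); spikes <- logical(n_steps)
  tau <- vapply(par$slots, function(s) s$tau, 1)
  ee <- vapply(par$slots, function(s) s$e, 1)
  gain <- vapply(par$slots, function(s) s$gain, 1)
  pending <- numeric(ns)
  for (t in seq_len(n_steps)) {
    g <- g * exp(-dt / tau) + gain * pending
    I_syn <- sum(g * (ee - V))
    V <- V + dt * (par$g_leak * (par$e_leak - V) + I_syn)
    sp <- V >= theta
    theta <- par$theta0 + (theta - par$theta0) * exp(-dt / par$tau_theta)
    if (sp) {
      theta <- theta + par$d_theta
      V <- par$e_reset
    }
    Vs[t] <- V; thetas[t] <- theta; spikes[t] <- sp
    pending <- drive_counts[t, ]
  }
  list(V = Vs, theta = thetas, spikes = spikes)
}

# run the compiled core on an arbitrary network with externally fixed mossy
# spikes (no randomness inside the core)
run_core_fixed <- function(network, mf_spikes, protocol = protocol_config(),
                           state = NULL, log = c("grc", "goc", "pc", "bc",
                                                 "sc", "dcn", "mf", "cf")) {
  n_mf <- network$pops[["mf"]]
  T <- ncol(mf_spikes)
  pcmli:::.run_segment(pcmli:::.pack_network(network),
                       pcmli:::.state_to_cpp(state),
                       matrix(0, n_mf, T), integer(0), integer(0), integer(0),
                       protocol, 0, log, mf_spikes = mf_spikes)
}
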