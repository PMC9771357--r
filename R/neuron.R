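# Point-neuron update on the 1 ms clock. This is the reference (pure R)
# implementation of the same per-step update the compiled trial runner
# executes; the two are held to 1e-9 agreement by the test suite.

.dyn_pops <- c("grc", "goc", "pc", "bc", "sc", "dcn")

#' Initialize per-neuron dynamical state for every population
#'
#' Membrane potentials start at the leak reversal, thresholds at baseline,
#' conductance accumulators at zero.
#'
#' @param network A `pcmli_network`.
#' @return A `pcmli_state` list: one entry per dynamic population with `V`,
#'   `theta`, `g` (neuron x afferent-slot conductance matrix), `pending`
#'   (weighted presynaptic spike counts awaiting delivery) and `spiked`.
#' @export
init_state <- function(network) {
  st <- lapply(.dyn_pops, function(pop) {
    pr <- network$params[[pop]]
    n <- network$pops[[pop]]
    ns <- length(pr$slots)
    list(V = rep(pr$e_leak, n), theta = rep(pr$theta0, n),
         g = matrix(0, n, ns, dimnames = list(NULL, names(pr$slots))),
         pending = matrix(0, n, ns, dimnames = list(NULL, names(pr$slots))),
         spiked = logical(n))
  })
  names(st) <- .dyn_pops
  structure(st, class = "pcmli_state")
}

#' Decay and increment synaptic conductance accumulators
#'
#' Each accumulator decays exponentially with its afferent time constant and
#' is incremented by `gain x (weighted presynaptic spike count)` for spikes
#' delivered this step.
#'
#' @param state Per-population state (list with a `g` matrix).
#' @param params The population's parameter list (see
#'   [default_neuron_params()]).
#' @param delivered Matrix of weighted presynaptic spike counts, one column
#'   per afferent slot (same shape as `state$g`). Must be non-negative.
#' @param dt Time step (ms).
#' @return `state` with updated `g`.
#' @export
update_conductances <- function(state, params, delivered, dt = 1) {
  if (any(delivered < 0)) {
    stop("input error: negative presynaptic spike count", call. = FALSE)
  }
  tau <- vapply(params$slots, `[[`, 1, "tau")
  gain <- vapply(params$slots, `[[`, 1, "gain")
  decay <- exp(-dt / tau)
  state$g <- sweep(state$g, 2, decay, `*`) +
    sweep(delivered, 2, gain, `*`)
  state
}

#' Adaptive-threshold update
#'
#' All thresholds relax exponentially toward baseline; neurons that spiked
#' this step additionally jump by `d_theta`. This threshold adaptation, not a
#' potential-based refractory mechanism, carries spike-rate adaptation.
#'
#' @param state Per-population state (list with `theta`).
#' @param params Population parameter list (`theta0`, `d_theta`,
#'   `tau_theta` > 0).
#' @param spiked Logical vector of this step's spikes.
#' @param dt Time step (ms).
#' @return `state` with updated `theta`.
#' @export
update_threshold <- function(state, params, spiked, dt = 1) {
  stopifnot(params$tau_theta > 0)
  state$theta <- params$theta0 +
    (state$theta - params$theta0) * exp(-dt / params$tau_theta)
  state$theta[spiked] <- state$theta[spiked] + params$d_theta
  state
}

#' Advance the whole network by one 1-ms step
#'
#' Applies, for every population: conductance decay plus delivery of the
#' spikes emitted on the previous step, a forward-Euler membrane update from
#' leak and synaptic currents, spike detection (`V >= theta`), reset of
#' spiking neurons to the leak reversal, and the adaptive-threshold update.
#' Spikes emitted this step (including the external mossy-fiber and
#' climbing-fiber drive) are queued for delivery on the next step, giving
#' every connection a one-step synaptic delay.
#'
#' This R implementation is the readable reference; [run_trial()] uses a
#' compiled equivalent.
#'
#' @param network A `pcmli_network`.
#' @param state A `pcmli_state` from [init_state()] (or a previous step).
#' @param external_drive List with integer/logical vectors `mf` (length
#'   `n_mf`) and `cf` (length `n_cf`): external spikes emitted this step.
#' @param dt Time step (ms).
#' @return Updated `pcmli_state`; each population's `spiked` holds this
#'   step's spikes.
#' @export
advance_timestep <- function(network, state, external_drive, dt = 1) {
  mf <- as.integer(external_drive$mf)
  cf <- as.integer(external_drive$cf)
  if (length(mf) != network$pops[["mf"]] || length(cf) != network$pops[["cf"]])
    stop("input error: drive lengths must match population sizes",
         call. = FALSE)

  for (pop in .dyn_pops) {
    pr <- network$params[[pop]]
    st <- state[[pop]]
    st <- update_conductances(st, pr, st$pending, dt)
    st$pending[] <- 0
    e_slot <- vapply(pr$slots, `[[`, 1, "e")
    syn <- as.numeric(st$g %*% e_slot) - st$V * rowSums(st$g)
    st$V <- st$V + dt * (pr$g_leak * (pr$e_leak - st$V) + syn)
    if (any(!is.finite(st$V))) {
      stop("numerical failure in population ", pop, " neuron ",
           which(!is.finite(st$V))[1], call. = FALSE)
    }
    st$spiked <- st$V >= st$theta
    st <- update_threshold(st, pr, st$spiked, dt)
    st$V[st$spiked] <- pr$e_reset
    state[[pop]] <- st
  }

  spikes_of <- function(pop) {
    switch(pop, mf = mf != 0L, cf = cf != 0L, state[[pop]]$spiked)
  }
  for (p in network$projections) {
    src_sp <- spikes_of(p$src_pop)
    if (!length(p$src) || !any(src_sp[p$src])) next
    sel <- src_sp[p$src]
    add <- rowsum(p$weight[sel], p$tgt[sel])
    tgt_idx <- as.integer(rownames(add))
    state[[p$tgt_pop]]$pending[tgt_idx, p$slot] <-
      state[[p$tgt_pop]]$pending[tgt_idx, p$slot] + add[, 1]
  }
  state
}
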