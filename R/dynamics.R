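#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the discrete-time stochastic LIF neuron.  The membrane
#' potential evolves as `V[t+1] = mu * V[t] + i_ext + (1/k) * sum(W_ij X_j[t])`
#' and is reset to 0 on firing.  The firing probability is
#' `Gamma * (V - theta) / (1 + Gamma * (V - theta))` when `V - theta > 0` and
#' `p_spont` otherwise, so a quiescent network is seeded only by rare
#' spontaneous spikes.
#'
#' Defaults are the model's reference values: `mu = 0` (memoryless membrane),
#' no external drive, gain `0.8`, threshold `0`, spontaneous rate `1e-4` per
#' neuron per step.
#'
#' @param mu Leak multiplier, in \[0, 1\].
#' @param i_ext Constant external input per step.
#' @param gamma Gain of the saturating transfer function, > 0.
#' @param theta Firing threshold.
#' @param p_spont Spontaneous firing probability, in \[0, 1\].
#' @return A `lif_params` list.
#' @export
lif_params <- function(mu = 0, i_ext = 0, gamma = 0.8, theta = 0,
                       p_spont = 1e-4) {
  if (gamma <= 0) abort("`gamma` must be > 0.", class = "socnet_spec_error")
  if (p_spont < 0 || p_spont > 1) {
    abort("`p_spont` must lie in [0, 1].", class = "socnet_spec_error")
  }
  if (mu < 0 || mu > 1) abort("`mu` must lie in [0, 1].",
                              class = "socnet_spec_error")
  structure(list(mu = mu, i_ext = i_ext, gamma = gamma, theta = theta,
                 p_spont = p_spont), class = "lif_params")
}

#' Synaptic plasticity parameters
#'
#' The increase/depression rule `W[t+1] = W[t] + 1/tau - u * W[t] * X_pre[t]`:
#' every synapse drifts up by `1/tau` per step and is depressed by the factor
#' `u` whenever its presynaptic neuron fires.  In expectation a synapse whose
#' source fires at rate `rho` settles at `1/(tau * u * rho)`, which is the
#' feedback that self-organizes the network towards its critical strength.
#'
#' @param tau Recovery time constant in steps, > 0.  Larger `tau` means slower
#'   growth.
#' @param u Depression coefficient, in (0, 1).
#' @param enabled If `FALSE` the synaptic strengths stay fixed (used for
#'   critical-point scans).
#' @return A `plasticity_params` list.
#' @export
plasticity_params <- function(tau = 500, u = 0.1, enabled = TRUE) {
  if (tau <= 0) abort("`tau` must be > 0.", class = "socnet_spec_error")
  if (u <= 0 || u >= 1) abort("`u` must lie in (0, 1).",
                              class = "socnet_spec_error")
  structure(list(tau = tau, u = u, enabled = isTRUE(enabled)),
            class = "plasticity_params")
}

#' Firing probability of a stochastic LIF neuron
#'
#' @param v Membrane potential(s), >= 0.  Vectorised.
#' @param params A [lif_params()] object.
#' @return Probability in \[0, 1): the saturating transfer
#'   `Gamma (V - theta) / (1 + Gamma (V - theta))` above threshold (strictly),
#'   `p_spont` at or below it.
#' @examples
#' firing_probability(1.25, lif_params()) # 0.5
#' @export
firing_probability <- function(v, params = lif_params()) {
  stopifnot(inherits(params, "lif_params"))
  d <- v - params$theta
  ifelse(d > 0, params$gamma * d / (1 + params$gamma * d), params$p_spont)
}

#' One plasticity update of a synaptic strength
#'
#' @param w Current strength(s), > 0.  Vectorised.
#' @param x_pre Presynaptic firing indicator(s), 0 or 1.
#' @param params A [plasticity_params()] object.
#' @return `w + 1/tau - u * w * x_pre`.
#' @examples
#' plasticity_update(2, 1, plasticity_params(tau = 500, u = 0.1)) # 1.802
#' @export
plasticity_update <- function(w, x_pre, params = plasticity_params()) {
  stopifnot(inherits(params, "plasticity_params"))
  w + 1 / params$tau - params$u * w * x_pre
}

#' Run a network simulation
#'
#' Initialises every synaptic strength to `w_init` and every membrane
#' potential to 0, then iterates the synchronous update for `t_max` steps:
#' spikes are sampled from the current potentials, propagated along directed
#' edges (each input scaled by `1/k_i`, the target's in-degree), fired neurons
#' are reset, and the plasticity rule is applied to every edge using the
#' just-sampled spikes.  Neurons with in-degree 0 receive no input term.
#'
#' The recorded `mean_w` series is the network-mean synaptic strength over
#' edges whose presynaptic (source) neuron has in-degree >= 2; a source with
#' in-degree 0 or 1 fires essentially only spontaneously, so its outgoing
#' strengths grow by `1/tau` almost unchecked and would bias the network
#' mean.  They are excluded (see [network_mean_weight()]).  `mean_w` is `NA`
#' if no edge qualifies.
#'
#' @param net A [build_network()] result.
#' @param lif [lif_params()].
#' @param plast [plasticity_params()]; set `enabled = FALSE` for a fixed-W run.
#' @param t_max Number of steps, >= 1.
#' @param w_init Initial strength of every synapse (typically the critical
#'   value `W_c`).
#' @param probe `"all"` or an integer vector of neuron ids whose spikes are
#'   counted into `probe_spikes`.
#' @param record_raster If `TRUE`, keep every (t, neuron) spike event.
#' @param seed Optional seed; identical seeds give bitwise-identical traces.
#'
#' @return A `soc_trace` object with `$trace` (tibble: `t`, `probe_spikes`,
#'   `mean_w`), `$raster` (tibble `t`, `neuron`, or `NULL`), per-neuron
#'   `$spike_counts`, final weights/potentials, and the run configuration.
#' @examples
#' net <- build_network("random", 200, 8, seed = 1)
#' tr <- run_simulation(net, t_max = 1000, w_init = 1.5, seed = 1)
#' head(tr$trace)
#' @export
run_simulation <- function(net, lif = lif_params(), plast = plasticity_params(),
                           t_max, w_init, probe = "all",
                           record_raster = FALSE, seed = NULL) {
  stopifnot(inherits(net, "soc_network"), inherits(lif, "lif_params"),
            inherits(plast, "plasticity_params"))
  if (t_max < 1) abort("`t_max` must be >= 1.", class = "socnet_spec_error")
  if (w_init <= 0) abort("`w_init` must be > 0.", class = "socnet_spec_error")
  probe_mask <- if (identical(probe, "all")) {
    rep(TRUE, net$n)
  } else {
    if (!is.numeric(probe) || any(probe < 1 | probe > net$n)) {
      abort("`probe` must be \"all\" or valid neuron ids.",
            class = "socnet_spec_error")
    }
    seq_len(net$n) %in% as.integer(probe)
  }

  runner <- function() {
    sim_core(net$n,
             net$edges$source - 1L, net$edges$target - 1L,
             as.integer(net$in_degree), w_init,
             lif$mu, lif$i_ext, lif$gamma, lif$theta, lif$p_spont,
             plast$enabled, plast$tau, plast$u,
             as.integer(t_max), probe_mask, isTRUE(record_raster))
  }
  res <- if (is.null(seed)) runner() else withr::with_seed(seed, runner())

  structure(
    list(
      trace = tibble(t = seq_len(t_max),
                     probe_spikes = res$probe_counts,
                     mean_w = res$mean_w),
      raster = if (record_raster) {
        tibble(t = res$raster_t, neuron = res$raster_neuron)
      },
      spike_counts = res$spikes_per_neuron,
      w_final = res$w_final,
      v_final = res$v_final,
      n = net$n, t_max = as.integer(t_max), w_init = w_init,
      probe = probe, lif = lif, plast = plast, kind = net$kind, seed = seed
    ),
    class = "soc_trace"
  )
}

#' @export
print.soc_trace <- function(x, ...) {
  cat(sprintf(
    "<soc_trace> %d neurons (%s), %d steps, %d spikes, plasticity %s\n",
    x$n, x$kind, x$t_max, sum(x$spike_counts),
    if (x$plast$enabled) sprintf("tau=%g u=%g", x$plast$tau, x$plast$u)
    else "off"))
  invisible(x)
}

#' Write a simulation trace (and optional raster) to CSV
#'
#' @param trace A `soc_trace`.
#' @param path Output CSV path for the per-step trace (`t, probe_spikes,
#'   mean_w`).
#' @param raster_path Optional path for the spike-event CSV (`t, neuron`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, raster_path = NULL) {
  stopifnot(inherits(trace, "soc_trace"))
  utils::write.csv(trace$trace, path, row.names = FALSE)
  if (!is.null(raster_path)) {
    if (is.null(trace$raster)) {
      abort("trace has no raster; rerun with `record_raster = TRUE`.",
            class = "socnet_spec_error")
    }
    utils::write.csv(trace$raster, raster_path, row.names = FALSE)
  }
  invisible(path)
}
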