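#' Neuron parameters for the fixed-threshold (Vogels-style) network variant
#'
#' Conductance-based leaky integrate-and-fire neuron with AMPA and GABA
#' conductances, a fixed spiking threshold and an absolute refractory period.
#' Both excitatory and inhibitory neurons share these parameters.
#'
#' @param tau_m Membrane time constant (ms).
#' @param V_rest Resting potential (mV); also the reset potential.
#' @param E_exc,E_inh Excitatory (AMPA) and inhibitory (GABA) reversal
#'   potentials (mV).
#' @param V_th Spiking threshold (mV).
#' @param tau_ref Absolute refractory period (ms); the membrane is clamped to
#'   `V_rest` and not integrated for this duration after a spike.
#' @param tau_AMPA,tau_GABA Conductance decay time constants (ms).
#'
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' vogels_neuron_params()
vogels_neuron_params <- function(tau_m = 20, V_rest = -60, E_exc = 0,
                                 E_inh = -80, V_th = -50, tau_ref = 5,
                                 tau_AMPA = 5, tau_GABA = 10) {
  p <- list(variant = "vogels", tau_m = tau_m, V_rest = V_rest, E_exc = E_exc,
            E_inh = E_inh, V_th = V_th, tau_ref = tau_ref,
            tau_AMPA = tau_AMPA, tau_GABA = tau_GABA)
  taus <- c(tau_m, tau_ref, tau_AMPA, tau_GABA)
  if (any(taus <= 0)) stop("all time constants must be > 0")
  if (!(E_inh < V_rest && V_rest < V_th && V_th < E_exc))
    stop("need E_inh < V_rest < V_th < E_exc")
  structure(p, class = "neuron_params")
}

#' Neuron parameters for the adaptive-threshold (Zenke-style) network variant
#'
#' Conductance-based LIF neuron whose threshold jumps by `V_th_spike` at each
#' spike and relaxes back to `V_th_base` with time constant `tau_th`.  The
#' excitatory conductance is a composite `g_E = a * g_AMPA + (1 - a) * g_NMDA`
#' where the NMDA-like conductance low-passes the AMPA conductance with
#' `tau_NMDA`.
#'
#' @param tau_m Membrane time constant (ms).
#' @param V_rest Resting potential (mV).
#' @param E_exc,E_inh Reversal potentials (mV).
#' @param V_reset Post-spike reset potential (mV).
#' @param V_th_base Baseline spiking threshold (mV).
#' @param V_th_spike Threshold increment per spike (mV).
#' @param tau_th Threshold relaxation time constant (ms).  Fast threshold
#'   adaptation; configurable because only its order of magnitude is
#'   constrained.
#' @param a_frac Fraction of the composite excitatory conductance carried by
#'   the fast AMPA component (unitless, in \[0, 1\]).
#' @param tau_AMPA,tau_NMDA,tau_GABA Conductance time constants (ms).
#'
#' @return An object of class `neuron_params`.
#' @export
zenke_neuron_params <- function(tau_m = 20, V_rest = -70, E_exc = 0,
                                E_inh = -80, V_reset = -70, V_th_base = -50,
                                V_th_spike = 100, tau_th = 5, a_frac = 0.23,
                                tau_AMPA = 5, tau_NMDA = 100, tau_GABA = 10) {
  if (a_frac < 0 || a_frac > 1) stop("a_frac must lie in [0, 1]")
  taus <- c(tau_m, tau_th, tau_AMPA, tau_NMDA, tau_GABA)
  if (any(taus <= 0)) stop("all time constants must be > 0")
  structure(list(variant = "zenke", tau_m = tau_m, V_rest = V_rest,
                 E_exc = E_exc, E_inh = E_inh, V_reset = V_reset,
                 V_th_base = V_th_base, V_th_spike = V_th_spike,
                 tau_th = tau_th, a_frac = a_frac, tau_AMPA = tau_AMPA,
                 tau_NMDA = tau_NMDA, tau_GABA = tau_GABA),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params: %s variant>\n", x$variant))
  flds <- setdiff(names(x), "variant")
  cat(paste(sprintf("  %-10s %g", flds, unlist(x[flds])), collapse = "\n"),
      "\n")
  invisible(x)
}

# internal: numeric parameter list consumed by the C++ integrator
.params_for_cpp <- function(p) {
  if (p$variant == "vogels") {
    list(tau_m = p$tau_m, V_rest = p$V_rest, E_exc = p$E_exc, E_inh = p$E_inh,
         tau_AMPA = p$tau_AMPA, tau_GABA = p$tau_GABA, V_th = p$V_th,
         tau_ref = p$tau_ref)
  } else {
    list(tau_m = p$tau_m, V_rest = p$V_rest, E_exc = p$E_exc, E_inh = p$E_inh,
         tau_AMPA = p$tau_AMPA, tau_GABA = p$tau_GABA, V_reset = p$V_reset,
         V_th_base = p$V_th_base, V_th_spike = p$V_th_spike,
         tau_th = p$tau_th, a_frac = p$a_frac, tau_NMDA = p$tau_NMDA)
  }
}
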