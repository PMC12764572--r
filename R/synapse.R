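#' Synaptic time constants
#'
#' Defaults are the double-exponential AMPA/GABA constants used throughout
#' the network: AMPA decay/rise 2/0.4 ms, GABA decay/rise 5/1 ms, impulse
#' latency `tau_L` 1 ms. `tau_m` (membrane time constant, scaling the
#' impulse) and `tau_rp` (refractory time) depend on the postsynaptic /
#' source cell type: 20 ms and 2 ms for pyramidal neurons, 10 ms and 1 ms
#' for interneurons.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_dA,tau_rA AMPA decay and rise times (ms).
#' @param tau_dG,tau_rG GABA decay and rise times (ms).
#' @param tau_L Latency of post-synaptic currents (ms).
#' @param tau_rp Refractory time of the source neuron (ms).
#' @return A named list of class `syn_params`.
#' @export
syn_params <- function(tau_m = 20, tau_dA = 2, tau_rA = 0.4,
                       tau_dG = 5, tau_rG = 1, tau_L = 1, tau_rp = 2) {
  p <- list(tau_m = tau_m, tau_dA = tau_dA, tau_rA = tau_rA,
            tau_dG = tau_dG, tau_rG = tau_rG, tau_L = tau_L,
            tau_rp = tau_rp)
  if (any(unlist(p) <= 0)) rlang::abort("all time constants must be positive")
  structure(p, class = "syn_params")
}

#' Per-connection synaptic state
#'
#' Holds the filtered currents (`I_A`, `I_G`), their rise-stage auxiliaries
#' (`x_A`, `x_G`), the connection weight `J`, and the distance-dependent
#' coupling factor `exp(-r / D)` for Euclidean distance `r` scaled by `D`.
#'
#' @param J Connection weight.
#' @param r Euclidean distance between the connected neurons.
#' @param D Distance scale; `r = 0` (or `D = Inf`) disables the scaling.
#' @return A named list of class `synapse_state` with fields `I_A`, `x_A`,
#'   `I_G`, `x_G`, `J`, `distance_factor`.
#' @export
synapse_state <- function(J = 1, r = 0, D = 1) {
  structure(list(I_A = 0, x_A = 0, I_G = 0, x_G = 0, J = J,
                 distance_factor = distance_factor(r, D)),
            class = "synapse_state")
}

#' Distance-dependent coupling factor
#'
#' `exp(-r / D)`: connection strength decays with the Euclidean distance
#' `r` between neurons, scaled by `D`.
#'
#' @param r Non-negative distance.
#' @param D Positive distance scale.
#' @return Numeric in `(0, 1]`.
#' @export
distance_factor <- function(r, D) {
  if (any(D <= 0)) rlang::abort("`D` must be positive")
  if (any(r < 0)) rlang::abort("`r` must be non-negative")
  exp(-r / D)
}

#' One Euler step of the AMPA (excitatory) filter
#'
#' The rise stage `x_A` receives an impulse
#' `tau_m * distance_factor * J / tau_rA` per (delayed) presynaptic spike
#' and decays with `tau_rA`; the current `I_A` relaxes toward `x_A` with
#' `tau_dA`. With `distance_factor = 1` this reduces to the unscaled
#' double-exponential form.
#'
#' @param st A [synapse_state()].
#' @param p A [syn_params()].
#' @param pre_spikes_at_t Number of presynaptic spikes arriving this step.
#' @param dt Step size (ms).
#' @return The updated `synapse_state`.
#' @export
ampa_step <- function(st, p, pre_spikes_at_t = 0, dt = 1 / 256) {
  stopifnot(dt > 0)
  st$x_A <- st$x_A + pre_spikes_at_t * p$tau_m * st$distance_factor *
    st$J / p$tau_rA
  st$I_A <- st$I_A + dt / p$tau_dA * (st$x_A - st$I_A)
  st$x_A <- st$x_A - dt / p$tau_rA * st$x_A
  st
}

#' One Euler step of the GABA (inhibitory) filter
#'
#' Mirrors [ampa_step()] with the GABA rise/decay constants; the distance
#' factor multiplies the impulse term in the same way.
#'
#' @inheritParams ampa_step
#' @return The updated `synapse_state`.
#' @export
gaba_step <- function(st, p, pre_spikes_at_t = 0, dt = 1 / 256) {
  stopifnot(dt > 0)
  st$x_G <- st$x_G + pre_spikes_at_t * p$tau_m * st$distance_factor *
    st$J / p$tau_rG
  st$I_G <- st$I_G + dt / p$tau_dG * (st$x_G - st$I_G)
  st$x_G <- st$x_G - dt / p$tau_rG * st$x_G
  st
}

#' Net synaptic drive
#'
#' The input current delivered to a neuron is the excitatory current minus
#' the inhibitory current: `I = I_A - I_G`.
#'
#' @param I_A,I_G Filtered AMPA and GABA currents.
#' @return `I_A - I_G`.
#' @export
total_current <- function(I_A, I_G) I_A - I_G
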