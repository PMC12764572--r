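#' Actor-critic configuration
#'
#' The critic is a population of 20 HR neurons whose burst rate provides
#' the state value `v`; the reward-prediction error is carried by a
#' 1000-neuron Poisson population (modeled at desk scale as a
#' rate-modulated Poisson source). The derivative term of the dopamine
#' variable is represented by an excitatory pathway delayed 1.5 ms and an
#' inhibitory pathway delayed 25 ms.
#'
#' @param n_critic_neurons Critic population size.
#' @param n_rpe_neurons Poisson reward-prediction-error population size.
#' @param exc_delay,inh_delay Delays of the derivative-surrogate pathways
#'   (ms).
#' @param gamma Discount factor of the reward-prediction error.
#' @param tau_r Scaling time constant of the value leak term (ms). Not
#'   given a value in the source model; default 200 ms.
#' @param baseline_window Trailing-average window for the dopamine
#'   baseline `b_D` (ms).
#' @return A named list of class `critic_config`.
#' @export
critic_config <- function(n_critic_neurons = 20, n_rpe_neurons = 1000,
                          exc_delay = 1.5, inh_delay = 25, gamma = 0.5,
                          tau_r = 200, baseline_window = 10) {
  stopifnot(n_critic_neurons > 0, n_rpe_neurons > 0,
            gamma >= 0, gamma <= 1, tau_r > 0)
  structure(list(n_critic_neurons = n_critic_neurons,
                 n_rpe_neurons = n_rpe_neurons,
                 exc_delay = exc_delay, inh_delay = inh_delay,
                 gamma = gamma, tau_r = tau_r,
                 baseline_window = baseline_window),
            class = "critic_config")
}

#' Reward-prediction error
#'
#' The temporal-difference error `delta_t = r + gamma * v_next - v_now`.
#'
#' @param r_next Reward received on the transition.
#' @param v_next,v_now State values after and before the transition.
#' @param gamma Discount factor.
#' @return The prediction error.
#' @export
rpe <- function(r_next, v_next, v_now, gamma = 0.5) {
  r_next + gamma * v_next - v_now
}

#' Dopaminergic signal from value and reward traces
#'
#' Computes `D(t) = vdot(t) + r(t) - v(t) / tau_r` on a uniform time grid,
#' with the derivative represented by the two delayed pathways of the
#' critic-to-RPE circuit: `vdot(t) = (v(t - exc_delay) - v(t - inh_delay))
#' / (inh_delay - exc_delay)`. The baseline `b_D` is the trailing mean of
#' `D` over `baseline_window` (10 ms by default). Before a delay has
#' filled, `v` is extended backwards with its first value.
#'
#' @param v_trace,r_trace Equal-length value and reward samples.
#' @param dt Sample spacing (ms).
#' @param cfg A [critic_config()] supplying delays, `tau_r` and the
#'   baseline window.
#' @return A tibble of class `dopamine_signal` with columns `t`, `D`,
#'   `b_D`.
#' @export
dopamine <- function(v_trace, r_trace, dt = 1, cfg = critic_config()) {
  if (length(v_trace) != length(r_trace))
    rlang::abort("`v_trace` and `r_trace` must have equal length")
  if (cfg$tau_r <= 0) rlang::abort("`tau_r` must be positive")
  n <- length(v_trace)
  lag_at <- function(lag_ms) {
    k <- round(lag_ms / dt)
    if (k == 0) return(v_trace)
    c(rep(v_trace[1], min(k, n)), v_trace[seq_len(max(n - k, 0))])
  }
  vdot <- (lag_at(cfg$exc_delay) - lag_at(cfg$inh_delay)) /
    (cfg$inh_delay - cfg$exc_delay)
  D <- vdot + r_trace - v_trace / cfg$tau_r
  structure(tibble::tibble(t = seq_len(n) * dt, D = D,
                           b_D = trailing_mean(D, cfg$baseline_window, dt)),
            class = c("dopamine_signal", class(tibble::tibble())))
}

# trailing mean of the last `window/dt` samples (including the current one)
trailing_mean <- function(x, window, dt) {
  k <- max(1L, round(window / dt))
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - k, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' Population value readout from critic bursts
#'
#' The state value is the critic population's mean burst rate: total burst
#' count divided by population size and window length, in events per
#' second.
#'
#' @param burst_onsets_per_neuron List of burst-onset time vectors (ms),
#'   one per critic neuron.
#' @param window Observation window length (ms).
#' @return Mean burst rate (Hz).
#' @export
critic_value <- function(burst_onsets_per_neuron, window) {
  stopifnot(window > 0)
  n <- length(burst_onsets_per_neuron)
  if (n == 0) return(0)
  total <- sum(lengths(burst_onsets_per_neuron))
  total / n / (window / 1000)
}

#' Reward emulation protocol
#'
#' The dopamine-source population ceases firing for 100 ms after a
#' misclassification and doubles its rate after a correct classification;
#' without feedback the rate is unchanged.
#'
#' @param correct `TRUE` (correct), `FALSE` (incorrect) or `NA` (no
#'   feedback).
#' @param duration Length of the feedback window (ms).
#' @return A list with `multiplier` (2, 0 or 1) and `duration`.
#' @export
reward_emulation <- function(correct, duration = 100) {
  multiplier <- if (is.na(correct)) 1 else if (correct) 2 else 0
  list(multiplier = multiplier, duration = duration)
}
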