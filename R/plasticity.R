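#' BTDP learning-rule parameters
#'
#' Defaults are the printed burst-timing window constants: `A_plus = 0.07`,
#' `A_minus = -0.05`, `gamma_plus = 20`, `gamma_minus = 25`, `tau = 10` ms.
#' `use_linear_exp` switches the exponential inside the window to its
#' piecewise-linear substitution table ([exp_table()]), the form the digital
#' learning block evaluates.
#'
#' @param A_plus,A_minus Base potentiation / depression amplitudes.
#' @param gamma_plus,gamma_minus ISI-adaptation divisors of the learning
#'   rate.
#' @param tau Time constant of the exponential window (ms).
#' @param use_linear_exp Use the segment table in place of `exp()`.
#' @param sigma_max Clamp on `|sigma|` when the window is driven by
#'   network activity: with sparse desk-scale firing, raw mean-ISI
#'   differences can reach hundreds of ms and would swamp (and sign-flip)
#'   the base amplitudes; the printed gamma values imply ISI differences
#'   of order 1 ms, so the clamp keeps `sigma/gamma` strictly below
#'   `|A_plus|` and `|A_minus|`.
#' @param w_max Symmetric weight bound applied when updates are accumulated
#'   into network weights.
#' @return A named list of class `plasticity_params`.
#' @export
plasticity_params <- function(A_plus = 0.07, A_minus = -0.05,
                              gamma_plus = 20, gamma_minus = 25, tau = 10,
                              use_linear_exp = FALSE, sigma_max = 1,
                              w_max = 5) {
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 tau = tau, use_linear_exp = use_linear_exp,
                 sigma_max = sigma_max, w_max = w_max),
            class = "plasticity_params")
}

#' ISI-difference term of the adaptive learning rate
#'
#' `sigma` is the mean inter-spike interval of the postsynaptic neuron
#' minus that of the presynaptic neuron; it shifts the learning-rate
#' amplitudes `A_plus + sigma / gamma_plus` and mirrored forms.
#'
#' @param isi_post_mean,isi_pre_mean Mean ISIs (ms).
#' @return `isi_post_mean - isi_pre_mean`.
#' @export
sigma_isi <- function(isi_post_mean, isi_pre_mean) {
  isi_post_mean - isi_pre_mean
}

# exponential window kernel: exact or linear-substituted decaying exp of
# the magnitude. The table can run slightly negative past its last printed
# knot, so the substituted kernel is floored at zero to keep the decaying
# semantics.
exp_kernel <- function(mag, p) {
  if (isTRUE(p$use_linear_exp)) {
    pmax(eval_piecewise(exp_table(), mag), 0)
  } else {
    exp(-mag / p$tau)
  }
}

#' BTDP pair window W(x)
#'
#' The weight change contributed by one pre/post burst pairing with signed
#' inter-burst interval `x` (post onset minus pre onset):
#' \deqn{W(x) = (A_+ + \sigma/\gamma_+) e^{-x/\tau}, x \ge 0}
#' \deqn{W(x) = (A_- - \sigma/\gamma_-) e^{x/\tau}, x < 0}
#'
#' @param x Signed inter-burst interval (ms); vectorized.
#' @param sigma ISI difference from [sigma_isi()].
#' @param p A [plasticity_params()].
#' @return Numeric vector of weight increments.
#' @examples
#' btdp_window(0, 0)     # A_plus
#' btdp_window(-10, 0)   # A_minus * exp(-1)
#' @export
btdp_window <- function(x, sigma = 0, p = plasticity_params()) {
  amp <- ifelse(x >= 0,
                p$A_plus + sigma / p$gamma_plus,
                p$A_minus - sigma / p$gamma_minus)
  amp * exp_kernel(abs(x), p)
}

#' Total BTDP weight change over two burst trains
#'
#' Sums [btdp_window()] over all pre/post burst-onset pairings within the
#' pairing horizon (all-to-all by default), with the inter-burst interval
#' of a pairing defined as post onset minus pre onset.
#'
#' @param pre_bursts,post_bursts Burst-onset times (ms).
#' @param sigma ISI difference of the connected pair.
#' @param p A [plasticity_params()].
#' @param horizon Pairings with `|IBI|` beyond this are ignored.
#' @return A single weight increment.
#' @export
btdp_delta <- function(pre_bursts, post_bursts, sigma = 0,
                       p = plasticity_params(), horizon = Inf) {
  if (length(pre_bursts) == 0 || length(post_bursts) == 0) return(0)
  ibi <- outer(post_bursts, pre_bursts, "-")
  ibi <- ibi[abs(ibi) <= horizon]
  if (length(ibi) == 0) return(0)
  sum(btdp_window(ibi, sigma, p))
}

#' Dopamine-gated (RBTDP) weight change
#'
#' The reinforcement form scales the BTDP increment by the deviation of the
#' dopaminergic variable from its baseline: `(D - b_D) * dw`.
#'
#' @param D Dopaminergic variable.
#' @param b_D Its trailing-average baseline.
#' @param btdp_dw A BTDP increment (e.g. from [btdp_delta()]).
#' @return `(D - b_D) * btdp_dw`.
#' @export
rbtdp_delta <- function(D, b_D, btdp_dw) (D - b_D) * btdp_dw

#' Per-pairing weight increment embedded in the synaptic impulse
#'
#' The network learning rules add an increment to the synaptic weight
#' inside the impulse bracket for every pre/post burst pairing. For
#' excitatory-source synapses the increment is `A~ * exp(-|IBI|/tau)` with
#' the amplitude branch selected by the sign of the inter-burst interval
#' (`A_plus + sigma/gamma_plus` when the presynaptic burst leads,
#' `A_minus + sigma/gamma_minus` otherwise — note the plus sign in the
#' depression branch of the per-synapse forms). Inhibitory-source synapses
#' use `B~ = 0.4 * A~`. The reinforcement variants for synapses onto the
#' output and critic layers are additionally gated by `(D - b_D)`.
#'
#' @param kind One of `"exc_btdp"`, `"inh_btdp"`, `"exc_rbtdp"`,
#'   `"inh_rbtdp"`.
#' @param ibi Signed inter-burst interval (post minus pre onset, ms);
#'   vectorized.
#' @param sigma ISI difference of the pair.
#' @param p A [plasticity_params()].
#' @param D,b_D Dopamine variable and baseline (reinforcement kinds only).
#' @return Numeric vector of weight increments.
#' @export
synaptic_rate_modifier <- function(kind = c("exc_btdp", "inh_btdp",
                                            "exc_rbtdp", "inh_rbtdp"),
                                   ibi, sigma = 0, p = plasticity_params(),
                                   D = NA_real_, b_D = NA_real_) {
  kind <- match.arg(kind)
  amp <- ifelse(ibi >= 0,
                p$A_plus + sigma / p$gamma_plus,
                p$A_minus + sigma / p$gamma_minus)
  w <- amp * exp_kernel(abs(ibi), p)
  if (startsWith(kind, "inh")) w <- 0.4 * w
  if (endsWith(kind, "rbtdp")) {
    if (is.na(D) || is.na(b_D))
      rlang::abort("reinforcement kinds need `D` and `b_D`")
    w <- (D - b_D) * w
  }
  w
}
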