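#' Hindmarsh-Rose model constants
#'
#' Defaults are the burst-regime constants used throughout the package:
#' `a = 1, b = 3, c = 1, d = 5, r = 0.001, s = 4, q = -1.618`. `r` controls
#' the spike/burst frequency; `I` is the constant input current.
#'
#' @param a,b,c,d,r,s,q Dimensionless model constants.
#' @param I Constant input current.
#' @return A named list of class `hr_params`.
#' @export
hr_params <- function(a = 1, b = 3, c = 1, d = 5, r = 0.001, s = 4,
                      q = -1.618, I = 0) {
  p <- list(a = a, b = b, c = c, d = d, r = r, s = s, q = q, I = I)
  structure(p, class = "hr_params")
}

#' Right-hand side of the HR neuron
#'
#' The three-variable burster: `x` is the membrane potential, `y` the fast
#' (Na/K) current, `z` the slow (Ca) current.
#' \deqn{dx/dt = y - a x^3 + b x^2 - z + I}
#' \deqn{dy/dt = c - d x^2 - y}
#' \deqn{dz/dt = r (s (x - q) - z)}
#'
#' @param state Numeric `c(x, y, z)`.
#' @param p An [hr_params()] list.
#' @return Numeric `c(dx, dy, dz)`.
#' @export
hr_derivs <- function(state, p = hr_params()) {
  x <- state[1]; y <- state[2]; z <- state[3]
  c(y - p$a * x^3 + p$b * x^2 - z + p$I,
    p$c - p$d * x^2 - y,
    p$r * (p$s * (x - p$q) - z))
}

#' Right-hand side of the linear HR (LHR) neuron
#'
#' Identical to [hr_derivs()] except that `x^3` and `x^2` are replaced by
#' their piecewise-linear segment tables, making the model multiplier-less
#' in hardware.
#'
#' @inheritParams hr_derivs
#' @param cube,square Segment tables substituting the cubic and quadratic.
#' @return Numeric `c(dx, dy, dz)`.
#' @export
lhr_derivs <- function(state, p = hr_params(), cube = cube_table(),
                       square = square_table()) {
  x <- state[1]; y <- state[2]; z <- state[3]
  x3 <- eval_piecewise(cube, x)
  x2 <- eval_piecewise(square, x)
  c(y - p$a * x3 + p$b * x2 - z + p$I,
    p$c - p$d * x2 - y,
    p$r * (p$s * (x - p$q) - z))
}

#' One first-order Euler step
#'
#' @param state Numeric state vector.
#' @param derivs_fn Function `state -> dstate`.
#' @param dt Positive step size.
#' @return The updated state `state + dt * derivs_fn(state)`.
#' @export
euler_step <- function(state, derivs_fn, dt) {
  stopifnot(dt > 0)
  state + dt * derivs_fn(state)
}

#' Simulate a single HR or LHR neuron
#'
#' Integrates the model with first-order Euler at fixed `dt` (default
#' 1/256, the step the digital datapath realizes as an arithmetic shift)
#' and extracts spike and burst events. Time is treated as milliseconds so
#' that neuron and synapse time constants share one clock.
#'
#' @param model `"hr"` or `"lhr"`.
#' @param p An [hr_params()] list (set `p$I` for the drive).
#' @param ic Initial condition `c(x, y, z)`.
#' @param duration Simulated time.
#' @param dt Euler step.
#' @param threshold Membrane-potential spike threshold (upward crossing).
#' @param intra_burst_isi_max Largest inter-spike interval still counted as
#'   within one burst.
#' @param guard Abort the integration (with an error) if `|x|` exceeds this.
#' @return A tibble of class `neuron_trace` with columns `t`, `x`, `y`, `z`
#'   and attributes `dt`, `spike_times`, `burst_onsets`, `model`, `params`.
#' @examples
#' tr <- simulate_neuron("hr", hr_params(I = 1.5), duration = 500)
#' length(burst_onsets(tr))
#' @export
simulate_neuron <- function(model = c("hr", "lhr"), p = hr_params(),
                            ic = c(-1, 0, 0), duration = 2000, dt = 1 / 256,
                            threshold = 0.8, intra_burst_isi_max = 15,
                            guard = 1e3) {
  model <- match.arg(model)
  stopifnot(duration > 0, dt > 0)
  n_steps <- round(duration / dt)
  cube <- pw_parts(cube_table())
  sq <- pw_parts(square_table())
  m <- cpp_simulate_neuron(ifelse(model == "hr", 0L, 1L),
                           unlist(p[c("a", "b", "c", "d", "r", "s", "q", "I")]),
                           ic, n_steps, dt,
                           cube$br, cube$slope, cube$intercept,
                           sq$br, sq$slope, sq$intercept, guard)
  tr <- tibble::tibble(t = seq(0, by = dt, length.out = n_steps + 1),
                       x = m[, 1], y = m[, 2], z = m[, 3])
  spikes <- detect_spikes(tr, threshold = threshold)
  bursts <- detect_bursts(spikes, intra_burst_isi_max = intra_burst_isi_max)
  structure(tr, dt = dt, spike_times = spikes, burst_onsets = bursts,
            model = model, params = p,
            class = c("neuron_trace", class(tr)))
}

#' Spike times of a trace
#'
#' Upward crossings of the membrane potential through `threshold`.
#'
#' @param trace A `neuron_trace` tibble (or any tibble with `t` and `x`).
#' @param threshold Crossing level.
#' @return Numeric vector of strictly increasing crossing times.
#' @export
detect_spikes <- function(trace, threshold = 0.8) {
  x <- trace$x
  up <- which(x[-length(x)] < threshold & x[-1] >= threshold)
  trace$t[up + 1L]
}

#' Group spikes into bursts
#'
#' Consecutive spikes closer than `intra_burst_isi_max` belong to one
#' burst; each burst is reported by its first-spike time. Grouping is
#' idempotent.
#'
#' @param spike_times Sorted numeric spike times.
#' @param intra_burst_isi_max Largest within-burst inter-spike interval.
#' @return Numeric vector of burst-onset times.
#' @export
detect_bursts <- function(spike_times, intra_burst_isi_max = 15) {
  if (length(spike_times) == 0) return(numeric(0))
  new_burst <- c(TRUE, diff(spike_times) > intra_burst_isi_max)
  spike_times[new_burst]
}

#' Access event times stored on a trace
#'
#' @param trace A `neuron_trace`.
#' @return Numeric event times.
#' @export
spike_times <- function(trace) attr(trace, "spike_times")

#' @rdname spike_times
#' @export
burst_onsets <- function(trace) attr(trace, "burst_onsets")

# mean and max instantaneous event frequency (1 / interval)
event_freqs <- function(times) {
  if (length(times) < 2) return(c(mean = 0, max = 0))
  f <- 1 / diff(times)
  c(mean = mean(f), max = max(f))
}

#' Compare two neuron traces
#'
#' Computes the four waveform-similarity criteria between a reference and a
#' test trace on the membrane potential: max-normalized mean absolute error
#' (NMAE), Pearson correlation, max-normalized root-mean-square error
#' (NRMSE), and the normalized frequency difference (NFD) of spike and
#' burst event rates. NFD is the absolute difference of mean instantaneous
#' event frequencies normalized by the maximum instantaneous frequency of
#' the reference.
#'
#' @param ref,test `neuron_trace` tibbles with identical `dt` and length.
#' @param discard Initial transient (in time units) excluded from the
#'   waveform metrics and event rates.
#' @return An object of class `trace_comparison`: a one-row tibble with
#'   columns `nmae`, `correlation`, `nrmse`, `nfd_spike`, `nfd_burst`.
#' @export
compare_traces <- function(ref, test, discard = 0) {
  if (nrow(ref) != nrow(test))
    rlang::abort("traces must have equal length")
  if (!isTRUE(all.equal(attr(ref, "dt"), attr(test, "dt"))))
    rlang::abort("traces must share dt")
  keep <- ref$t >= discard
  r <- ref$x[keep]
  s <- test$x[keep]
  mx <- max(abs(r))
  nmae <- mean(abs(r - s)) / mx
  nrmse <- sqrt(mean(((r - s) / mx)^2))
  correlation <- stats::cor(r, s)

  nfd <- function(ref_times, test_times) {
    fr <- event_freqs(ref_times[ref_times >= discard])
    ft <- event_freqs(test_times[test_times >= discard])
    if (fr[["max"]] == 0) return(if (ft[["max"]] == 0) 0 else NA_real_)
    abs(fr[["mean"]] - ft[["mean"]]) / fr[["max"]]
  }
  out <- tibble::tibble(
    nmae = nmae, correlation = correlation, nrmse = nrmse,
    nfd_spike = nfd(spike_times(ref), spike_times(test)),
    nfd_burst = nfd(burst_onsets(ref), burst_onsets(test)))
  class(out) <- c("trace_comparison", class(out))
  out
}

#' @export
glance.trace_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.trace_comparison <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)),
                      cols = dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
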