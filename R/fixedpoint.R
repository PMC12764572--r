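#' Fixed-point number format
#'
#' Signed Q-format with `int_bits` integer bits and `frac_bits` fractional
#' bits (plus sign); a real `v` is stored as the integer
#' `round(v * 2^frac_bits)`, saturating at the representable range. The
#' default Q8.24 covers the observed state range of the burst models with
#' sub-1e-7 resolution; narrower formats are sweepable, but below ~20
#' fractional bits the slow-current increment falls under one LSB after the
#' dt shift and the burst dynamics freeze.
#'
#' @param int_bits,frac_bits Bit widths; total must not exceed 32.
#' @return A named list of class `q_format`.
#' @export
q_format <- function(int_bits = 8, frac_bits = 24) {
  stopifnot(int_bits + frac_bits <= 32, int_bits >= 1, frac_bits >= 0)
  structure(list(int_bits = int_bits, frac_bits = frac_bits,
                 scale = 2^frac_bits,
                 max_int = 2^(int_bits + frac_bits) - 1),
            class = "q_format")
}

#' Quantize reals to a Q-format
#'
#' Round-to-nearest representable value with saturation. The number of
#' saturated inputs is attached as attribute `n_saturations` (and the
#' saturation is also reported with a warning), mirroring the logged
#' overflow flag of the hardware registers.
#'
#' @param v Finite numeric vector.
#' @param q A [q_format()].
#' @return Integer register values (as doubles; exact below 2^53).
#' @export
quantize <- function(v, q = q_format()) {
  stopifnot(all(is.finite(v)))
  i <- round(v * q$scale)
  n_sat <- sum(i > q$max_int | i < -q$max_int)
  if (n_sat > 0)
    rlang::warn(sprintf("%d value(s) saturated in quantization", n_sat))
  structure(pmin(pmax(i, -q$max_int), q$max_int), n_saturations = n_sat)
}

#' @rdname quantize
#' @param i Integer register values.
#' @export
dequantize <- function(i, q = q_format()) as.numeric(i) / q$scale

#' Decompose a constant into a signed power-of-two (shift-and-add) program
#'
#' Greedy canonical-signed-digit style decomposition: the constant is
#' approximated by at most `max_terms` terms `sign * 2^shift`, so that a
#' multiplication by it reduces to shifts and adds. The residual
#' approximation error is reported.
#'
#' @param value Constant to decompose.
#' @param max_terms Maximum number of power-of-two terms.
#' @param min_shift Smallest (most negative) usable shift; defaults to the
#'   fractional resolution of the default [q_format()].
#' @return A list with `plan` (matrix with columns `sign`, `shift`),
#'   `realized` (the value the program computes) and `residual`.
#' @examples
#' shift_add_plan(3)$plan        # 2^1 + 2^0
#' shift_add_plan(0.001)$residual
#' @export
shift_add_plan <- function(value, max_terms = 3, min_shift = -24) {
  res <- value
  sign <- integer(0)
  shift <- integer(0)
  for (i in seq_len(max_terms)) {
    if (abs(res) < 2^min_shift / 2) break     # below Q resolution
    k <- min(max(round(log2(abs(res))), min_shift), 30L)
    sign <- c(sign, if (res > 0) 1L else -1L)
    shift <- c(shift, as.integer(k))
    res <- res - sign[length(sign)] * 2^k
  }
  plan <- cbind(sign = sign, shift = shift)
  realized <- if (nrow(plan) == 0) 0 else sum(plan[, 1] * 2^plan[, 2])
  list(plan = plan, realized = realized, residual = value - realized)
}

# plan matrix in the form the C++ stepper consumes
plan_mat <- function(value, max_terms = 3, min_shift = -24) {
  m <- shift_add_plan(value, max_terms, min_shift)$plan
  storage.mode(m) <- "integer"
  m
}

#' Build the fixed-point LHR datapath description
#'
#' Pre-converts the model constants and the segment-table coefficients into
#' shift-and-add programs and quantized registers for the bit-deterministic
#' stepper. The time-step multiply is realized as an arithmetic right shift
#' (`dt_shift = 8` for dt = 1/256; a shift of 9 is selectable).
#'
#' @param p An [hr_params()] list.
#' @param q A [q_format()].
#' @param dt_shift Right-shift realizing the Euler step scaling.
#' @param max_terms Shift-and-add terms allowed per constant. The default
#'   (8) recodes every constant to the format's resolution; a 3-term
#'   greedy decomposition (a few tenths of a percent residual) is a
#'   measurably different vector field for the burster.
#' @return A list consumed by [simulate_neuron_fixed()] and the network
#'   stepper.
#' @export
fixed_lhr_model <- function(p = hr_params(), q = q_format(), dt_shift = 8,
                            max_terms = 8) {
  cube <- cube_table(); sq <- square_table()
  min_shift <- -q$frac_bits
  plans <- function(vals) lapply(vals, plan_mat, max_terms = max_terms,
                                 min_shift = min_shift)
  qz <- function(v) as.numeric(round(v * q$scale))
  list(frac_bits = q$frac_bits, int_bits = q$int_bits, dt_shift = dt_shift,
       a_plan = plan_mat(p$a, max_terms, min_shift),
       b_plan = plan_mat(p$b, max_terms, min_shift),
       d_plan = plan_mat(p$d, max_terms, min_shift),
       r_plan = plan_mat(p$r, max_terms, min_shift),
       s_plan = plan_mat(p$s, max_terms, min_shift),
       c_q = qz(p$c), q_q = qz(p$q),
       cube_br_q = qz(cube$lo[-1]), cube_in_q = qz(cube$intercept),
       cube_sl_plans = plans(cube$slope),
       sq_br_q = qz(sq$lo[-1]), sq_in_q = qz(sq$intercept),
       sq_sl_plans = plans(sq$slope))
}

#' Simulate the fixed-point LHR neuron
#'
#' Bit-deterministic emulation of the multiplier-less digital datapath: all
#' state is held in Q-format integer registers, constant multiplications
#' are shift-and-add programs, and the Euler `dt` is an arithmetic right
#' shift. Useful for quantifying hardware-vs-float divergence via
#' [compare_traces()].
#'
#' @inheritParams simulate_neuron
#' @param q A [q_format()].
#' @param dt_shift Right shift realizing dt (8 = 1/256, 9 = 1/512).
#' @param max_terms Shift-and-add terms per constant.
#' @return A `neuron_trace` tibble (like [simulate_neuron()]) with an extra
#'   attribute `n_saturations`.
#' @export
simulate_neuron_fixed <- function(p = hr_params(), ic = c(-1, 0, 0),
                                  duration = 2000, q = q_format(),
                                  dt_shift = 8, threshold = 0.8,
                                  intra_burst_isi_max = 15, max_terms = 8) {
  dt <- 2^(-dt_shift)
  n_steps <- round(duration / dt)
  fx <- fixed_lhr_model(p, q, dt_shift, max_terms)
  res <- cpp_simulate_fixed(fx, round(ic * q$scale), round(p$I * q$scale),
                            n_steps)
  m <- res$trace
  tr <- tibble::tibble(t = seq(0, by = dt, length.out = n_steps + 1),
                       x = m[, 1], y = m[, 2], z = m[, 3])
  spikes <- detect_spikes(tr, threshold = threshold)
  bursts <- detect_bursts(spikes, intra_burst_isi_max = intra_burst_isi_max)
  structure(tr, dt = dt, spike_times = spikes, burst_onsets = bursts,
            model = "lhr_fixed", params = p,
            n_saturations = res$n_saturations,
            class = c("neuron_trace", class(tr)))
}

# operator-count bookkeeping for the learning datapath audit
audit_log <- function() {
  tibble::tibble(op = c("multiply", "add", "subtract", "shift"),
                 count = c(0L, 0L, 0L, 0L))
}

audit_add <- function(log, op, n = 1L) {
  log$count[log$op == op] <- log$count[log$op == op] + as.integer(n)
  log
}

# shift-add product: register times runtime-recoded constant. Counts one
# shift and one add/subtract per program term; no multiplies.
fixed_shift_add_mul <- function(reg, value, q, log, max_terms = 3) {
  plan <- shift_add_plan(value, max_terms, -q$frac_bits)$plan
  acc <- 0
  for (i in seq_len(nrow(plan))) {
    k <- plan[i, "shift"]
    term <- if (k >= 0) reg * 2^k else floor(reg / 2^(-k))
    log <- audit_add(log, "shift")
    acc <- acc + plan[i, "sign"] * term
    log <- audit_add(log, if (plan[i, "sign"] > 0) "add" else "subtract")
  }
  list(value = acc, log = log)
}

#' One fixed-point learning-block evaluation
#'
#' Evaluates the BTDP pair window in fixed point the way the digital
#' learning module does: the linear exponential substitution table provides
#' the kernel, the adaptive amplitude `A~` is applied as a shift-and-add
#' program, and (for the reinforcement variant) the dopamine gate
#' `(D - b_D)` contributes the block's single true multiplication. Every
#' operator is tallied in an audit log comparable to hardware resource
#' tables: the BTDP path uses no multiplier.
#'
#' @param ibi Signed inter-burst interval (ms).
#' @param sigma ISI difference of the pair.
#' @param p A [plasticity_params()].
#' @param D,b_D Dopamine variable and baseline; leave `NULL` for the pure
#'   BTDP path.
#' @param q A [q_format()].
#' @param max_terms Shift-and-add terms for the amplitude recoding.
#' @return A list with `delta` (the dequantized weight increment),
#'   `delta_q` (the register value) and `audit` (operator-count tibble).
#' @export
fixed_learning_step <- function(ibi, sigma = 0, p = plasticity_params(),
                                D = NULL, b_D = NULL, q = q_format(),
                                max_terms = 3) {
  log <- audit_log()
  # adaptive amplitude: A_pm + sigma / gamma_pm (per-synapse branch forms)
  sigma_q <- as.numeric(quantize(sigma, q))
  if (ibi >= 0) {
    base <- p$A_plus; gam <- p$gamma_plus
  } else {
    base <- p$A_minus; gam <- p$gamma_minus
  }
  sg <- fixed_shift_add_mul(sigma_q, 1 / gam, q, log, max_terms)
  log <- sg$log
  amp_q <- as.numeric(quantize(base, q)) + sg$value
  log <- audit_add(log, "add")

  # kernel from the linear exponential table, fixed-point segment selection
  fx <- exp_table()
  xq <- as.numeric(quantize(abs(ibi), q))
  br_q <- round(fx$lo[-1] * q$scale)
  seg <- findInterval(xq, br_q) + 1L
  sl <- fixed_shift_add_mul(xq, fx$slope[seg], q, log, max_terms)
  log <- sl$log
  kern_q <- max(sl$value + as.numeric(quantize(fx$intercept[seg], q)), 0)
  log <- audit_add(log, "add")

  # W = amp * kernel: kernel register scaled by the recoded amplitude
  wq <- fixed_shift_add_mul(kern_q, dequantize(amp_q, q), q, log, max_terms)
  log <- wq$log
  delta_q <- wq$value

  if (!is.null(D) && !is.null(b_D)) {
    gate_q <- as.numeric(quantize(D, q)) - as.numeric(quantize(b_D, q))
    log <- audit_add(log, "subtract")
    delta_q <- floor(gate_q * delta_q / q$scale)   # the one true multiply
    log <- audit_add(log, "multiply")
  }
  delta_q <- unname(as.numeric(delta_q))
  list(delta = dequantize(delta_q, q), delta_q = delta_q, audit = log)
}
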