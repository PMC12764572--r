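# closed-form impulse response of the rise/decay filter pair: an impulse A
# on the rise stage at t = 0 gives
#   I(t) = A * tau_r / (tau_d - tau_r) * (exp(-t/tau_d) - exp(-t/tau_r))
double_exp <- function(t, A, tau_d, tau_r) {
  A * tau_r / (tau_d - tau_r) * (exp(-t / tau_d) - exp(-t / tau_r))
}

step_many <- function(st, p, n, dt, kind = ampa_step, spikes_at = integer(0)) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    st <- kind(st, p, pre_spikes_at_t = sum(spikes_at == i), dt = dt)
    out[i] <- if (identical(kind, ampa_step)) st$I_A else st$I_G
  }
  list(trace = out, state = st)
}

test_that("silent synapses decay to zero at the closed-form rate", {
  p <- syn_params()
  dt <- 1 / 256
  st <- synapse_state(J = 1)
  st$I_A <- 1; st$I_G <- 1
  n <- round(20 / dt)
  ta <- step_many(st, p, n, dt)$trace
  tg <- step_many(st, p, n, dt, kind = gaba_step)$trace
  tt <- seq_len(n) * dt
  expect_lt(max(abs(ta - exp(-tt / p$tau_dA))), 0.01)
  expect_lt(max(abs(tg - exp(-tt / p$tau_dG))), 0.01)
  expect_lt(ta[n], 1e-4)
})

test_that("single-impulse response follows the double-exponential solution", {
  p <- syn_params()
  dt <- 1 / 256
  st <- synapse_state(J = 1)
  n <- round(10 / dt)
  tr <- step_many(st, p, n, dt, spikes_at = 1L)$trace
  tt <- seq_len(n) * dt - dt
  A <- p$tau_m * 1 / p$tau_rA
  ref <- double_exp(tt, A, p$tau_dA, p$tau_rA)
  expect_lt(max(abs(tr - ref)) / max(ref), 0.02)
  # peak occurs after the rise time, then decays
  expect_gt(which.max(tr) * dt, p$tau_rA)
  expect_lt(tr[n], max(tr) / 10)
})

test_that("GABA outlasts AMPA for the same impulse", {
  p <- syn_params()
  dt <- 1 / 256
  n <- round(15 / dt)
  st <- synapse_state(J = 1)
  a <- step_many(st, p, n, dt, spikes_at = 1L)$trace
  g <- step_many(st, p, n, dt, kind = gaba_step, spikes_at = 1L)$trace
  t10 <- function(v) max(which(v > max(v) / 10)) * dt
  expect_gt(t10(g), t10(a))
})

test_that("responses superpose and scale linearly in J and spike count", {
  p <- syn_params()
  dt <- 1 / 128
  n <- round(12 / dt)
  one <- step_many(synapse_state(J = 1), p, n, dt, spikes_at = 10L)$trace
  other <- step_many(synapse_state(J = 1), p, n, dt, spikes_at = 500L)$trace
  both <- step_many(synapse_state(J = 1), p, n, dt,
                    spikes_at = c(10L, 500L))$trace
  expect_lt(max(abs(both - (one + other))), 1e-10)
  twoJ <- step_many(synapse_state(J = 2), p, n, dt, spikes_at = 10L)$trace
  expect_lt(max(abs(twoJ - 2 * one)), 1e-10)
  twice <- step_many(synapse_state(J = 1), p, n, dt,
                     spikes_at = c(10L, 10L))$trace
  expect_lt(max(abs(twice - 2 * one)), 1e-10)
})

test_that("distance factor is exp(-r/D) with unit value at zero distance", {
  expect_equal(distance_factor(0, 3), 1)
  expect_equal(distance_factor(3, 3), exp(-1))
  r <- seq(0, 10, by = 0.5)
  expect_true(all(diff(distance_factor(r, 4)) < 0))
  expect_error(distance_factor(1, 0), "positive")
  expect_error(distance_factor(-1, 1), "non-negative")
  # unit factor reduces the scaled impulse to the unscaled form
  p <- syn_params()
  plain <- ampa_step(synapse_state(J = 1, r = 0, D = 1), p, 1, 1 / 256)
  scaled <- ampa_step(synapse_state(J = 1, r = 1e-12, D = 1e12), p, 1, 1 / 256)
  expect_equal(plain$x_A, scaled$x_A, tolerance = 1e-9)
})

test_that("net drive is the excitatory minus the inhibitory current", {
  expect_equal(total_current(0, 0), 0)
  expect_equal(total_current(2, 0.5), 1.5)
  expect_equal(total_current(1.3, 1.3), 0)
})

test_that("network impulses arrive one latency after the presynaptic event", {
  # a single bright input cell; its first spike can influence layer 2 no
  # earlier than tau_L = 1 ms later
  cfg <- tiny_config(input_fanout = 0.5, rate_max = 0)
  net <- build_network(cfg, seed = 3)
  spk <- structure(tibble::tibble(cell_row = 1L, cell_col = 1L, t = 5),
                   shape = c(7L, 7L), duration = 60,
                   class = c("spike_array", class(tibble::tibble())))
  rec <- run_trial(net, spk, trial_protocol(eval_window = 60,
                                            transient_discard = 0),
                   seed = 9)
  first <- suppressWarnings(min(unlist(rec$spikes_by_neuron)))
  if (is.finite(first)) expect_gte(first, 5 + 1)
})
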