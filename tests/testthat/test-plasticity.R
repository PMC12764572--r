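test_that("sigma is the antisymmetric ISI-mean difference", {
  expect_equal(sigma_isi(10, 10), 0)
  expect_equal(sigma_isi(12, 10), 2)
  expect_equal(sigma_isi(3, 8), -sigma_isi(8, 3))
})

test_that("the pair window takes the printed values at reference points", {
  expect_equal(btdp_window(0, 0), 0.07)
  expect_equal(btdp_window(-10, 0), -0.05 * exp(-1))
  expect_lt(abs(btdp_window(500, 0)), 1e-20)
  # sigma shifts the amplitudes with opposite signs in the two branches
  expect_equal(btdp_window(0, 2), 0.07 + 2 / 20)
  expect_equal(btdp_window(-1e-9, 2), (-0.05 - 2 / 25) * exp(-1e-10),
               tolerance = 1e-6)
})

test_that("trainwise weight change equals the brute-force double loop", {
  set.seed(11)
  p <- plasticity_params()
  for (rep in 1:4) {
    pre <- sort(runif(sample(2:6, 1), 0, 300))
    post <- sort(runif(sample(2:6, 1), 0, 300))
    sigma <- runif(1, -1, 1)
    oracle <- 0
    for (tp in post) for (tq in pre)
      oracle <- oracle + btdp_window(tp - tq, sigma, p)
    expect_equal(btdp_delta(pre, post, sigma, p), oracle, tolerance = 1e-12)
  }
  expect_equal(btdp_delta(numeric(0), c(1, 2)), 0)
  expect_equal(btdp_delta(c(0), c(0)), 0.07)
})

test_that("the pairing horizon excludes distant pairings", {
  full <- btdp_delta(c(0, 100), c(5), horizon = Inf)
  near <- btdp_delta(c(0, 100), c(5), horizon = 50)
  expect_equal(near, btdp_window(5, 0))
  expect_equal(full, btdp_window(5, 0) + btdp_window(-95, 0))
})

test_that("per-pairing magnitude respects the amplitude envelope", {
  p <- plasticity_params()
  set.seed(3)
  x <- runif(200, -60, 60)
  sigma <- runif(200, -1, 1)
  w <- btdp_window(x, sigma, p)
  bound <- pmax(abs(p$A_plus) + abs(sigma) / p$gamma_plus,
                abs(p$A_minus) + abs(sigma) / p$gamma_minus)
  expect_true(all(abs(w) <= bound + 1e-12))
})

test_that("dopamine gating is bilinear and vanishes at baseline", {
  expect_equal(rbtdp_delta(0.3, 0.3, 5), 0)
  expect_equal(rbtdp_delta(1, 0, 0.07), 0.07)
  expect_equal(rbtdp_delta(0.1, 0.4, 2), -rbtdp_delta(0.4, 0.1, 2))
  expect_equal(rbtdp_delta(2, 1, 3) + rbtdp_delta(1, 1, 3),
               rbtdp_delta(2, 1, 3))
  expect_equal(rbtdp_delta(3, 1, 4), 2 * rbtdp_delta(2, 1, 4))
})

test_that("rate modifiers follow the per-synapse branch forms", {
  expect_equal(synaptic_rate_modifier("exc_btdp", 1e-12, 0), 0.07,
               tolerance = 1e-9)
  # inhibitory-source variants are 0.4 times the excitatory ones
  ibis <- c(-20, -5, 0, 5, 20)
  expect_equal(synaptic_rate_modifier("inh_btdp", ibis, 0.5),
               0.4 * synaptic_rate_modifier("exc_btdp", ibis, 0.5))
  # reinforcement kinds vanish at the dopamine baseline
  expect_equal(synaptic_rate_modifier("exc_rbtdp", 5, 0, D = 0.2, b_D = 0.2),
               0)
  expect_equal(
    synaptic_rate_modifier("inh_rbtdp", ibis, 0, D = 1, b_D = 0),
    0.4 * synaptic_rate_modifier("exc_rbtdp", ibis, 0, D = 1, b_D = 0))
  expect_error(synaptic_rate_modifier("exc_rbtdp", 1), "need")
})

test_that("linear-exponential window tracks the exact one at Table-5 level", {
  p_exact <- plasticity_params(use_linear_exp = FALSE)
  p_lin <- plasticity_params(use_linear_exp = TRUE)
  x <- seq(0, 50, length.out = 2001)
  exact <- btdp_window(x, 0, p_exact)
  lin <- btdp_window(x, 0, p_lin)
  expect_lte(nmae_curve(exact, lin), 0.003)
})

test_that("zero bursts on either side means exactly zero weight change", {
  net <- build_network(tiny_config(rate_max = 0), seed = 5)
  pats <- tiny_patterns()
  rec <- tiny_trial(net, pats$image[[1]], label = 0, seed = 3,
                    learning = TRUE, feedback = TRUE)
  # no input spikes -> no layer-2 or output bursts -> weights untouched
  expect_identical(rec$net$syn$J, net$syn$J)
})
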