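test_that("HR right-hand side matches hand substitution", {
  p <- hr_params()
  expect_equal(hr_derivs(c(0, 0, 0), p), c(0, 1, 0.001 * 4 * 1.618))
  expect_equal(hr_derivs(c(1, 0, 0), p),
               c(-1 + 3, 1 - 5, 0.001 * 4 * (1 - (-1.618))))
  # dz vanishes on the slow nullcline z = s (x - q)
  x <- 0.7
  st <- c(x, 0.2, p$s * (x - p$q))
  expect_equal(hr_derivs(st, p)[3], 0)
})

test_that("LHR right-hand side substitutes the segment tables", {
  p <- hr_params()
  expect_equal(lhr_derivs(c(0, 0, 0), p)[1:2], c(0, 1))
  expect_equal(lhr_derivs(c(0, 0, 0), p)[3], hr_derivs(c(0, 0, 0), p)[3])
  # at x = 2 the tables give 6.63 and 3.721 in place of 8 and 4
  d <- lhr_derivs(c(2, 0, 0), p)
  expect_equal(d[1], -6.63 + 3 * 3.721)
  expect_equal(d[2], 1 - 5 * 3.721)
})

test_that("LHR derivative error is bounded by the table errors", {
  p <- hr_params()
  xg <- seq(-1.8, 1.8, length.out = 181)
  e3 <- max(abs(eval_piecewise(cube_table(), xg) - xg^3))
  e2 <- max(abs(eval_piecewise(square_table(), xg) - xg^2))
  dx_err <- sapply(xg, function(x)
    abs(lhr_derivs(c(x, 0, 0), p)[1] - hr_derivs(c(x, 0, 0), p)[1]))
  expect_true(all(dx_err <= p$a * e3 + p$b * e2 + 1e-12))
})

test_that("Euler stepping is the plain first-order update", {
  p <- hr_params(I = 1.5)
  st <- euler_step(c(0, 0, 0), function(s) hr_derivs(s, p), 1 / 256)
  expect_equal(st, c(1.5 / 256, 1 / 256, 0.001 * 4 * 1.618 / 256))
  # two explicit steps equal the composition
  f <- function(s) hr_derivs(s, p)
  expect_equal(euler_step(euler_step(c(0, 0, 0), f, 0.01), f, 0.01),
               {
                 s <- c(0, 0, 0)
                 for (i in 1:2) s <- s + 0.01 * f(s)
                 s
               })
  # dt -> 0 leaves the state unchanged
  expect_equal(euler_step(c(1, 2, 3), f, 1e-300), c(1, 2, 3))
})

test_that("HR bursts recurrently at I = 1.5 and is silent at I = 0", {
  tr <- simulate_neuron("hr", hr_params(I = 1.5), duration = 600)
  expect_gte(length(burst_onsets(tr)), 2)
  # spikes per burst
  sp <- spike_times(tr)
  expect_gte(length(sp) / length(burst_onsets(tr)), 2)

  # from the resting state (x = q, y = c - d q^2, z = 0) nothing fires
  quiet <- simulate_neuron("hr", hr_params(I = 0),
                           ic = c(-1.618, -12.1, 0), duration = 300)
  expect_length(spike_times(quiet), 0)
})

test_that("simulation is deterministic and stays bounded across drives", {
  a <- simulate_neuron("lhr", hr_params(I = 1.5), duration = 200)
  b <- simulate_neuron("lhr", hr_params(I = 1.5), duration = 200)
  expect_identical(a$x, b$x)
  for (I in c(0, 1.5, 3)) {
    for (m in c("hr", "lhr")) {
      tr <- simulate_neuron(m, hr_params(I = I), duration = 800)
      expect_lt(max(abs(tr$x)), 5)
    }
  }
})

test_that("integration failure is signalled on blow-up", {
  expect_error(simulate_neuron("hr", hr_params(I = 1e8), duration = 10),
               "integration failure")
})

test_that("spike detection finds upward crossings only", {
  flat <- tibble::tibble(t = 0:10, x = rep(0, 11))
  expect_length(detect_spikes(flat), 0)
  pulse <- tibble::tibble(t = 0:6, x = c(0, 0.5, 1.2, 0.5, 0, 0, 0))
  expect_equal(detect_spikes(pulse), 2)
})

test_that("burst grouping follows the ISI gap rule and is idempotent", {
  expect_length(detect_bursts(numeric(0)), 0)
  sp <- c(0, 1, 2, 100, 101)
  on <- detect_bursts(sp, intra_burst_isi_max = 10)
  expect_equal(on, c(0, 100))
  expect_equal(detect_bursts(on, intra_burst_isi_max = 10), on)
})

test_that("trace comparison returns the exact identity tuple on itself", {
  tr <- simulate_neuron("hr", hr_params(I = 1.5), duration = 300)
  m <- compare_traces(tr, tr)
  expect_equal(unname(unlist(glance(m))),
               c(0, 1, 0, 0, 0))
  expect_error(compare_traces(tr, tr[1:10, ]), "equal length")
})

test_that("halving dt changes the waveform by a bounded amount", {
  # convergence is checked on a smooth (subthreshold) trajectory; on the
  # bursting attractor any perturbation dephases the spikes
  coarse <- simulate_neuron("hr", hr_params(I = 0), ic = c(-1.4, -10, 0),
                            duration = 200, dt = 1 / 256)
  fine <- simulate_neuron("hr", hr_params(I = 0), ic = c(-1.4, -10, 0),
                          duration = 200, dt = 1 / 512)
  r <- coarse$x
  s <- fine$x[seq(1, nrow(fine), by = 2)]
  expect_lt(sqrt(mean(((r - s) / max(abs(r)))^2)), 0.05)
})

test_that("traces round-trip through the columnar text format", {
  tr <- simulate_neuron("hr", hr_params(I = 1.5), duration = 50)
  path <- tempfile(fileext = ".txt")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$x, tr$x, tolerance = 1e-6)
  expect_equal(attr(back, "dt"), attr(tr, "dt"), tolerance = 1e-9)
  unlink(path)
})
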