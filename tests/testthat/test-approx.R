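test_that("fixed segment tables match their printed structure and values", {
  cube <- cube_table()
  sq <- square_table()
  ex <- exp_table()
  expect_equal(nrow(cube), 10)
  expect_equal(nrow(sq), 8)
  expect_equal(nrow(ex), 10)

  # spot values read straight off the segment lines
  expect_equal(eval_piecewise(cube, 0), 0)
  expect_equal(eval_piecewise(cube, 2), 6.33 * 2 - 6.03)
  expect_equal(eval_piecewise(cube, -2), -6.63)
  expect_equal(eval_piecewise(sq, 0), 0)
  expect_equal(eval_piecewise(ex, 0), 0.999)
  expect_equal(eval_piecewise(ex, 40), -0.0020 * 40 + 0.1)
})

test_that("table symmetries and monotonicity hold on a grid", {
  x <- seq(0.01, 1.99, length.out = 211)
  expect_equal(eval_piecewise(cube_table(), -x),
               -eval_piecewise(cube_table(), x))
  expect_equal(eval_piecewise(square_table(), -x),
               eval_piecewise(square_table(), x))
  t <- seq(0, 50, length.out = 301)
  v <- eval_piecewise(exp_table(), t)
  expect_true(all(v >= 0))              # exactly zero at t = 50
  expect_true(all(v[t < 49] > 0))
  expect_true(all(diff(v) <= 0))
})

test_that("printed tables are near-continuous at their breakpoints", {
  for (pw in list(cube_table(), square_table(), exp_table())) {
    br <- pw$lo[-1]
    left <- pw$slope[-nrow(pw)] * br + pw$intercept[-nrow(pw)]
    right <- pw$slope[-1] * br + pw$intercept[-1]
    expect_lt(max(abs(left - right)), 0.05)
  }
})

test_that("evaluation is total and assigns breakpoints to the higher segment", {
  pw <- piecewise_linear(c(-Inf, 0), c(0, Inf), c(1, 2), c(0, 5))
  expect_equal(eval_piecewise(pw, 0), 5)      # right-closed at the boundary
  expect_equal(eval_piecewise(pw, -1e9), -1e9)
  expect_false(any(is.na(eval_piecewise(pw, c(-1e6, -1, 0, 1, 1e6)))))
})

test_that("constructor rejects malformed segment sets", {
  expect_error(piecewise_linear(c(0, -1), c(-1, Inf), c(1, 1), c(0, 0)),
               "sorted")
  expect_error(piecewise_linear(c(-Inf, 1), c(0, Inf), c(1, 1), c(0, 0)),
               "share boundaries")
})

test_that("normalized error metrics match hand-computed and oracle values", {
  expect_equal(nmae_curve(c(1, 2), c(1, 2)), 0)
  expect_equal(nrmse_curve(c(1, 2), c(1, 2)), 0)
  expect_equal(nmae_curve(c(1, 2), c(1, 1)), 0.25)      # (0+1)/(2*2)
  expect_equal(nrmse_curve(c(2, 2), c(2, 0)), sqrt(4 / 2) / 2)
  expect_error(nmae_curve(1:3, 1:2), "equal length")
  expect_error(nrmse_curve(c(0, 0), c(1, 1)), "nonzero")

  # brute-force summation oracle on random curves
  set.seed(42)
  for (i in 1:5) {
    ref <- runif(100, 0.1, 3)
    app <- ref + rnorm(100, 0, 0.1)
    n <- length(ref)
    oracle_nmae <- 0
    oracle_sq <- 0
    for (j in seq_len(n)) {
      oracle_nmae <- oracle_nmae + abs(ref[j] - app[j])
      oracle_sq <- oracle_sq + (ref[j] - app[j])^2
    }
    expect_equal(nmae_curve(ref, app), oracle_nmae / (n * max(ref)),
                 tolerance = 1e-12)
    expect_equal(nrmse_curve(ref, app), sqrt(oracle_sq / n) / max(ref),
                 tolerance = 1e-12)
  }
})

test_that("polynomial substitution errors sit near the published level", {
  e2 <- table_error(square_table(), function(x) x^2, c(-2, 2))
  e3 <- table_error(cube_table(), function(x) x^3, c(-2, 2))
  expect_lt(abs(e2$nmae - 0.0121) / 0.0121, 0.3)
  expect_lt(abs(e3$nmae - 0.0216) / 0.0216, 0.3)
})

test_that("best-fit search nails a linear target with two knots", {
  fit <- search_best_fit(function(x) 2 * x + 1, c(-1, 1), tolerance = 1e-6,
                         seed = 3)
  expect_true(fit$converged)
  expect_equal(fit$n_points, 2)
  expect_lt(fit$achieved_error, 1e-6)
})

test_that("best-fit search reaches published-level errors on x^2 and x^3", {
  fit2 <- search_best_fit(function(x) x^2, c(-2, 2), tolerance = 0.015,
                          seed = 5)
  expect_true(fit2$converged)
  expect_lte(fit2$achieved_error, 0.015)
  fit3 <- search_best_fit(function(x) x^3, c(-2, 2), tolerance = 0.03,
                          seed = 5)
  expect_true(fit3$converged)
  expect_lte(fit3$achieved_error, 0.03)
})

test_that("search error is non-increasing in the knot budget in expectation", {
  errs <- suppressWarnings(sapply(1:20, function(s) {
    lo <- search_best_fit(function(x) x^2, c(-2, 2), tolerance = 1e-9,
                          n_points_max = 4, n_restarts = 10, seed = s)
    hi <- search_best_fit(function(x) x^2, c(-2, 2), tolerance = 1e-9,
                          n_points_max = 9, n_restarts = 10, seed = s)
    c(lo = lo$achieved_error, hi = hi$achieved_error)
  }))
  expect_lte(mean(errs["hi", ]), mean(errs["lo", ]))
})

test_that("search warns but returns best-so-far when tolerance is unreachable", {
  expect_warning(
    fit <- search_best_fit(function(x) x^2, c(-2, 2), tolerance = 1e-9,
                           n_points_max = 3, n_restarts = 5, seed = 1),
    "did not reach")
  expect_false(fit$converged)
  expect_s3_class(fit$table, "piecewise_linear")
})

test_that("segment tables round-trip through the plain-text format", {
  path <- tempfile(fileext = ".txt")
  write_segments(cube_table(), path)
  back <- read_segments(path)
  expect_equal(as.data.frame(back), as.data.frame(cube_table()))
  unlink(path)
})
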