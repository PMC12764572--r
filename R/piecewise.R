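#' Construct a piecewise-linear segment table
#'
#' A piecewise-linear table substitutes a nonlinear scalar function by an
#' ordered set of line segments `slope * x + intercept` on half-open
#' intervals `[lo, hi)`. The outermost segments extend to +/-infinity, so
#' evaluation is a total function; a breakpoint value belongs to the higher
#' segment.
#'
#' @param lo,hi Numeric vectors of segment bounds. Segments must be sorted
#'   and contiguous (`hi[i] == lo[i + 1]`); the first `lo` and last `hi` are
#'   `-Inf` / `Inf`.
#' @param slope,intercept Numeric vectors, one line per segment.
#' @return A tibble of class `piecewise_linear` with columns `lo`, `hi`,
#'   `slope`, `intercept`.
#' @examples
#' pw <- piecewise_linear(c(-Inf, 0), c(0, Inf), c(-1, 1), c(0, 0))
#' eval_piecewise(pw, c(-2, 2))
#' @export
piecewise_linear <- function(lo, hi, slope, intercept) {
  stopifnot(length(lo) == length(hi), length(lo) == length(slope),
            length(lo) == length(intercept), length(lo) >= 1)
  if (is.unsorted(lo, strictly = TRUE))
    rlang::abort("segments must be sorted by `lo`")
  if (any(hi[-length(hi)] != lo[-1]))
    rlang::abort("adjacent segments must share boundaries (hi[i] == lo[i+1])")
  if (any(hi <= lo))
    rlang::abort("each segment needs hi > lo")
  out <- tibble::tibble(lo = as.numeric(lo), hi = as.numeric(hi),
                        slope = as.numeric(slope),
                        intercept = as.numeric(intercept))
  class(out) <- c("piecewise_linear", class(out))
  out
}

# internal breakpoints (length nrow - 1) plus line coefficients
pw_parts <- function(pw) {
  list(br = pw$lo[-1], slope = pw$slope, intercept = pw$intercept)
}

#' Evaluate a piecewise-linear table
#'
#' Total and deterministic: every real `x` maps to exactly one segment
#' (breakpoints belong to the higher segment).
#'
#' @param pw A [piecewise_linear()] table.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector `slope * x + intercept` of the containing segments.
#' @export
eval_piecewise <- function(pw, x) {
  p <- pw_parts(pw)
  idx <- findInterval(x, p$br, left.open = FALSE) + 1L
  p$slope[idx] * x + p$intercept[idx]
}

#' Segment table substituting the cubic x^3
#'
#' The ten-segment table used inside the linear HR (LHR) neuron in place of
#' the cubic membrane nonlinearity. Odd-symmetric about the origin.
#'
#' @return A [piecewise_linear()] table with 10 segments.
#' @examples
#' eval_piecewise(cube_table(), 2)   # 6.33 * 2 - 6.03
#' @export
cube_table <- function() {
  piecewise_linear(
    lo = c(-Inf, -1.3, -1.03, -0.78, -0.47, 0, 0.47, 0.78, 1.03, 1.3),
    hi = c(-1.3, -1.03, -0.78, -0.47, 0, 0.47, 0.78, 1.03, 1.3, Inf),
    slope = c(6.33, 4.08, 2.473, 1.196, 0.22, 0.22, 1.196, 2.473, 4.08, 6.33),
    intercept = c(6.03, 3.1, 1.45, 0.458, 0, 0, -0.458, -1.45, -3.1, -6.03))
}

#' Segment table substituting the quadratic x^2
#'
#' The eight-segment table used inside the LHR neuron in place of the
#' quadratic nonlinearity. The printed source gives the last condition as
#' `x > 29.1`; this is treated as a typo for `x > 1.21` (the value required
#' for the table to be contiguous and even-symmetric with its first
#' segment), and the corrected bound is used here.
#'
#' @return A [piecewise_linear()] table with 8 segments.
#' @export
square_table <- function() {
  piecewise_linear(
    lo = c(-Inf, -1.21, -0.82, -0.41, 0, 0.41, 0.82, 1.21),
    hi = c(-1.21, -0.82, -0.41, 0, 0.41, 0.82, 1.21, Inf),
    slope = c(-2.859, -2.029, -1.23, -0.41, 0.41, 1.23, 2.029, 2.859),
    intercept = c(-1.997, -0.99, -0.336, 0, 0, -0.336, -0.99, -1.997))
}

#' Segment table substituting the decaying exponential exp(-dt/10)
#'
#' The ten-segment table used inside the BTDP/RBTDP learning window in place
#' of `exp(-x / tau)` with `tau = 10` ms, for non-negative time differences
#' `x = t_pre - t_post`. All slopes are negative, so the table is monotone
#' non-increasing.
#'
#' @return A [piecewise_linear()] table with 10 segments.
#' @examples
#' eval_piecewise(exp_table(), 0)    # 0.999
#' eval_piecewise(exp_table(), 40)   # 0.02
#' @export
exp_table <- function() {
  piecewise_linear(
    lo = c(-Inf, 2.63, 5.23, 8.19, 11.12, 14.15, 17.71, 22.43, 28.95, 34.17),
    hi = c(2.63, 5.23, 8.19, 11.12, 14.15, 17.71, 22.43, 28.95, 34.17, Inf),
    slope = c(-0.0876, -0.0677, -0.0513, -0.0382, -0.0284, -0.0204,
              -0.0136, -0.0078, -0.0043, -0.0020),
    intercept = c(0.999, 0.9468, 0.8611, 0.7539, 0.6444, 0.5321,
                  0.4104, 0.2810, 0.18, 0.1))
}

check_curves <- function(ref, approx) {
  if (length(ref) != length(approx))
    rlang::abort("`ref` and `approx` must have equal length")
  if (length(ref) < 1) rlang::abort("need at least one sample")
  if (max(ref) == 0) rlang::abort("max(ref) must be nonzero")
  invisible(NULL)
}

#' Normalized mean absolute error between two sampled curves
#'
#' `NMAE = sum(|ref - approx|) / (n * max(ref))`. The normalization uses the
#' maximum of the reference curve (not of its absolute value).
#'
#' @param ref,approx Equal-length numeric vectors sampled at the same points.
#' @return A single number.
#' @export
nmae_curve <- function(ref, approx) {
  check_curves(ref, approx)
  sum(abs(ref - approx)) / (length(ref) * max(ref))
}

#' Normalized root-mean-square error between two sampled curves
#'
#' `NRMSE = sqrt(mean((ref - approx)^2)) / max(ref)`.
#'
#' @inheritParams nmae_curve
#' @return A single number.
#' @export
nrmse_curve <- function(ref, approx) {
  check_curves(ref, approx)
  sqrt(mean((ref - approx)^2)) / max(ref)
}

#' Approximation error of a segment table against its target function
#'
#' Samples both the table and the target on a uniform grid and reports both
#' normalized error metrics. The default grid (10,001 points) and the
#' domains used for the built-in tables (`[-2, 2]` for the polynomial
#' tables, `[0, 50]` for the exponential) span all printed breakpoints with
#' margin.
#'
#' @param pw A [piecewise_linear()] table.
#' @param target A vectorized function of one argument.
#' @param domain Length-2 numeric evaluation interval.
#' @param n Number of grid points.
#' @return A one-row tibble with columns `nmae` and `nrmse`.
#' @examples
#' table_error(square_table(), function(x) x^2, c(-2, 2))
#' @export
table_error <- function(pw, target, domain, n = 10001) {
  x <- seq(domain[1], domain[2], length.out = n)
  ref <- target(x)
  approx <- eval_piecewise(pw, x)
  tibble::tibble(nmae = nmae_curve(ref, approx),
                 nrmse = nrmse_curve(ref, approx))
}

#' Search for a best-fitting piecewise-linear substitution
#'
#' Seeded stochastic search for a segment table approximating `target` on
#' `domain`. Starting from two knots, the search draws random knot locations
#' on the target curve (uniformly, one batch per half-domain), connects
#' consecutive knots by chords, extends the outer chords to the domain ends,
#' and scores the candidate by [nmae_curve()] on a uniform grid. Knot
#' placement is resampled `n_restarts` times per knot count; the knot count
#' grows until the error tolerance is met or `n_points_max` is reached.
#'
#' @param target Vectorized function of one argument.
#' @param domain Length-2 numeric interval to approximate over.
#' @param tolerance Positive NMAE target.
#' @param seed Integer seed for the knot sampling.
#' @param n_points_min,n_points_max Knot-count range (2 to 11).
#' @param grid_resolution Number of error-grid samples.
#' @param n_restarts Random placements tried per knot count.
#' @return A list with elements `table` (the best [piecewise_linear()]
#'   found), `achieved_error` (its NMAE), `n_points`, and `converged`.
#'   Warns (and still returns the best table) when the tolerance was not met
#'   at `n_points_max`.
#' @export
search_best_fit <- function(target, domain, tolerance, seed = 1L,
                            n_points_min = 2L, n_points_max = 11L,
                            grid_resolution = 2001L, n_restarts = 60L) {
  stopifnot(tolerance > 0, n_points_min >= 2, n_points_max <= 11,
            n_points_min <= n_points_max)
  grid <- seq(domain[1], domain[2], length.out = grid_resolution)
  ref <- target(grid)
  if (max(ref) == 0) rlang::abort("target must have a nonzero maximum")
  mid <- mean(domain)

  best <- NULL
  best_err <- Inf
  best_m <- NA_integer_
  rng <- make_rng(seed)

  for (m in seq(n_points_min, n_points_max)) {
    for (rep in seq_len(n_restarts)) {
      # knots drawn uniformly, split between the two half-domains
      n_left <- ceiling(m / 2)
      xs <- sort(c(runif_rng(rng, n_left, domain[1], mid),
                   runif_rng(rng, m - n_left, mid, domain[2])))
      if (anyDuplicated(xs)) next
      cand <- chords_to_table(xs, target(xs))
      if (is.null(cand)) next
      err <- nmae_curve(ref, eval_piecewise(cand, grid))
      if (err < best_err) {
        best <- cand
        best_err <- err
        best_m <- m
      }
    }
    if (best_err < tolerance) break
  }

  converged <- best_err < tolerance
  if (!converged)
    rlang::warn(sprintf(
      "search did not reach tolerance %.4g (best NMAE %.4g with %d points)",
      tolerance, best_err, best_m))
  list(table = best, achieved_error = best_err, n_points = best_m,
       converged = converged)
}

# chords between consecutive on-curve knots; outer chords extended outward
chords_to_table <- function(xs, ys) {
  m <- length(xs)
  if (m < 2) return(NULL)
  dx <- diff(xs)
  if (any(dx == 0)) return(NULL)
  slope <- diff(ys) / dx
  intercept <- ys[-m] - slope * xs[-m]
  lo <- c(-Inf, xs[-c(1, m)])
  hi <- c(xs[-c(1, m)], Inf)
  piecewise_linear(lo, hi, slope, intercept)
}

# Small counter-based RNG wrapper so the search never disturbs the global
# .Random.seed (library code should not).
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- as.integer(seed)
  env
}

runif_rng <- function(rng, n, lo, hi) {
  if (n == 0) return(numeric(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$state)
  rng$state <- as.integer((as.numeric(rng$state) * 69069 + 1) %% 2147483647)
  stats::runif(n, lo, hi)
}
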