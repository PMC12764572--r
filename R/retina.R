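#' Average-pool an image
#'
#' The amacrine/horizontal stage of the pseudo-retina: non-overlapping mean
#' pooling with a square window. Two stages of 2x2/stride-2 pooling reduce
#' 28x28 to 7x7 and 32x32 to 8x8. Pooling is globally mean-preserving.
#'
#' @param image 2-D numeric matrix.
#' @param window Pooling window side length.
#' @param stride Pooling stride (must equal `window`; windows do not
#'   overlap).
#' @return The pooled matrix.
#' @export
pool_image <- function(image, window = 2, stride = 2) {
  stopifnot(is.matrix(image), window == stride)
  h <- nrow(image); w <- ncol(image)
  if (h %% stride != 0 || w %% stride != 0)
    rlang::abort("image dimensions must be divisible by the stride")
  oh <- h %/% stride; ow <- w %/% stride
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) {
    ri <- ((i - 1) * stride + 1):(i * stride)
    for (j in seq_len(ow)) {
      cj <- ((j - 1) * stride + 1):(j * stride)
      out[i, j] <- mean(image[ri, cj])
    }
  }
  out
}

#' Encode an image as ganglion spike trains
#'
#' The pseudo-retinal front end: the image is average-pooled
#' `n_pool_stages` times (2x2, stride 2), then each pooled cell emits a
#' homogeneous Poisson spike train with rate `intensity * rate_max`. The
#' ganglion output for a 28x28 input is therefore a 7x7 array of 49 spike
#' trains with intensity-dependent frequencies. The internal bipolar and
#' ganglion cell dynamics are not modeled; this rate-to-Poisson surrogate
#' preserves the image-in / spike-array-out interface.
#'
#' @param image 2-D numeric matrix with intensities in `[0, 1]`.
#' @param rate_max Firing rate of a fully bright cell (Hz).
#' @param duration Encoding window (ms).
#' @param n_pool_stages Number of 2x2 pooling stages.
#' @param seed Integer seed; encoding is reproducible and does not disturb
#'   the global RNG state.
#' @return A tibble of class `spike_array` with columns `cell_row`,
#'   `cell_col`, `t` (ms, sorted within cell) and attributes `shape`,
#'   `duration`.
#' @export
encode_image <- function(image, rate_max = 40, duration = 500,
                         n_pool_stages = 2, seed = 1L) {
  stopifnot(is.matrix(image))
  if (any(image < 0 | image > 1))
    rlang::abort("image intensities must lie in [0, 1]")
  pooled <- image
  for (s in seq_len(n_pool_stages)) pooled <- pool_image(pooled)
  rates <- pooled * rate_max                    # Hz
  counts <- with_seed(seed, stats::rpois(length(rates),
                                         rates * duration / 1000))
  cells <- which(counts > 0)
  times <- with_seed(seed + 1L, stats::runif(sum(counts), 0, duration))
  idx <- rep(cells, counts[cells])
  out <- tibble::tibble(
    cell_row = arrayInd(idx, dim(rates))[, 1],
    cell_col = arrayInd(idx, dim(rates))[, 2],
    t = times) |>
    dplyr::arrange(.data$cell_row, .data$cell_col, .data$t)
  structure(out, shape = dim(rates), duration = duration,
            class = c("spike_array", class(out)))
}

#' Synthetic labeled pattern set
#'
#' Generates a toy image-classification task standing in for natural image
#' datasets at desk scale: each class has a distinct oriented-bar/blob
#' prototype (horizontal bar, vertical bar, main diagonal, anti-diagonal,
#' center blob, ...) on an otherwise dark background, and each sample is
#' the prototype plus clipped Gaussian pixel noise.
#'
#' @param n_classes Number of classes (2 to 5).
#' @param n_per_class Samples generated per class.
#' @param shape Image dimensions `c(h, w)`.
#' @param noise Standard deviation of the additive pixel noise; `0` makes
#'   within-class samples identical.
#' @param seed Integer seed.
#' @return A tibble with columns `label` (0-based class index) and `image`
#'   (list column of matrices).
#' @export
make_patterns <- function(n_classes = 3, n_per_class = 10,
                          shape = c(28, 28), noise = 0.05, seed = 1L) {
  stopifnot(n_classes >= 2, n_classes <= 5)
  protos <- lapply(seq_len(n_classes) - 1L, class_prototype, shape = shape)
  imgs <- list()
  labels <- integer(0)
  k <- 0L
  for (cls in seq_len(n_classes) - 1L) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      img <- protos[[cls + 1L]]
      if (noise > 0) {
        eps <- with_seed(seed + 1000L * k,
                         stats::rnorm(length(img), 0, noise))
        img <- pmin(pmax(img + matrix(eps, nrow(img)), 0), 1)
      }
      imgs[[k]] <- img
      labels[k] <- cls
    }
  }
  tibble::tibble(label = labels, image = imgs)
}

class_prototype <- function(cls, shape) {
  h <- shape[1]; w <- shape[2]
  img <- matrix(0, h, w)
  th <- max(2L, round(h / 7))          # bar half-thickness scale
  mid_r <- (h + 1) / 2; mid_c <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- switch(as.character(cls),
    "0" = abs(rows - mid_r) < th,                       # horizontal bar
    "1" = abs(cols - mid_c) < th,                       # vertical bar
    "2" = abs(rows - cols) < th,                        # main diagonal
    "3" = abs(rows + cols - (h + 1)) < th,              # anti-diagonal
    "4" = (rows - mid_r)^2 + (cols - mid_c)^2 < (h / 4)^2)  # center blob
  img[mask] <- 1
  img
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
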