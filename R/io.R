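#' Read and write piecewise-linear tables as plain text
#'
#' One segment per line: `lo hi slope intercept`, whitespace separated.
#'
#' @param pw A [piecewise_linear()] table.
#' @param path File path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns a [piecewise_linear()].
#' @export
write_segments <- function(pw, path) {
  utils::write.table(as.data.frame(pw), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  d <- utils::read.table(path, col.names = c("lo", "hi", "slope",
                                             "intercept"))
  piecewise_linear(d$lo, d$hi, d$slope, d$intercept)
}

#' Read and write neuron traces as columnar text
#'
#' Columns `t x y z`, space separated, with a header line.
#'
#' @param trace A `neuron_trace` tibble.
#' @param path File path.
#' @param dt Integration step to attach on read.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   `neuron_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(as.data.frame(trace)[, c("t", "x", "y", "z")], path,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, dt = NULL) {
  d <- tibble::as_tibble(utils::read.table(path, header = TRUE))
  if (is.null(dt)) dt <- d$t[2] - d$t[1]
  spikes <- detect_spikes(d)
  structure(d, dt = dt, spike_times = spikes,
            burst_onsets = detect_bursts(spikes),
            class = c("neuron_trace", class(d)))
}

#' Read and write network weights as a sparse triplet text format
#'
#' One synapse per line: `pre post J delay distance`, with a header.
#'
#' @param net A `burst_network`.
#' @param path File path.
#' @param delay Latency recorded for every synapse (ms).
#' @return `write_weights()` returns `path` invisibly; `read_weights()` a
#'   tibble of the triplets.
#' @export
write_weights <- function(net, path, delay = 1) {
  d <- data.frame(pre = net$syn$pre, post = net$syn$post, J = net$syn$J,
                  delay = delay, distance = net$syn$distance)
  utils::write.table(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE))
}

#' Write a spike array in the columnar event format
#'
#' One event per line: `cell_row cell_col t`.
#'
#' @param spikes A `spike_array`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_events <- function(spikes, path) {
  utils::write.table(as.data.frame(spikes), path, row.names = FALSE)
  invisible(path)
}
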