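#' Plot a piecewise-linear table against its target
#'
#' @param object A [piecewise_linear()] table.
#' @param target Optional vectorized reference function drawn underneath.
#' @param domain Plot interval.
#' @param n Samples.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.piecewise_linear <- function(object, target = NULL,
                                      domain = c(-2, 2), n = 801, ...) {
  x <- seq(domain[1], domain[2], length.out = n)
  d <- tibble::tibble(x = x, approximation = eval_piecewise(object, x))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x))
  if (!is.null(target)) {
    d$target <- target(x)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$target),
                                colour = "steelblue", linewidth = 0.8)
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$approximation),
                         colour = "firebrick") +
    ggplot2::labs(y = "value", title = "piecewise-linear substitution")
}

#' Plot a neuron trace
#'
#' Membrane potential with detected burst onsets marked.
#'
#' @param object A `neuron_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neuron_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$x)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = burst_onsets(object),
                        colour = "firebrick", linetype = "dotted") +
    ggplot2::labs(x = "time (ms)", y = "membrane potential x")
}

#' Plot a dopamine signal and its baseline
#'
#' @param object A `dopamine_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dopamine_signal <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object), c("D", "b_D"),
                           names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "dopaminergic variable")
}

#' Plot a training history
#'
#' @param object A `burstnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burstnet_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch", names_to = "split")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "accuracy (%)")
}

#' Plot a confusion matrix
#'
#' @param object A `burstnet_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burstnet_eval <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$confusion))
  names(d) <- c("true", "predicted", "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "row-normalized confusion matrix")
}
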