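test_that("recurrent wiring follows the Bernoulli connection model", {
  none <- build_network(tiny_config(conn_prob = 0), seed = 1)
  expect_equal(sum(none$syn$type == "recurrent"), 0)

  full <- build_network(tiny_config(conn_prob = 1), seed = 1)
  n <- full$cfg$n_layer2
  expect_equal(sum(full$syn$type == "recurrent"), n * (n - 1))

  cfg <- network_config(n_layer2 = 200)
  net <- build_network(cfg, seed = 2)
  m <- sum(net$syn$type == "recurrent")
  mu <- 0.2 * 200 * 199
  expect_lt(abs(m - mu), 4 * sqrt(mu * 0.8))
  # output and critic projections are fully connected
  expect_equal(sum(net$syn$type == "output"), 200 * cfg$n_out)
  expect_equal(sum(net$syn$type == "critic"), 200 * cfg$n_critic)
  expect_error(build_network(network_config(n_layer2 = 2,
                                            exc_fraction = 0.01)),
               "degenerate")
})

test_that("weights initialize from the configured normal distribution", {
  net <- build_network(network_config(n_layer2 = 300,
                                      readout_weight_sd = 0.2), seed = 4)
  J <- net$syn$J[net$syn$type == "recurrent"]
  expect_lt(abs(mean(J)), 0.01)
  expect_lt(abs(sd(J) - 0.2), 0.01)
})

test_that("distance factors store exp(-r/D) of the grid distances", {
  net <- build_network(tiny_config(), seed = 6)
  rec <- net$syn[net$syn$type == "recurrent", ]
  expect_equal(rec$factor, exp(-rec$distance / net$cfg$distance_scale),
               tolerance = 1e-12)
  expect_true(all(net$syn$factor[net$syn$type != "recurrent"] == 1))
})

test_that("frozen trials leave weights bit-identical and are deterministic", {
  net <- build_network(tiny_config(), seed = 2)
  pats <- tiny_patterns()
  r1 <- tiny_trial(net, pats$image[[1]], label = 0, seed = 10)
  expect_identical(r1$net$syn$J, net$syn$J)
  r2 <- tiny_trial(net, pats$image[[1]], label = 0, seed = 10)
  expect_identical(r1$burst_counts, r2$burst_counts)
  expect_identical(r1$winner, r2$winner)
  expect_identical(r1$gate, r2$gate)
})

test_that("zero input produces no output bursts and no weight change", {
  net <- build_network(tiny_config(rate_max = 0), seed = 2)
  pats <- tiny_patterns()
  rec <- tiny_trial(net, pats$image[[1]], label = 0, seed = 3,
                    learning = TRUE, feedback = TRUE)
  expect_true(all(rec$burst_counts$bursts == 0))
  expect_identical(rec$net$syn$J, net$syn$J)
})

test_that("winner selection is argmax with a logged lowest-index tie-break", {
  expect_equal(classify_bursts(c(6, 1, 1)), list(class = 0L, tie = FALSE))
  expect_equal(classify_bursts(c(2, 2, 2)), list(class = 0L, tie = TRUE))
  expect_equal(classify_bursts(c(1, 5, 2))$class, 1L)
  # permutation equivariance away from ties
  counts <- c(3, 9, 5)
  perm <- c(2, 3, 1)
  expect_equal(perm[classify_bursts(counts[perm])$class + 1L] - 1L,
               classify_bursts(counts)$class)
})

test_that("distance scaling lowers the population burst rate", {
  # with excitation-dominant recurrence, damping coupling with distance
  # must reduce total activity
  pats <- tiny_patterns()
  on <- build_network(tiny_config(use_distance = TRUE, recurrent_gain = 0.5),
                      seed = 3)
  on$syn$J[on$syn$type == "recurrent"] <-
    abs(on$syn$J[on$syn$type == "recurrent"])
  off <- on
  off$syn$factor[off$syn$type == "recurrent"] <- 1
  rate <- function(net) {
    tot <- 0
    for (i in 1:3)
      tot <- tot + sum(lengths(
        tiny_trial(net, pats$image[[i]], label = 0,
                   seed = 40 + i)$bursts_by_neuron[1:40]))
    tot
  }
  expect_lt(rate(on), rate(off))
})

test_that("evaluation reports a row-normalized confusion matrix", {
  net <- build_network(tiny_config(), seed = 2)
  pats <- tiny_patterns()
  ev <- evaluate_network(net, pats, tiny_protocol(), repeats = 1, seed = 5)
  expect_true(all(abs(rowSums(ev$confusion) - 1) < 1e-12))
  expect_equal(nrow(ev$trials), nrow(pats))
  # balanced classes: mean diagonal equals overall accuracy
  expect_equal(100 * mean(diag(ev$confusion)), ev$accuracy, tolerance = 1e-9)
  g <- glance(ev)
  expect_equal(g$accuracy, ev$accuracy)
})

test_that("zero-epoch training changes nothing and history is well-formed", {
  net <- build_network(tiny_config(), seed = 2)
  pats <- tiny_patterns()
  fit <- train_network(net, pats, tiny_protocol(epochs = 0), seed = 3)
  expect_identical(fit$net$syn$J, net$syn$J)
  expect_equal(nrow(fit$history), 0)
})

test_that("training runs end-to-end, updates weights and is reproducible", {
  net <- build_network(tiny_config(), seed = 2)
  pats <- tiny_patterns(n_per_class = 3)
  fit <- train_network(net, pats, tiny_protocol(epochs = 2),
                       keep_best = FALSE, seed = 9)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(c("epoch", "train_accuracy", "holdout_accuracy") %in%
                    names(fit$history)))
  expect_false(identical(fit$net$syn$J, net$syn$J))
  # learned recurrent weights respect the clip
  expect_true(all(abs(fit$net$syn$J) <= plasticity_params()$w_max))
  fit2 <- train_network(net, pats, tiny_protocol(epochs = 2),
                        keep_best = FALSE, seed = 9)
  expect_identical(fit$net$syn$J, fit2$net$syn$J)
  expect_identical(tidy(fit), fit$history)
})

test_that("the plateau rule stops training early when enabled", {
  net <- build_network(tiny_config(rate_max = 0), seed = 2)  # silent -> flat
  pats <- tiny_patterns()
  fit <- train_network(net, pats, tiny_protocol(epochs = 5),
                       auto_stop = TRUE, seed = 4)
  expect_true(fit$stopped_early)
  expect_lt(nrow(fit$history), 5)
})
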