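# shared fixtures: a deliberately tiny network keeps unit tests fast while
# exercising every population and synapse type
tiny_config <- function(...) {
  network_config(n_layer2 = 40, n_out = 3, n_critic = 5,
                 input_shape = c(7, 7), ...)
}

tiny_protocol <- function(...) {
  trial_protocol(eval_window = 150, transient_discard = 20,
                 reward_window = 50, ...)
}

tiny_patterns <- function(n_per_class = 2, seed = 7) {
  make_patterns(3, n_per_class = n_per_class, shape = c(28, 28),
                noise = 0.05, seed = seed)
}

tiny_trial <- function(net, image, label = 0, seed = 1, ...) {
  sp <- encode_image(image, rate_max = net$cfg$rate_max,
                     duration = 170, seed = seed)
  run_trial(net, sp, tiny_protocol(), label = label, seed = seed + 1, ...)
}
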