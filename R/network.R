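#' Network architecture configuration
#'
#' Describes the three-layer classification network plus critic: a
#' pseudo-retinal input layer projecting with fixed weights onto a
#' recurrently connected layer of excitatory (80%) and inhibitory (20%) HR
#' neurons arranged on a rectangular grid, a fully connected output layer
#' of classifying pyramidal neurons, and a fully connected critic
#' population. Recurrent synapses are drawn independently with probability
#' `conn_prob` (all four PY/IN interaction types); trainable weights are
#' initialized from `N(0, weight_sd^2)`.
#'
#' Desk-scale defaults (200 layer-2 neurons) keep simulations tractable;
#' the published architecture (5000 or 10000 layer-2 neurons, 2000 ms
#' evaluation windows) is selectable but long-running.
#'
#' @param n_layer2 Layer-2 population size.
#' @param exc_fraction Fraction of layer-2 neurons that are excitatory.
#' @param conn_prob Recurrent connection probability.
#' @param n_out Number of classifying output neurons (one per class).
#' @param n_critic Critic population size.
#' @param input_shape Ganglion array dimensions, e.g. `c(7, 7)`.
#' @param input_fanout Fraction of layer-2 neurons each ganglion cell
#'   projects to (fixed, non-plastic weights `J_ext`).
#' @param J_ext Input synapse weight (fixed during learning).
#' @param grid_shape Layer-2 grid `c(rows, cols)`; near-square by default.
#' @param distance_scale `D` in the coupling factor `exp(-r/D)`; defaults
#'   to the grid side length.
#' @param use_distance Apply distance-dependent coupling to recurrent
#'   synapses.
#' @param weight_sd Initial weight standard deviation (recurrent
#'   synapses).
#' @param readout_weight_sd Initial weight standard deviation of the
#'   output/critic projections. Larger than `weight_sd` so the untrained
#'   classifiers are driven by layer-2 volleys (and hence emit the burst
#'   pairings that reinforcement learning needs) rather than sitting
#'   silent.
#' @param model Neuron model for all simulated populations: `"lhr"`
#'   (default), `"hr"`, or `"lhr_fixed"` (fixed-point datapath).
#' @param neuron An [hr_params()] list (bias `I` is ignored; drive is
#'   synaptic).
#' @param dt Shared integration step (ms).
#' @param spike_threshold,intra_burst_isi_max Event-detection settings.
#' @param rate_max Ganglion peak firing rate passed to [encode_image()].
#' @param recurrent_gain Scaling of the layer-2 recurrent impulses.
#'   Unit gain makes single recurrent spikes suprathreshold events that
#'   drive the whole population regardless of the stimulus; a sub-unit
#'   gain keeps recurrence perturbative so layer-2 activity stays
#'   stimulus-selective.
#' @param readout_gain Scaling of the layer-2 to output/critic projection
#'   impulses. The double-exponential impulse of a unit-weight spike peaks
#'   near the burst threshold, so unscaled N(0, 0.2) weights make single
#'   presynaptic spikes act as all-or-none kicks on the classifiers; the
#'   gain moves the readout into the mean-driven regime where an output
#'   neuron's drive reflects the summed alignment of its ~200 afferents
#'   with the layer-2 activity pattern. Input and recurrent synapses stay
#'   at full strength (layer 2 works in the strong, event-driven regime).
#' @param eta_l2,eta_out Learning-rate scalings applied to the layer-2
#'   BTDP and output/critic RBTDP batch updates.
#' @param eta_decay Per-epoch learning-rate decay used by
#'   [train_network()]: epoch `k` trains with `eta / (1 + eta_decay *
#'   (k - 1))`, so early epochs explore and late epochs consolidate.
#' @param rpe_rate Baseline drive rate of the reward-prediction-error
#'   population (a.u.), modulated by [reward_emulation()].
#' @param q,dt_shift Fixed-point format and dt shift (`model =
#'   "lhr_fixed"` only).
#' @param output_bias Tonic drive current added to output and critic
#'   neurons. Set just above the bursting threshold of the neuron so the
#'   readout layers burst at a base rate from the start (burst pairings
#'   exist before any learning) and synaptic drive modulates the rate up
#'   or down.
#' @param drive_max Saturation bound on the net synaptic drive delivered
#'   to any neuron (the segment tables only emulate the cubic within their
#'   breakpoint span, and the digital input register is bounded).
#' @param normalize_updates Make each reinforcement batch update zero-sum
#'   across the afferents of every output/critic neuron (per source type),
#'   so reward reallocates drive between inputs instead of changing its
#'   total.
#' @param guard Integration blow-up guard on `|x|`.
#' @return A named list of class `network_config`.
#' @export
network_config <- function(n_layer2 = 200, exc_fraction = 0.8,
                           conn_prob = 0.2, n_out = 3, n_critic = 20,
                           input_shape = c(7, 7), input_fanout = 0.03,
                           J_ext = 1, grid_shape = NULL,
                           distance_scale = NULL, use_distance = TRUE,
                           weight_sd = 0.2, readout_weight_sd = 1,
                           model = c("lhr", "hr", "lhr_fixed"),
                           neuron = hr_params(), dt = 1 / 256,
                           spike_threshold = 0.8, intra_burst_isi_max = 15,
                           rate_max = 40, recurrent_gain = 0.1,
                           readout_gain = 0.05,
                           output_bias = 0,
                           eta_l2 = 0.002, eta_out = 50, eta_decay = 0.5,
                           rpe_rate = 100, q = q_format(), dt_shift = 8,
                           drive_max = 10, normalize_updates = TRUE,
                           guard = 1e3) {
  model <- match.arg(model)
  stopifnot(exc_fraction > 0, exc_fraction < 1,
            conn_prob >= 0, conn_prob <= 1, n_layer2 >= 2, n_out >= 2)
  if (is.null(grid_shape)) {
    side <- ceiling(sqrt(n_layer2))
    grid_shape <- c(ceiling(n_layer2 / side), side)
  }
  if (is.null(distance_scale)) distance_scale <- max(grid_shape)
  structure(list(n_layer2 = n_layer2, exc_fraction = exc_fraction,
                 conn_prob = conn_prob, n_out = n_out, n_critic = n_critic,
                 input_shape = input_shape, input_fanout = input_fanout,
                 J_ext = J_ext, grid_shape = grid_shape,
                 distance_scale = distance_scale,
                 use_distance = use_distance, weight_sd = weight_sd,
                 readout_weight_sd = readout_weight_sd,
                 model = model, neuron = neuron, dt = dt,
                 spike_threshold = spike_threshold,
                 intra_burst_isi_max = intra_burst_isi_max,
                 rate_max = rate_max, recurrent_gain = recurrent_gain,
                 readout_gain = readout_gain,
                 output_bias = output_bias,
                 eta_l2 = eta_l2, eta_out = eta_out,
                 eta_decay = eta_decay,
                 rpe_rate = rpe_rate, q = q, dt_shift = dt_shift,
                 drive_max = drive_max,
                 normalize_updates = normalize_updates, guard = guard),
            class = "network_config")
}

#' Trial timing protocol
#'
#' Each presented pattern is simulated for `transient_discard +
#' eval_window` ms; the initial transient is disregarded and the burst
#' rate of the classifying neurons over the evaluation window decides the
#' winner. A pause separates successive patterns during training (the
#' dynamic equations relax to equilibrium; the simulator restarts each
#' trial from rest, which realizes the same separation), and the reward
#' feedback acts over `reward_window` ms after classification.
#'
#' @param eval_window Burst-rate evaluation window (ms). 500 ms at desk
#'   scale; the published protocol uses 2000 ms.
#' @param transient_discard Initial transient to discard (ms).
#' @param inter_pattern_gap Pause between patterns during training (ms).
#' @param epochs Training epochs.
#' @param reward_window Reward feedback duration (ms).
#' @return A named list of class `trial_protocol`.
#' @export
trial_protocol <- function(eval_window = 500, transient_discard = 50,
                           inter_pattern_gap = 100, epochs = 6,
                           reward_window = 100) {
  stopifnot(eval_window > 0, transient_discard >= 0, epochs >= 0)
  structure(list(eval_window = eval_window,
                 transient_discard = transient_discard,
                 inter_pattern_gap = inter_pattern_gap, epochs = epochs,
                 reward_window = reward_window),
            class = "trial_protocol")
}

# deterministic sub-seed derivation (stays below 2^31)
sub_seed <- function(seed, k) (as.integer(seed) * 48271 + k) %% 2147483587L

#' Build a network instance
#'
#' Draws the seeded random architecture: grid placement of layer-2
#' neurons, Bernoulli(`conn_prob`) recurrent connectivity with
#' distance-dependent coupling factors, fully connected projections to the
#' output and critic layers, and the fixed input wiring (each ganglion
#' cell projects to a random `input_fanout` fraction of layer 2).
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return An object of class `burst_network`: a list with the synapse
#'   table (`pre`, `post`, `J`, `distance`, `factor`, `type`), the input
#'   wiring, neuron types and grid positions.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  n2 <- cfg$n_layer2
  n_exc <- round(cfg$exc_fraction * n2)
  if (n_exc < 1 || n_exc >= n2) rlang::abort("degenerate excitatory split")
  n_out <- cfg$n_out; n_crit <- cfg$n_critic

  # grid positions, randomly assigned so PY/IN interleave spatially
  gs <- cfg$grid_shape
  cells <- with_seed(sub_seed(seed, 1L), sample.int(gs[1] * gs[2], n2))
  pos <- cbind(row = (cells - 1) %/% gs[2] + 1,
               col = (cells - 1) %% gs[2] + 1)

  # recurrent layer-2 synapses: independent Bernoulli over ordered pairs
  keep <- with_seed(sub_seed(seed, 2L),
                    stats::runif(n2 * n2) < cfg$conn_prob)
  pre <- rep(seq_len(n2), each = n2)[keep]
  post <- rep(seq_len(n2), times = n2)[keep]
  self <- pre == post
  pre <- pre[!self]; post <- post[!self]
  m_rec <- length(pre)
  dist <- sqrt(rowSums((pos[pre, , drop = FALSE] -
                        pos[post, , drop = FALSE])^2))
  fac <- if (cfg$use_distance) distance_factor(dist, cfg$distance_scale)
         else rep(1, m_rec)

  # full projections to output and critic
  pre_out <- rep(seq_len(n2), times = n_out)
  post_out <- rep(n2 + seq_len(n_out), each = n2)
  pre_cr <- rep(seq_len(n2), times = n_crit)
  post_cr <- rep(n2 + n_out + seq_len(n_crit), each = n2)

  m_all <- m_rec + length(pre_out) + length(pre_cr)
  sds <- rep(c(cfg$weight_sd, cfg$readout_weight_sd),
             c(m_rec, length(pre_out) + length(pre_cr)))
  J <- with_seed(sub_seed(seed, 3L), stats::rnorm(m_all, 0, sds))

  syn <- tibble::tibble(
    pre = c(pre, pre_out, pre_cr),
    post = c(post, post_out, post_cr),
    J = J,
    distance = c(dist, rep(0, length(pre_out) + length(pre_cr))),
    factor = c(fac, rep(1, length(pre_out) + length(pre_cr))),
    type = rep(c("recurrent", "output", "critic"),
               c(m_rec, length(pre_out), length(pre_cr)))) |>
    dplyr::arrange(.data$pre, .data$post)

  # fixed input wiring
  n_in <- prod(cfg$input_shape)
  fan <- max(1L, round(cfg$input_fanout * n2))
  targets <- with_seed(sub_seed(seed, 4L),
                       lapply(seq_len(n_in),
                              function(i) sample.int(n2, fan)))
  input <- tibble::tibble(cell = rep(seq_len(n_in), each = fan),
                          post = unlist(targets), J = cfg$J_ext)

  structure(list(cfg = cfg, n_exc = n_exc, pos = pos, syn = syn,
                 input = input, seed = seed),
            class = "burst_network")
}

#' @export
print.burst_network <- function(x, ...) {
  cat(sprintf(
    "<burst_network> layer2 %d (%d PY / %d IN), out %d, critic %d, %d synapses\n",
    x$cfg$n_layer2, x$n_exc, x$cfg$n_layer2 - x$n_exc, x$cfg$n_out,
    x$cfg$n_critic, nrow(x$syn)))
  invisible(x)
}

# CSR arrays for the C++ stepper (0-based)
net_csr <- function(net) {
  n2 <- net$cfg$n_layer2
  syn <- net$syn                     # already sorted by pre
  counts <- tabulate(syn$pre, nbins = n2)
  in_counts <- tabulate(net$input$cell, nbins = prod(net$cfg$input_shape))
  ord <- order(net$input$cell)
  g <- ifelse(syn$type == "recurrent", net$cfg$recurrent_gain,
              net$cfg$readout_gain)
  list(src_ptr = as.integer(c(0, cumsum(counts))),
       syn_dst = as.integer(syn$post - 1L),
       syn_w = g * syn$J * syn$factor,
       in_ptr = as.integer(c(0, cumsum(in_counts))),
       in_dst = as.integer(net$input$post[ord] - 1L),
       in_w = net$input$J[ord])
}

#' Run one stimulus trial
#'
#' Integrates every neuron and synapse with the shared step `dt`, counts
#' output bursts over the evaluation window, picks the winner, and — when
#' learning is enabled — applies the batch BTDP update to layer-2
#' recurrent synapses and the dopamine-gated RBTDP update to the
#' output/critic projections. With `feedback` the reward emulation
#' (silence on error, rate doubling on success) shapes the dopamine gate;
#' without it the gate is computed under a neutral reward.
#'
#' @param net A [build_network()] instance.
#' @param spikes A `spike_array` from [encode_image()] (its cells must
#'   match `cfg$input_shape`).
#' @param protocol A [trial_protocol()].
#' @param learning Apply weight updates.
#' @param feedback Apply reward emulation (requires `label`).
#' @param label True class (0-based) or `NA`.
#' @param plasticity A [plasticity_params()].
#' @param critic A [critic_config()].
#' @param seed Integer seed for the reward-noise draw.
#' @return A list of class `trial_record`: `winner` (0-based), `correct`,
#'   `tie`, `burst_counts`, `gate`, `dopamine` (a `dopamine_signal`),
#'   `spikes_by_neuron`, and `net` (the possibly updated network).
#' @export
run_trial <- function(net, spikes, protocol = trial_protocol(),
                      learning = FALSE, feedback = FALSE, label = NA,
                      plasticity = plasticity_params(),
                      critic = critic_config(), seed = 1L) {
  cfg <- net$cfg
  n2 <- cfg$n_layer2; n_out <- cfg$n_out; n_crit <- cfg$n_critic
  duration <- protocol$transient_discard + protocol$eval_window
  n_steps <- round(duration / cfg$dt)

  csr <- net_csr(net)
  ord <- order(spikes$t)
  in_step <- as.integer(floor(spikes$t[ord] / cfg$dt))
  in_cell <- as.integer((spikes$cell_col[ord] - 1L) * attr(spikes, "shape")[1] +
                          spikes$cell_row[ord] - 1L)

  types_pyr <- c(seq_len(n2) <= net$n_exc,      # layer 2
                 rep(TRUE, n_out + n_crit))     # output & critic pyramidal
  tau_m <- ifelse(types_pyr, 20, 10)
  tau_rp <- ifelse(types_pyr, 2, 1)

  cube <- pw_parts(cube_table()); sq <- pw_parts(square_table())
  model_code <- switch(cfg$model, hr = 0L, lhr = 1L, lhr_fixed = 2L)
  fx <- if (model_code == 2L)
    fixed_lhr_model(cfg$neuron, cfg$q, cfg$dt_shift) else list()

  res <- cpp_network_trial(
    n2, net$n_exc, n_out, n_crit,
    csr$src_ptr, csr$syn_dst, csr$syn_w,
    csr$in_ptr, csr$in_dst, csr$in_w,
    in_step, in_cell, n_steps, cfg$dt,
    unlist(cfg$neuron[c("a", "b", "c", "d", "r", "s", "q")]),
    tau_m, tau_rp,
    2, 0.4, 5, 1, 1,                  # AMPA/GABA/latency constants
    cfg$spike_threshold, model_code,
    cube$br, cube$slope, cube$intercept,
    sq$br, sq$slope, sq$intercept,
    # start every neuron at the I = 0 resting state so trials begin
    # without a spurious transient volley (x = q, y = c - d*q^2, z = 0)
    fx, c(-1.618, -12.1, 0), cfg$guard, cfg$drive_max, cfg$output_bias)

  t_sp <- res$spike_step * cfg$dt
  keep <- t_sp >= protocol$transient_discard
  sp_by_neuron <- split(t_sp[keep], factor(res$spike_neuron[keep] + 1L,
                                           levels = seq_len(n2 + n_out + n_crit)))
  bursts <- lapply(sp_by_neuron, detect_bursts,
                   intra_burst_isi_max = cfg$intra_burst_isi_max)

  out_counts <- lengths(bursts[n2 + seq_len(n_out)])
  cls <- classify_bursts(out_counts)
  correct <- if (is.na(label)) NA else cls$class == label

  # dopamine: critic value trace on a 1 ms grid plus the reward window
  crit_bursts <- bursts[n2 + n_out + seq_len(n_crit)]
  dop <- trial_dopamine(crit_bursts, duration, protocol$reward_window,
                        if (feedback) correct else NA, cfg$rpe_rate,
                        critic, seed)

  if (learning) {
    net <- apply_learning(net, bursts, sp_by_neuron, dop$gate,
                          plasticity, protocol)
  }

  list(winner = cls$class, correct = correct, tie = cls$tie,
       burst_counts = tibble::tibble(neuron = seq_len(n_out) - 1L,
                                     bursts = as.integer(out_counts)),
       gate = dop$gate, dopamine = dop$signal,
       spikes_by_neuron = sp_by_neuron, bursts_by_neuron = bursts,
       n_saturations = res$n_saturations, net = net) |>
    structure(class = "trial_record")
}

# value/reward traces -> dopamine signal and scalar gate over the reward
# window. The RPE population is a rate-modulated Poisson source.
trial_dopamine <- function(crit_bursts, duration, reward_window, correct,
                           rpe_rate, critic, seed) {
  bin <- 1                                    # ms
  n_trial <- ceiling(duration / bin)
  n_rw <- ceiling(reward_window / bin)
  n <- n_trial + n_rw
  tgrid <- seq_len(n) * bin
  # population burst rate (Hz) in a trailing 50 ms window, held during reward
  all_b <- unlist(crit_bursts)
  vwin <- 50
  v <- vapply(tgrid, function(tt) {
    sum(all_b > tt - vwin & all_b <= min(tt, duration)) /
      length(crit_bursts) / (vwin / 1000)
  }, numeric(1))
  mult <- reward_emulation(correct, reward_window)$multiplier
  rate <- c(rep(rpe_rate, n_trial), rep(rpe_rate * mult, n_rw))
  lam <- rate * critic$n_rpe_neurons * bin / 1000
  counts <- with_seed(seed, stats::rpois(n, lam))
  r <- counts / (critic$n_rpe_neurons * bin / 1000)
  sig <- dopamine(v, r, dt = bin, cfg = critic)
  # gate in units of the baseline RPE drive, so its scale is independent
  # of rpe_rate (which only sets the Poisson signal-to-noise)
  gate <- mean((sig$D - sig$b_D)[(n_trial + 1):n]) / rpe_rate
  list(signal = sig, gate = gate)
}

# batch weight update at trial end; see the learning rules in plasticity.R
apply_learning <- function(net, bursts, spikes, gate, p, protocol) {
  cfg <- net$cfg
  n2 <- cfg$n_layer2
  isi_mean <- vapply(spikes, function(s) {
    if (length(s) < 2) protocol$eval_window else mean(diff(s))
  }, numeric(1))
  n_b <- lengths(bursts)
  syn <- net$syn
  active <- n_b[syn$pre] > 0 & n_b[syn$post] > 0
  if (!any(active)) return(net)
  idx <- which(active)
  is_inh <- syn$pre[idx] > net$n_exc
  is_out <- syn$type[idx] != "recurrent"
  sig <- isi_mean[syn$post[idx]] - isi_mean[syn$pre[idx]]
  sig <- pmin(pmax(sig, -p$sigma_max), p$sigma_max)
  # inlined per-pairing increment: the Eq.-22-style window (depression
  # amplitude A_minus - sigma/gamma_minus) keeps the pairing sum
  # potentiation-dominant for any sigma; the per-synapse sign variant
  # (A_minus + sigma/gamma_minus, see synaptic_rate_modifier) lets the
  # ISI term flip the net update direction and de-stabilizes
  # reinforcement at desk scale
  dw <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    ibi <- outer(bursts[[syn$post[i]]], bursts[[syn$pre[i]]], "-")
    sum(btdp_window(ibi, sig[k], p))
  }, numeric(1))
  dw[is_inh] <- 0.4 * dw[is_inh]
  dw[is_out] <- gate * dw[is_out]
  eta <- ifelse(is_out, cfg$eta_out, cfg$eta_l2)
  dJ <- eta * dw
  if (isTRUE(cfg$normalize_updates)) {
    # competitive normalization of the reinforcement updates:
    # (1) center across the output population per presynaptic neuron -
    #     a weight tilt shared by every classifier shifts all drives
    #     equally and cannot change the argmax, so only the differential
    #     component is kept;
    # (2) zero-sum per postsynaptic neuron and source type - each
    #     classifier's total drive stays fixed, so reward reallocates
    #     drive between afferents and no output drifts into
    #     depolarization block
    is_out_syn <- syn$type[idx] == "output"
    if (any(is_out_syn)) {
      sub <- idx[is_out_syn]
      mu_pre <- ave(dJ[is_out_syn], syn$pre[sub], FUN = mean)
      dJ[is_out_syn] <- dJ[is_out_syn] - mu_pre
    }
    grp <- interaction(syn$post[idx], is_inh, drop = TRUE)
    mu <- ave(dJ, grp, FUN = mean)
    dJ[is_out] <- dJ[is_out] - mu[is_out]
  }
  syn$J[idx] <- pmin(pmax(syn$J[idx] + dJ, -p$w_max), p$w_max)
  net$syn <- syn
  net
}

#' Winner selection from output burst counts
#'
#' The classifying neuron with the highest burst rate wins; ties are
#' broken deterministically toward the lowest index and flagged.
#'
#' @param counts Integer burst counts per output neuron.
#' @return A list with `class` (0-based winner index) and `tie`.
#' @export
classify_bursts <- function(counts) {
  stopifnot(length(counts) >= 1)
  w <- which.max(counts)
  list(class = as.integer(w - 1L), tie = sum(counts == counts[w]) > 1L)
}

#' Train a network on a labeled pattern set
#'
#' Runs `protocol$epochs` training epochs. Within an epoch the training
#' patterns are presented in random order, each encoded afresh by the
#' pseudo-retina and simulated with learning and reward feedback on.
#' After each epoch the held-out split is evaluated with learning frozen.
#' When `auto_stop` is set, training stops once the epoch-to-epoch
#' improvement in held-out accuracy falls below 0.3 percentage points.
#'
#' @param net A [build_network()] instance.
#' @param dataset Tibble with `label` and `image` columns (see
#'   [make_patterns()]).
#' @param protocol A [trial_protocol()].
#' @param holdout_frac Fraction of each class held out for evaluation.
#' @param plasticity A [plasticity_params()].
#' @param critic A [critic_config()].
#' @param auto_stop Stop at the accuracy plateau.
#' @param keep_best Return the weights of the epoch with the highest
#'   held-out accuracy (early-stopping checkpoint) rather than the last
#'   epoch's; with a stochastic reward signal the final epoch is not
#'   always the best one.
#' @param seed Integer seed driving presentation order, encoding and
#'   reward noise.
#' @return A list of class `burstnet_fit` with elements `net` (trained),
#'   `history` (tibble: `epoch`, `train_accuracy`, `holdout_accuracy`),
#'   `holdout` (the held-out subset) and `stopped_early`.
#' @export
train_network <- function(net, dataset, protocol = trial_protocol(),
                          holdout_frac = 0.25,
                          plasticity = plasticity_params(),
                          critic = critic_config(), auto_stop = FALSE,
                          keep_best = TRUE, seed = 1L) {
  stopifnot(nrow(dataset) > 0)
  split <- holdout_split(dataset, holdout_frac, seed)
  train <- split$train; holdout <- split$holdout
  history <- tibble::tibble(epoch = integer(0), train_accuracy = numeric(0),
                            holdout_accuracy = numeric(0))
  stopped_early <- FALSE
  best_acc <- -Inf
  best_J <- net$syn$J
  trial_no <- 0L
  eta0_out <- net$cfg$eta_out
  eta0_l2 <- net$cfg$eta_l2
  for (ep in seq_len(protocol$epochs)) {
    decay <- 1 / (1 + (net$cfg$eta_decay %||% 0) * (ep - 1))
    net$cfg$eta_out <- eta0_out * decay
    net$cfg$eta_l2 <- eta0_l2 * decay
    ord <- with_seed(sub_seed(seed, 100L + ep), sample.int(nrow(train)))
    n_ok <- 0L
    for (i in ord) {
      trial_no <- trial_no + 1L
      sp <- encode_image(train$image[[i]], rate_max = net$cfg$rate_max,
                         duration = protocol$transient_discard +
                           protocol$eval_window,
                         seed = sub_seed(seed, 1000L + trial_no))
      rec <- run_trial(net, sp, protocol, learning = TRUE, feedback = TRUE,
                       label = train$label[i], plasticity = plasticity,
                       critic = critic,
                       seed = sub_seed(seed, 5000L + trial_no))
      net <- rec$net
      if (isTRUE(rec$correct)) n_ok <- n_ok + 1L
    }
    ev <- evaluate_network(net, holdout, protocol, repeats = 1,
                           seed = sub_seed(seed, 9000L + ep))
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = ep, train_accuracy = 100 * n_ok / nrow(train),
      holdout_accuracy = ev$accuracy))
    if (ev$accuracy > best_acc) {
      best_acc <- ev$accuracy
      best_J <- net$syn$J
    }
    if (auto_stop && ep >= 2) {
      gain <- history$holdout_accuracy[ep] - history$holdout_accuracy[ep - 1]
      if (gain < 0.3) { stopped_early <- TRUE; break }
    }
  }
  net$cfg$eta_out <- eta0_out
  net$cfg$eta_l2 <- eta0_l2
  if (keep_best) net$syn$J <- best_J
  structure(list(net = net, history = history, holdout = holdout,
                 stopped_early = stopped_early),
            class = "burstnet_fit")
}

holdout_split <- function(dataset, holdout_frac, seed) {
  idx_hold <- unlist(lapply(unique(dataset$label), function(cls) {
    rows <- which(dataset$label == cls)
    k <- max(1L, round(holdout_frac * length(rows)))
    with_seed(sub_seed(seed, 7000L + cls), sample(rows, k))
  }))
  list(train = dataset[-idx_hold, ], holdout = dataset[idx_hold, ])
}

#' Evaluate a network with learning frozen
#'
#' Presents every pattern `repeats` times (freshly encoded each time),
#' with weight updates halted, and reports mean accuracy (percent) and
#' the row-normalized confusion matrix. The mean of the confusion-matrix
#' diagonal equals the per-class-balanced accuracy.
#'
#' @inheritParams train_network
#' @param repeats Number of presentations per pattern.
#' @return A list of class `burstnet_eval` with `accuracy` (percent),
#'   `confusion` (row-normalized matrix), and `trials` (per-trial tibble).
#' @export
evaluate_network <- function(net, dataset, protocol = trial_protocol(),
                             repeats = 1, seed = 1L) {
  n_out <- net$cfg$n_out
  rows <- list()
  k <- 0L
  for (rep_i in seq_len(repeats)) {
    for (i in seq_len(nrow(dataset))) {
      k <- k + 1L
      sp <- encode_image(dataset$image[[i]], rate_max = net$cfg$rate_max,
                         duration = protocol$transient_discard +
                           protocol$eval_window,
                         seed = sub_seed(seed, 300L + k))
      rec <- run_trial(net, sp, protocol, learning = FALSE,
                       feedback = FALSE, label = dataset$label[i],
                       seed = sub_seed(seed, 600L + k))
      rows[[k]] <- tibble::tibble(repeat_i = rep_i, item = i,
                                  label = dataset$label[i],
                                  winner = rec$winner,
                                  correct = isTRUE(rec$correct),
                                  tie = rec$tie)
    }
  }
  trials <- dplyr::bind_rows(rows)
  conf <- matrix(0, n_out, n_out,
                 dimnames = list(true = seq_len(n_out) - 1L,
                                 predicted = seq_len(n_out) - 1L))
  for (j in seq_len(nrow(trials)))
    conf[trials$label[j] + 1L, trials$winner[j] + 1L] <-
      conf[trials$label[j] + 1L, trials$winner[j] + 1L] + 1
  rs <- rowSums(conf)
  conf <- conf / ifelse(rs == 0, 1, rs)
  structure(list(accuracy = 100 * mean(trials$correct), confusion = conf,
                 trials = trials),
            class = "burstnet_eval")
}

#' @export
tidy.burstnet_fit <- function(x, ...) x$history

#' @export
glance.burstnet_fit <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history),
                 final_holdout_accuracy =
                   utils::tail(x$history$holdout_accuracy, 1),
                 stopped_early = x$stopped_early)
}

#' @export
glance.burstnet_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 n_trials = nrow(x$trials),
                 mean_diagonal = 100 * mean(diag(x$confusion)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
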