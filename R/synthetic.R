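#' Random ground-truth Laguerre-Volterra MIMO model
#'
#' Draws a MIMO model with a known group-sparsity mask to serve as
#' generating truth for recovery experiments: a fraction `sparsity` of the
#' inputs is zeroed (both first- and second-order blocks) for every output
#' neuron, active first-order coefficients are Gaussian, second-order
#' coefficients are smaller Gaussians, and the feedback kernel is
#' refractory (negative after-potential decaying over ~20 ms), obtained by
#' projecting `-depth * exp(-tau / tau_ref)` onto the feedback basis.
#'
#' @param n_ca3,n_ca1 Input and output neuron counts.
#' @param sparsity Fraction of inputs zeroed per output, in `[0, 1]`.
#' @param kernel_shapes List of scales: `c1_sd`, `c2_sd`,
#'   `baseline_rate_hz` (target mean output rate), `input_rate_hz`
#'   (expected input rate used to centre the bias), `refractory_depth`,
#'   `refractory_tau_bins`.
#' @param seed Integer seed.
#' @param config [glvm_config()] giving the basis family.
#' @return A `mimo_model` whose `$fits` are the generating coefficients;
#'   carries a `$truth` list with the per-output active-input masks.
#' @export
make_ground_truth_model <- function(n_ca3, n_ca1, sparsity = 0.25,
                                    kernel_shapes = list(), seed = 1,
                                    config = glvm_config()) {
  stopifnot(sparsity >= 0, sparsity <= 1)
  ks <- utils::modifyList(
    list(c1_sd = 0.8, c2_sd = 0.05, baseline_rate_hz = 10,
         input_rate_hz = 10, refractory_depth = 4,
         refractory_tau_bins = 10),
    kernel_shapes)
  ffb <- laguerre_basis(config$ff_alpha, config$J, config$memory_bins)
  fbb <- laguerre_basis(config$fb_alpha, config$L, config$fb_memory_bins)
  J <- config$J
  K <- J * (J + 1) / 2
  bin_w <- 0.002
  n_zero <- round(sparsity * n_ca3)
  # refractory feedback: project the target after-potential on the basis
  Bh <- fbb$values[, -1L, drop = FALSE]
  h_target <- -ks$refractory_depth *
    exp(-(seq_len(fbb$memory_bins)) / ks$refractory_tau_bins)
  ch <- drop(solve(tcrossprod(Bh), Bh %*% h_target))
  # moments of the Laguerre features under Bernoulli(p_in) inputs, used to
  # centre the bias so every output sits at the target baseline rate:
  # E v_j = p S_j,  E v_j1 v_j2 = p(1-p) delta_{j1 j2} + p^2 S_j1 S_j2
  p_in <- ks$input_rate_hz * bin_w
  S <- rowSums(ffb$values)
  pairs <- lower_tri_pairs(J)
  Ev1 <- p_in * S
  Ev2 <- p_in * (1 - p_in) * (pairs[, 1L] == pairs[, 2L]) +
    p_in^2 * S[pairs[, 1L]] * S[pairs[, 2L]]
  fits <- vector("list", n_ca1)
  masks <- vector("list", n_ca1)
  withr::with_seed(seed, {
    for (i in seq_len(n_ca1)) {
      zero_in <- if (n_zero > 0) sort(sample.int(n_ca3, n_zero)) else integer(0)
      active <- setdiff(seq_len(n_ca3), zero_in)
      c1 <- matrix(0, n_ca3, J)
      c2s <- matrix(0, n_ca3, K)
      c1[active, ] <- stats::rnorm(length(active) * J, sd = ks$c1_sd)
      c2s[active, ] <- stats::rnorm(length(active) * K, sd = ks$c2_sd)
      drift <- sum(c1 %*% Ev1) + sum(c2s %*% Ev2)
      c0 <- qnorm(ks$baseline_rate_hz * bin_w) - drift
      fit <- glvm_coefficients(c0, c1, c2s, ch, ffb, fbb)
      fits[[i]] <- fit
      masks[[i]] <- list(active = active, zero = zero_in)
    }
  })
  structure(list(fits = fits, cv = NULL, config = config,
                 input_neuron_ids = sprintf("ca3_%02d", seq_len(n_ca3)),
                 output_neuron_ids = sprintf("ca1_%02d", seq_len(n_ca1)),
                 bin_width_s = bin_w, truth = list(masks = masks,
                                                   shapes = ks)),
            class = "mimo_model")
}

#' Specification of a synthetic DNMS session
#'
#' Describes the generating conditions of a delayed-non-match-to-sample
#' session: neuron counts, trial count and left-trial proportion, CA3
#' baseline rates, side-dependent event-locked rate modulation (Gaussian
#' gain bumps), and the ground-truth MIMO model that turns CA3 into CA1.
#'
#' @param n_ca3,n_ca1 Neuron counts per region.
#' @param n_trials Number of sample-phase trials (sessions run ~100).
#' @param p_left Proportion of left trials; the count is
#'   `round(n_trials * p_left)`, assigned deterministically under the seed.
#' @param baseline_rate_hz CA3 baseline rate(s), scalar or per neuron.
#' @param modulation Tibble with columns `neuron`, `side` (`"left"` /
#'   `"right"`), `gain` (peak rate multiple), `center_s`, `width_s`
#'   (Gaussian bump center/sd relative to the event).
#' @param ground_truth A [make_ground_truth_model()] result.
#' @param window_s,bin_width_s Perievent window and bin width.
#' @param seed Integer master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_ca3, n_ca1, n_trials = 100, p_left = 0.5,
                           baseline_rate_hz = 10,
                           modulation = NULL, ground_truth = NULL,
                           window_s = c(-2, 2), bin_width_s = 0.002,
                           seed = 1) {
  baseline_rate_hz <- rep_len(baseline_rate_hz, n_ca3)
  stopifnot(all(baseline_rate_hz >= 0), p_left >= 0, p_left <= 1)
  modulation <- modulation %||%
    tibble::tibble(neuron = integer(0), side = character(0),
                   gain = numeric(0), center_s = numeric(0),
                   width_s = numeric(0))
  structure(list(n_ca3 = n_ca3, n_ca1 = n_ca1, n_trials = n_trials,
                 p_left = p_left, baseline_rate_hz = baseline_rate_hz,
                 modulation = tibble::as_tibble(modulation),
                 ground_truth = ground_truth, window_s = window_s,
                 bin_width_s = bin_width_s, seed = seed),
            class = "synthetic_spec")
}

#' Preset synthetic scenarios
#'
#' Three pinned generating conditions used throughout the test battery:
#' * `easy` — 8 CA3, 4 CA1, 200 trials; 6 of 8 CA3 neurons carry strong
#'   side-selective modulation (gain x3 Gaussian bumps of sd 125 ms, i.e.
#'   ~500 ms of elevated rate, at staggered perievent times).
#' * `null` — same geometry, 100 trials, no modulation at all: left and
#'   right trials are statistically identical and decoding must sit at
#'   chance.
#' * `hard` — 6 CA3, 3 CA1, 100 trials, weak modulation (gain x1.5 in 2
#'   neurons).
#'
#' @param name `"easy"`, `"null"` or `"hard"`.
#' @param seed Master seed for the generator (the ground-truth model uses
#'   a seed derived from it).
#' @return A [synthetic_spec()].
#' @export
scenario_spec <- function(name = c("easy", "null", "hard"), seed = 1) {
  name <- match.arg(name)
  mk_mod <- function(neurons, gain, width_s = 0.125) {
    n <- length(neurons)
    tibble::tibble(
      neuron = neurons,
      side = rep_len(c("left", "right"), n),
      gain = gain,
      center_s = seq(-1, 1, length.out = n),
      width_s = width_s)
  }
  gt_seed <- derive_seed(seed, 101L)
  switch(name,
    easy = synthetic_spec(
      n_ca3 = 8, n_ca1 = 4, n_trials = 200, p_left = 0.5,
      baseline_rate_hz = 10,
      modulation = mk_mod(1:6, gain = 3),
      ground_truth = make_ground_truth_model(8, 4, sparsity = 0.25,
                                             seed = gt_seed),
      seed = seed),
    null = synthetic_spec(
      n_ca3 = 8, n_ca1 = 4, n_trials = 100, p_left = 0.5,
      baseline_rate_hz = 10,
      modulation = NULL,
      ground_truth = make_ground_truth_model(8, 4, sparsity = 0.25,
                                             seed = gt_seed),
      seed = seed),
    hard = synthetic_spec(
      n_ca3 = 6, n_ca1 = 3, n_trials = 100, p_left = 0.5,
      baseline_rate_hz = 8,
      modulation = mk_mod(1:2, gain = 1.5),
      ground_truth = make_ground_truth_model(6, 3, sparsity = 1 / 3,
                                             seed = gt_seed),
      seed = seed))
}

#' Generate a synthetic DNMS session with known ground truth
#'
#' CA3 spikes are drawn as an inhomogeneous Bernoulli process per 2 ms bin
#' with side-dependent Gaussian rate-gain bumps; CA1 spikes are generated
#' by running the ground-truth MIMO model on the CA3 trains
#' ([simulate_output()], one realization per output neuron), so the fitted
#' model faces a well-specified truth. Events are placed so that
#' [extract_perievent_patterns()] recovers the generating windows exactly
#' (spike times sit at bin centers; one sample event per trial, 6 s
#' apart).
#'
#' @param spec A [synthetic_spec()] (or [scenario_spec()]).
#' @return A `dnms_dataset`: list with `$set` (a [spike_train_set()]),
#'   `$labels` (tibble `trial_id`, `label`), `$session`
#'   (the generating `concatenated_session`), `$ground_truth`, `$spec`.
#' @export
generate_dnms_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$ground_truth)) abort("spec has no ground-truth model")
  n3 <- spec$n_ca3; n1 <- spec$n_ca1
  win <- spec$window_s; dt <- spec$bin_width_s
  M <- round((win[2] - win[1]) / dt)
  n_tr <- spec$n_trials
  tgrid <- win[1] + (seq_len(M) - 0.5) * dt # bin centers, event-relative

  # deterministic label assignment
  n_left <- round(n_tr * spec$p_left)
  labels <- integer(n_tr)
  withr::with_seed(derive_seed(spec$seed, 1L), {
    labels[sample.int(n_tr, n_left)] <- 1L
  })

  # per-side rate profiles: baseline x Gaussian gain bumps
  rate_profile <- function(side) {
    R <- matrix(rep(spec$baseline_rate_hz, each = M), nrow = n3,
                ncol = M, byrow = TRUE)
    mod <- spec$modulation[spec$modulation$side == side, ]
    if (nrow(mod)) {
      for (r in seq_len(nrow(mod))) {
        bump <- exp(-(tgrid - mod$center_s[r])^2 / (2 * mod$width_s[r]^2))
        n <- mod$neuron[r]
        R[n, ] <- R[n, ] * (1 + (mod$gain[r] - 1) * bump)
      }
    }
    R
  }
  p_left_mat <- rate_profile("left") * dt
  p_right_mat <- rate_profile("right") * dt
  if (any(p_left_mat >= 1) || any(p_right_mat >= 1)) {
    abort("modulated per-bin probability reaches 1; lower gain or rates",
          class = "memodecode_spec_error")
  }

  inputs <- matrix(0L, nrow = n3, ncol = n_tr * M)
  withr::with_seed(derive_seed(spec$seed, 2L), {
    for (tr in seq_len(n_tr)) {
      pm <- if (labels[tr] == 1L) p_left_mat else p_right_mat
      draw <- matrix(runif(n3 * M), n3, M) < pm
      inputs[, (tr - 1L) * M + seq_len(M)] <- draw
    }
  })
  rownames(inputs) <- spec$ground_truth$input_neuron_ids

  bounds <- as.integer(M * (seq_len(n_tr) - 1L))
  gen_session <- structure(
    list(inputs = inputs, outputs = NULL, segment_bounds = bounds,
         trial_ids = as.character(seq_len(n_tr)), labels = labels,
         bin_width_s = dt),
    class = "concatenated_session")
  outputs <- matrix(0L, nrow = n1, ncol = n_tr * M)
  for (i in seq_len(n1)) {
    sim <- simulate_output(spec$ground_truth$fits[[i]], gen_session,
                           n_realizations = 1,
                           seed = derive_seed(spec$seed, 10L + i))
    outputs[i, ] <- sim$spikes[1L, ]
  }
  rownames(outputs) <- spec$ground_truth$output_neuron_ids
  gen_session$outputs <- outputs

  # spike/event tables with one sample event per trial, 6 s apart
  trial_spacing <- 6
  event_times <- (seq_len(n_tr) - 1L) * trial_spacing + 2
  to_rows <- function(mat, region) {
    idx <- which(mat == 1L, arr.ind = TRUE)
    tr <- (idx[, 2L] - 1L) %/% M + 1L
    bin <- (idx[, 2L] - 1L) %% M
    tibble::tibble(
      trial_id = tr,
      neuron_id = rownames(mat)[idx[, 1L]],
      region = region,
      spike_time_s = event_times[tr] + win[1] + (bin + 0.5) * dt)
  }
  spikes <- dplyr::bind_rows(to_rows(inputs, "CA3"),
                             to_rows(outputs, "CA1"))
  events <- tibble::tibble(
    trial_id = seq_len(n_tr),
    event_code = ifelse(labels == 1L, "LS", "RS"),
    event_time_s = event_times)
  set <- spike_train_set(spikes, events)
  structure(list(set = set,
                 labels = tibble::tibble(trial_id = seq_len(n_tr),
                                         label = labels),
                 session = gen_session,
                 ground_truth = spec$ground_truth,
                 spec = spec),
            class = "dnms_dataset")
}

#' Read a scenario description from YAML
#'
#' Accepts either `preset: easy|null|hard` (plus `seed`), or the full
#' [synthetic_spec()] fields with `modulation` as a list of records; the
#' three preset files ship under
#' `system.file("extdata/scenarios", package = "memodecode")`.
#'
#' @param path YAML file path.
#' @return A [synthetic_spec()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$preset)) {
    return(scenario_spec(y$preset, seed = y$seed %||% 1))
  }
  mod <- if (is.null(y$modulation)) NULL else
    dplyr::bind_rows(lapply(y$modulation, tibble::as_tibble))
  gt <- make_ground_truth_model(
    y$n_ca3, y$n_ca1,
    sparsity = y$sparsity %||% 0.25,
    seed = derive_seed(y$seed %||% 1, 101L))
  synthetic_spec(n_ca3 = y$n_ca3, n_ca1 = y$n_ca1,
                 n_trials = y$n_trials %||% 100,
                 p_left = y$p_left %||% 0.5,
                 baseline_rate_hz = y$baseline_rate_hz %||% 10,
                 modulation = mod, ground_truth = gt,
                 seed = y$seed %||% 1)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `spikes.csv`, `events.csv`, `labels.csv` and
#' `ground_truth_model.json` (all synthetic; the JSON carries the
#' generating coefficients).
#'
#' @param data A [generate_dnms_dataset()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_dnms_dataset <- function(data, dir) {
  stopifnot(inherits(data, "dnms_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spike_times(data$set, dir)
  readr::write_csv(data$labels, file.path(dir, "labels.csv"),
                   progress = FALSE)
  write_mimo_model(data$ground_truth,
                   file.path(dir, "ground_truth_model.json"))
  invisible(dir)
}
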