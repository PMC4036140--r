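# Shared fixture builders; everything is generated in code under fixed
# seeds, nothing is read from disk.

# random binary spatio-temporal patterns with labels
make_patterns <- function(n_trials, n_neurons, M, p = 0.05, seed = 1,
                          labels = NULL) {
  labels <- labels %||% rep_len(c(1L, 0L), n_trials)
  pats <- withr::with_seed(seed, lapply(seq_len(n_trials), function(i) {
    structure(list(
      pattern = matrix(as.integer(stats::runif(n_neurons * M) < p),
                       n_neurons, M),
      label = labels[i], trial_id = i,
      event_code = if (labels[i] == 1L) "LS" else "RS"),
      class = "perievent_pattern")
  }))
  structure(pats, class = "perievent_patterns", bin_width_s = 0.002)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small concatenated session with random inputs/outputs
make_toy_session <- function(n_trials = 4, n_in = 2, n_out = 1, M = 200,
                             p_in = 0.05, p_out = 0.04, seed = 1) {
  pin <- make_patterns(n_trials, n_in, M, p_in, seed = seed)
  pout <- make_patterns(n_trials, n_out, M, p_out, seed = seed + 1)
  concatenate_trials(pin, pout)
}

# tiny spike-train set written fully in code
make_tiny_set <- function() {
  spikes <- data.frame(
    trial_id = c(1, 1, 1, 2, 2),
    neuron_id = c("n1", "n1", "n2", "n1", "n2"),
    region = c("CA3", "CA3", "CA1", "CA3", "CA1"),
    spike_time_s = c(0.10, 0.20, 0.15, 6.30, 6.10))
  events <- data.frame(
    trial_id = c(1, 2),
    event_code = c("LS", "RS"),
    event_time_s = c(2, 8))
  spike_train_set(spikes, events)
}

# a 2-input single-output ground-truth session: input 2 has all-zero
# kernels and a low firing rate; used for support-recovery experiments
make_support_toy <- function(seed, n_tr = 8, M = 400, rate1 = 0.05,
                             rate2 = 0.002, c1_sd = 0.8) {
  cfg <- glvm_config(J = 3, L = 2, ff_alpha = 0.95, fb_alpha = 0.95,
                     memory_bins = 100, fb_memory_bins = 100)
  gt <- make_ground_truth_model(
    2, 1, sparsity = 0, seed = seed, config = cfg,
    kernel_shapes = list(c1_sd = c1_sd, c2_sd = 0.02,
                         input_rate_hz = rate1 / 0.002,
                         baseline_rate_hz = 10))
  gt$fits[[1]]$c1[2, ] <- 0
  gt$fits[[1]]$c2s[2, ] <- 0
  inputs <- withr::with_seed(memodecode:::derive_seed(seed, 3L), {
    rbind(as.integer(stats::runif(n_tr * M) < rate1),
          as.integer(stats::runif(n_tr * M) < rate2))
  })
  ses <- structure(
    list(inputs = inputs, outputs = NULL,
         segment_bounds = as.integer(M * (seq_len(n_tr) - 1L)),
         trial_ids = as.character(seq_len(n_tr)),
         labels = rep(0L, n_tr), bin_width_s = 0.002),
    class = "concatenated_session")
  sim <- simulate_output(gt$fits[[1]], ses, 1,
                         seed = memodecode:::derive_seed(seed, 4L))
  ses$outputs <- matrix(sim$spikes[1, ], 1)
  list(session = ses, truth = gt, config = cfg)
}

# one CV-selected fit on the support toy; returns zeroing indicators
support_toy_run <- function(seed) {
  td <- make_support_toy(seed)
  ffb <- laguerre_basis(0.95, 3, 100)
  fbb <- laguerre_basis(0.95, 2, 100)
  des <- build_design(td$session, ffb, fbb, 1)
  grid <- glvm_lambda_grid(des, n_lambda = 15, min_ratio = 1e-2)
  cv <- cross_validate_lambda(des, lambda_grid = grid, n_folds = 2)
  fit <- fit_miso_glvm(des, lambda = cv$lambda, init = cv$warm_start)
  c(zeroed = all(fit$c1[2, ] == 0) && all(fit$c2s[2, ] == 0),
    active = any(fit$c1[1, ] != 0))
}

# the easy-scenario end-to-end run is expensive; compute it once per test
# session and share across acceptance blocks
.acceptance_cache <- new.env(parent = emptyenv())

get_easy_dataset <- function() {
  if (is.null(.acceptance_cache$dat)) {
    .acceptance_cache$dat <- generate_dnms_dataset(scenario_spec("easy",
                                                                 seed = 42))
  }
  .acceptance_cache$dat
}

get_easy_report <- function() {
  if (is.null(.acceptance_cache$report)) {
    dat <- get_easy_dataset()
    .acceptance_cache$report <- run_full_pipeline(
      dat, pipeline_config(n_realizations = 10, seed = 1))
  }
  .acceptance_cache$report
}
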