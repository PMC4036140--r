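# cut a concatenated neuron x T matrix back into per-trial patterns
session_to_patterns <- function(mat, bounds, labels, trial_ids = NULL,
                                bin_width_s = 0.002) {
  T_total <- ncol(mat)
  starts <- bounds + 1L
  ends <- c(bounds[-1L], T_total)
  trial_ids <- trial_ids %||% as.character(seq_along(starts))
  out <- lapply(seq_along(starts), function(i) {
    structure(list(pattern = mat[, starts[i]:ends[i], drop = FALSE],
                   label = labels[i], trial_id = trial_ids[i],
                   event_code = if (labels[i] == 1L) "LS" else "RS"),
              class = "perievent_pattern")
  })
  structure(out, class = "perievent_patterns", bin_width_s = bin_width_s)
}

#' Out-of-sample memory decoding with nested cross-validation
#'
#' Outer stratified folds give the out-of-sample predictions; within each
#' outer training set the L1 penalty is chosen by the usual four-fold
#' cross-validation, a decoder is fit at that penalty, and the held-out
#' trials are decoded. The per-fold decoders are returned so that they can
#' be applied *unchanged* to other versions of the same trials (e.g.
#' model-predicted output patterns).
#'
#' @param patterns A `perievent_patterns` list (or feature matrix).
#' @param labels Binary labels; default from the patterns.
#' @param basis A [bspline_basis()]; or give `J`/`d` to build one.
#' @param J,d Basis size and degree used when `basis` is missing.
#' @param n_outer Outer folds (default 4).
#' @param n_inner Inner folds for the penalty (default 4).
#' @param seed Fold seed.
#' @param lambda_grid Optional penalty grid.
#' @param n_lambda,min_ratio Grid shape when `lambda_grid` is derived.
#' @return List with `accuracy` (tibble from
#'   [classification_accuracy()]), `per_trial` (tibble `trial`, `fold`,
#'   `truth`, `p_left`, `label`), `fold_models`, `folds`, `basis`.
#' @export
decode_out_of_sample <- function(patterns, labels = NULL, basis = NULL,
                                 J = 20, d = 3, n_outer = 4, n_inner = 4,
                                 seed = 1, lambda_grid = NULL,
                                 n_lambda = 30, min_ratio = 1e-3) {
  labels <- labels %||% pattern_labels(patterns)
  if (is.null(basis)) {
    M <- ncol(patterns[[1]]$pattern) - 1L
    basis <- bspline_basis(m = J - d - 1, d = d, M = M)
  }
  feats <- if (is.matrix(patterns)) patterns else
    project_features(patterns, basis)
  y <- as.numeric(labels)
  plan <- make_trial_splits(seq_len(nrow(feats)), y, n_outer,
                            stratified = TRUE, seed = seed)
  fold_models <- vector("list", n_outer)
  rows <- vector("list", n_outer)
  for (f in seq_len(n_outer)) {
    te <- which(plan$fold == f)
    tr <- which(plan$fold != f)
    grid_f <- lambda_grid %||%
      decoder_lambda_grid(feats[tr, , drop = FALSE], y[tr],
                          n_lambda = n_lambda, min_ratio = min_ratio)
    cv <- cross_validate_decoder(feats[tr, , drop = FALSE], y[tr], basis,
                                 lambda_grid = grid_f,
                                 n_folds = n_inner,
                                 seed = derive_seed(seed, f))
    fit <- fit_decoder(feats[tr, , drop = FALSE], y[tr], basis,
                       lambda = cv$lambda)
    pred <- decode(feats[te, , drop = FALSE], fit)
    fold_models[[f]] <- fit
    rows[[f]] <- tibble::tibble(trial = te, fold = f, truth = y[te],
                                p_left = pred$p_left, label = pred$label)
  }
  per_trial <- dplyr::arrange(dplyr::bind_rows(rows), .data$trial)
  list(accuracy = classification_accuracy(per_trial$truth,
                                          per_trial$label),
       per_trial = per_trial, fold_models = fold_models, folds = plan,
       basis = basis)
}

# apply the (unchanged) per-fold decoders to another pattern set over the
# same trials and folds
apply_fold_models <- function(oos, patterns) {
  feats <- if (is.matrix(patterns)) patterns else
    project_features(patterns, oos$basis)
  rows <- lapply(seq_along(oos$fold_models), function(f) {
    te <- which(oos$folds$fold == f)
    pred <- decode(feats[te, , drop = FALSE], oos$fold_models[[f]])
    tibble::tibble(trial = te, fold = f,
                   truth = as.numeric(oos$folds$label[te]),
                   p_left = pred$p_left, label = pred$label)
  })
  per_trial <- dplyr::arrange(dplyr::bind_rows(rows), .data$trial)
  list(accuracy = classification_accuracy(per_trial$truth,
                                          per_trial$label),
       per_trial = per_trial)
}

#' Free-run prediction of output spatio-temporal patterns
#'
#' Runs every fitted output neuron of a MIMO model in free-run Monte Carlo
#' mode on the session inputs and returns predicted output patterns in two
#' forms: a single realization (the prosthesis-style output) and the
#' per-bin mean spike indicator over `n_realizations` thresholded at 0.5.
#'
#' @param model A [fit_mimo()] (or ground-truth) `mimo_model`.
#' @param session A `concatenated_session` providing inputs and labels.
#' @param n_realizations Realizations for the mean path (default 50).
#' @param seed Integer seed.
#' @return List with `single` and `mean_thresholded`
#'   (`perievent_patterns` lists), plus `p_mean` (outputs x T matrix).
#' @export
predict_ca1_patterns <- function(model, session, n_realizations = 50,
                                 seed = 1) {
  stopifnot(inherits(model, "mimo_model"),
            inherits(session, "concatenated_session"))
  n_out <- length(model$fits)
  T_total <- ncol(session$inputs)
  single <- matrix(0L, n_out, T_total)
  meanth <- matrix(0L, n_out, T_total)
  p_mean <- matrix(0, n_out, T_total)
  for (i in seq_len(n_out)) {
    sim <- simulate_output(model$fits[[i]], session,
                           n_realizations = n_realizations,
                           seed = derive_seed(seed, 31L + i))
    single[i, ] <- sim$spikes[1L, ]
    meanth[i, ] <- as.integer(colMeans(sim$spikes) > 0.5)
    p_mean[i, ] <- sim$p_mean
  }
  rownames(single) <- rownames(meanth) <- rownames(p_mean) <-
    model$output_neuron_ids
  list(single = session_to_patterns(single, session$segment_bounds,
                                    session$labels, session$trial_ids,
                                    session$bin_width_s),
       mean_thresholded = session_to_patterns(meanth,
                                              session$segment_bounds,
                                              session$labels,
                                              session$trial_ids,
                                              session$bin_width_s),
       p_mean = p_mean)
}

#' Configuration of the full encode-decode pipeline
#'
#' @param bin_width_s,window_s Binning and perievent window.
#' @param mimo [glvm_config()] for the signal model.
#' @param decoder_J,decoder_d Decoder basis size and degree (J = 20 is the
#'   typical optimum on 4 s windows).
#' @param decoder_folds Outer and inner decoding folds (default 4).
#' @param decoder_n_lambda,decoder_min_ratio Decoder penalty-grid shape.
#' @param n_realizations Free-run realizations for the mean path.
#' @param predicted_path Which predicted-pattern form the decoder is
#'   evaluated on: `"single"` realization (prosthesis-like; default) or
#'   `"mean_thresholded"`.
#' @param seed Master seed.
#' @return A named list of settings.
#' @export
pipeline_config <- function(bin_width_s = 0.002, window_s = c(-2, 2),
                            mimo = glvm_config(), decoder_J = 20,
                            decoder_d = 3, decoder_folds = 4,
                            decoder_n_lambda = 30,
                            decoder_min_ratio = 1e-3,
                            n_realizations = 50,
                            predicted_path = c("single",
                                               "mean_thresholded"),
                            seed = 1) {
  list(bin_width_s = bin_width_s, window_s = window_s, mimo = mimo,
       decoder_J = decoder_J, decoder_d = decoder_d,
       decoder_folds = decoder_folds,
       decoder_n_lambda = decoder_n_lambda,
       decoder_min_ratio = decoder_min_ratio,
       n_realizations = n_realizations,
       predicted_path = match.arg(predicted_path), seed = seed)
}

#' Run the three-stage encode-decode workflow
#'
#' Stage 1 decodes the memory from the input (CA3) patterns; stage 2 fits
#' the MIMO signal model on the concatenated session and free-run-predicts
#' the output (CA1) patterns; stage 3 decodes the actual CA1 patterns; and
#' stage 4 applies the *same* stage-3 decoders, weights unchanged, to the
#' MIMO-predicted CA1 patterns. A weight-identity assertion guards stage 4
#' against re-fitting.
#'
#' @param data A `dnms_dataset` (from [generate_dnms_dataset()]), or a
#'   [spike_train_set()] containing both regions and sample events.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report (JSON), the
#'   fitted models and the feature matrices (CSV) are written there.
#' @param progress Emit stage messages.
#' @return A `pipeline_report` list: per-stage accuracies with confidence
#'   intervals, chosen penalties, per-output KS results, and the decoder
#'   feature matrices.
#' @export
run_full_pipeline <- function(data, config = pipeline_config(),
                              out_dir = NULL, progress = FALSE) {
  say <- function(...) if (progress) message(sprintf(...))
  if (inherits(data, "dnms_dataset")) {
    set <- data$set
  } else if (inherits(data, "spike_train_set")) {
    set <- data
  } else {
    abort("`data` must be a dnms_dataset or spike_train_set")
  }
  pats_ca3 <- extract_perievent_patterns(set, "CA3", "sample",
                                         config$window_s,
                                         config$bin_width_s)
  pats_ca1 <- extract_perievent_patterns(set, "CA1", "sample",
                                         config$window_s,
                                         config$bin_width_s)
  labels <- pattern_labels(pats_ca3)

  say("stage 1/4: decoding memory from CA3 patterns")
  oos_ca3 <- decode_out_of_sample(pats_ca3, labels, J = config$decoder_J,
                                  d = config$decoder_d,
                                  n_outer = config$decoder_folds,
                                  n_inner = config$decoder_folds,
                                  seed = derive_seed(config$seed, 1L),
                                  n_lambda = config$decoder_n_lambda,
                                  min_ratio = config$decoder_min_ratio)

  say("stage 2/4: fitting the MIMO signal model and predicting CA1")
  session <- concatenate_trials(pats_ca3, pats_ca1)
  mimo <- fit_mimo(session, config$mimo, progress = progress)
  predicted <- predict_ca1_patterns(mimo, session,
                                    n_realizations = config$n_realizations,
                                    seed = derive_seed(config$seed, 2L))
  ks <- lapply(seq_along(mimo$fits), function(i) {
    tr <- predict_intensity(mimo$fits[[i]], session, mode = "teacher",
                            output_neuron = i)
    y <- as.numeric(session$outputs[i, ])
    if (sum(y) < 2) return(NULL)
    ks_time_rescaling(y, clip_prob(tr$p))
  })
  names(ks) <- mimo$output_neuron_ids

  say("stage 3/4: decoding memory from actual CA1 patterns")
  oos_ca1 <- decode_out_of_sample(pats_ca1, labels, J = config$decoder_J,
                                  d = config$decoder_d,
                                  n_outer = config$decoder_folds,
                                  n_inner = config$decoder_folds,
                                  seed = derive_seed(config$seed, 3L),
                                  n_lambda = config$decoder_n_lambda,
                                  min_ratio = config$decoder_min_ratio)

  say("stage 4/4: decoding MIMO-predicted CA1 with unchanged weights")
  w_before <- lapply(oos_ca1$fold_models, function(m) list(m$w0, m$w))
  pred_pats <- predicted[[config$predicted_path]]
  res_pred <- apply_fold_models(oos_ca1, pred_pats)
  w_after <- lapply(oos_ca1$fold_models, function(m) list(m$w0, m$w))
  if (!identical(w_before, w_after)) {
    abort("decoder weights changed during stage 4",
          class = "memodecode_internal_error")
  }

  final_ca1 <- {
    feats <- project_features(pats_ca1, oos_ca1$basis)
    cv <- cross_validate_decoder(
      feats, labels, oos_ca1$basis,
      lambda_grid = decoder_lambda_grid(
        feats, labels, n_lambda = config$decoder_n_lambda,
        min_ratio = config$decoder_min_ratio),
      n_folds = config$decoder_folds,
      seed = derive_seed(config$seed, 4L))
    fit_decoder(feats, labels, oos_ca1$basis, lambda = cv$lambda)
  }
  report <- structure(list(
    accuracies = dplyr::bind_rows(
      dplyr::mutate(oos_ca3$accuracy, source = "CA3", .before = 1),
      dplyr::mutate(oos_ca1$accuracy, source = "CA1_actual", .before = 1),
      dplyr::mutate(res_pred$accuracy, source = "CA1_predicted",
                    .before = 1)),
    decoder = list(J = config$decoder_J, d = config$decoder_d,
                   lambda_ca3 = vapply(oos_ca3$fold_models,
                                       function(m) m$lambda, 0),
                   lambda_ca1 = vapply(oos_ca1$fold_models,
                                       function(m) m$lambda, 0)),
    mimo = list(lambda = vapply(mimo$fits, function(f) f$lambda, 0),
                nll = vapply(mimo$fits,
                             function(f) f$diagnostics$nll, 0)),
    ks = lapply(ks, function(k) if (is.null(k)) NULL else
      list(ks_statistic = k$ks_statistic, band_95 = k$band_95,
           inside_band = k$inside_band, n_intervals = k$n_intervals)),
    per_trial = list(ca3 = oos_ca3$per_trial, ca1 = oos_ca1$per_trial,
                     ca1_predicted = res_pred$per_trial),
    feature_matrix_ca1 = reconstruct_feature_matrix(final_ca1),
    models = list(mimo = mimo, decoder_ca1 = final_ca1),
    config = config), class = "pipeline_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(accuracies = report$accuracies, decoder = report$decoder,
           mimo = report$mimo, ks = report$ks),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    write_mimo_model(mimo, file.path(out_dir, "mimo_model.json"))
    write_decoder(final_ca1, file.path(out_dir, "decoder_ca1.json"))
    utils::write.csv(unclass(report$feature_matrix_ca1),
                     file.path(out_dir, "feature_matrix_ca1.csv"),
                     row.names = FALSE)
  }
  report
}

#' @exportS3Method print pipeline_report
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  acc <- x$accuracies
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-14s accuracy %.3f (%d/%d, 95%% CI %.3f-%.3f)\n",
                acc$source[i], acc$accuracy[i], acc$n_correct[i],
                acc$n[i], acc$ci_lower[i], acc$ci_upper[i]))
  }
  inside <- vapply(x$ks, function(k) isTRUE(k$inside_band), NA)
  cat(sprintf("  KS (teacher-forced): %d/%d output neurons inside the 95%% band\n",
              sum(inside, na.rm = TRUE), length(inside)))
  invisible(x)
}
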