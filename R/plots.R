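#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_tile
#'   geom_ribbon geom_col labs scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' KS plot of a time-rescaling goodness-of-fit result
#'
#' Sorted rescaled quantiles against the uniform positions, with the 95%
#' band; a well-specified intensity keeps the curve inside the band.
#'
#' @param object A [ks_time_rescaling()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ks_result <- function(object, ...) {
  n <- object$n_intervals
  df <- tibble::tibble(uniform = (seq_len(n) - 0.5) / n,
                       rescaled = object$rescaled_quantiles)
  ggplot(df, aes(x = .data$uniform, y = .data$rescaled)) +
    geom_ribbon(aes(ymin = .data$uniform - object$band_95,
                    ymax = .data$uniform + object$band_95),
                fill = "grey85") +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    geom_line(colour = "steelblue") +
    labs(x = "uniform quantile", y = "rescaled interval quantile",
         title = sprintf("KS = %.3f (95%% band %.3f)",
                         object$ks_statistic, object$band_95)) +
    theme_minimal()
}

#' Heatmap of a decoder classification feature matrix
#'
#' Neuron-by-time map of the time-domain decoding weights; zero rows show
#' neurons the sparse decoder ignores, warm/cold colours positive/negative
#' evidence for the left memory.
#'
#' @param object A [reconstruct_feature_matrix()] result.
#' @param bin_width_s Bin width used to label the time axis.
#' @param window_start_s Time of the first column relative to the event.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.feature_matrix <- function(object, bin_width_s = 0.002,
                                    window_start_s = -2, ...) {
  F_mat <- unclass(object)
  df <- tidyr::expand_grid(neuron = seq_len(nrow(F_mat)),
                           bin = seq_len(ncol(F_mat)))
  df$weight <- as.numeric(t(F_mat))[
    (df$neuron - 1L) * ncol(F_mat) + df$bin]
  df$time_s <- window_start_s + (df$bin - 0.5) * bin_width_s
  ggplot(df, aes(x = .data$time_s, y = .data$neuron,
                 fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "black", high = "orange") +
    labs(x = "time from event (s)", y = "neuron",
         fill = "F(n, tau)") +
    theme_minimal()
}

#' Trace plot of model intensity
#'
#' @param object An `intensity_trace` from [predict_intensity()].
#' @param ... Unused.
#' @return A ggplot of the per-bin firing probability.
#' @export
autoplot.intensity_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$bin, y = .data$p)) +
    geom_line(colour = "steelblue") +
    labs(x = "bin", y = "P(spike)") +
    theme_minimal()
}

#' Peri-event time histogram of one neuron
#'
#' Companion to [prescreen_neurons()]: the visual check on event-locked
#' firing that the rate-band filter does not capture.
#'
#' @param s A [spike_train_set()].
#' @param neuron_id Neuron to plot.
#' @param phase `"sample"` or `"nonmatch"`.
#' @param window_s Perievent window.
#' @param binwidth_s Histogram bin width (default 100 ms).
#' @return A ggplot.
#' @export
plot_perievent_histogram <- function(s, neuron_id,
                                     phase = c("sample", "nonmatch"),
                                     window_s = c(-2, 2),
                                     binwidth_s = 0.1) {
  phase <- match.arg(phase)
  codes <- if (phase == "sample") c("LS", "RS") else c("LN", "RN")
  ev <- s$events[s$events$event_code %in% codes, ]
  sp <- s$spikes[s$spikes$neuron_id == neuron_id, ]
  rel <- unlist(lapply(seq_len(nrow(ev)), function(i) {
    d <- sp$spike_time_s[sp$trial_id == ev$trial_id[i]] - ev$event_time_s[i]
    d[d >= window_s[1] & d < window_s[2]]
  }))
  breaks <- seq(window_s[1], window_s[2], by = binwidth_s)
  h <- hist(rel, breaks = breaks, plot = FALSE)
  df <- tibble::tibble(time_s = h$mids,
                       rate_hz = h$counts / (nrow(ev) * binwidth_s))
  ggplot(df, aes(x = .data$time_s, y = .data$rate_hz)) +
    geom_col(fill = "steelblue") +
    labs(x = "time from event (s)", y = "rate (Hz)",
         title = sprintf("neuron %s, %s phase", neuron_id, phase)) +
    theme_minimal()
}

#' Cross-validation curve plot
#'
#' Works for both the signal-model penalty curve (`mean_nll_per_bin`) and
#' the decoder accuracy curve (`mean_accuracy`).
#'
#' @param cv A tibble from [cross_validate_lambda()] or
#'   [cross_validate_decoder()] (`$cv` element).
#' @return A ggplot with a log-scale penalty axis.
#' @export
plot_cv_curve <- function(cv) {
  metric <- setdiff(names(cv), "lambda")[1]
  ggplot(cv, aes(x = .data$lambda, y = .data[[metric]])) +
    geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    labs(x = "penalty (log scale)", y = metric) +
    theme_minimal()
}
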