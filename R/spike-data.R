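#' Spike-train sets
#'
#' A `spike_train_set` bundles the two tables a delayed-non-match-to-sample
#' (DNMS) session produces: a spike table (one row per spike, with trial,
#' neuron, region and time) and a behavioral event table (one row per lever
#' press, coded `LS`/`RS` for left/right sample and `LN`/`RN` for left/right
#' non-match). All model input preparation starts from this container.
#'
#' @param spikes A data frame with columns `trial_id`, `neuron_id`, `region`
#'   (`"CA3"` or `"CA1"`) and `spike_time_s` (seconds, non-negative).
#' @param events A data frame with columns `trial_id`, `event_code`
#'   (`LS`, `RS`, `LN`, `RN`) and `event_time_s`.
#' @return An object of class `spike_train_set` with tibbles `$spikes`,
#'   `$events` and a neuron directory `$neurons` (columns `neuron_id`,
#'   `region`). Spike times are sorted non-decreasingly within each
#'   (trial, neuron).
#' @export
spike_train_set <- function(spikes, events) {
  spikes <- tibble::as_tibble(spikes)
  events <- tibble::as_tibble(events)
  req_s <- c("trial_id", "neuron_id", "region", "spike_time_s")
  req_e <- c("trial_id", "event_code", "event_time_s")
  miss <- setdiff(req_s, names(spikes))
  if (length(miss)) {
    abort(sprintf("spikes table is missing column(s): %s", toString(miss)),
          class = "memodecode_format_error")
  }
  miss <- setdiff(req_e, names(events))
  if (length(miss)) {
    abort(sprintf("events table is missing column(s): %s", toString(miss)),
          class = "memodecode_format_error")
  }
  bad <- which(!(spikes$region %in% c("CA3", "CA1")))
  if (length(bad)) {
    abort(sprintf("unknown region %s in spikes row %d",
                  spikes$region[bad[1]], bad[1]),
          class = "memodecode_validation_error")
  }
  bad <- which(!(events$event_code %in% c("LS", "RS", "LN", "RN")))
  if (length(bad)) {
    abort(sprintf("invalid event_code %s in events row %d",
                  events$event_code[bad[1]], bad[1]),
          class = "memodecode_validation_error")
  }
  bad <- which(spikes$spike_time_s < 0)
  if (length(bad)) {
    abort(sprintf("negative spike time in spikes row %d", bad[1]),
          class = "memodecode_validation_error")
  }
  spikes <- dplyr::arrange(spikes, .data$trial_id, .data$neuron_id,
                           .data$spike_time_s)
  neurons <- dplyr::distinct(spikes, .data$neuron_id, .data$region)
  neurons <- dplyr::arrange(neurons, .data$region, .data$neuron_id)
  structure(
    list(spikes = spikes, events = events, neurons = neurons),
    class = "spike_train_set"
  )
}

#' @exportS3Method print spike_train_set
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d spikes | %d neurons (%d CA3, %d CA1) | %d trials | %d events\n",
    nrow(x$spikes), nrow(x$neurons),
    sum(x$neurons$region == "CA3"), sum(x$neurons$region == "CA1"),
    length(unique(c(x$spikes$trial_id, x$events$trial_id))), nrow(x$events)))
  invisible(x)
}

#' Load spike times and behavioral events from CSV
#'
#' Reads the two session CSVs (UTF-8, header required) and validates them
#' into a [spike_train_set()]. The spikes file must have columns
#' `trial_id,neuron_id,region,spike_time_s`; the events file
#' `trial_id,event_code,event_time_s`.
#'
#' @param spikes_path,events_path Paths to the two CSV files.
#' @return A validated [spike_train_set()].
#' @export
load_spike_times <- function(spikes_path, events_path) {
  spikes <- readr::read_csv(spikes_path, show_col_types = FALSE,
                            progress = FALSE)
  events <- readr::read_csv(events_path, show_col_types = FALSE,
                            progress = FALSE)
  spike_train_set(spikes, events)
}

#' Write a spike-train set to CSV
#'
#' Inverse of [load_spike_times()]: writes `spikes.csv` and `events.csv`
#' under `dir` so that reading them back reproduces the same tables.
#'
#' @param s A [spike_train_set()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_spike_times <- function(s, dir) {
  stopifnot(inherits(s, "spike_train_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "spikes.csv")
  ev <- file.path(dir, "events.csv")
  readr::write_csv(s$spikes, sp, progress = FALSE)
  readr::write_csv(s$events, ev, progress = FALSE)
  invisible(c(spikes = sp, events = ev))
}

#' Pre-screen neurons by session-wide mean firing rate
#'
#' Retains neurons whose mean rate over the session (spike count divided by
#' the session duration, taken as the span from time 0 to the last spike or
#' event) lies inside `[min_rate_hz, max_rate_hz]`. This is the rate-band
#' reduction of the usual unit pre-screening; peri-event histograms are left
#' to visual inspection via [plot_perievent_histogram()].
#'
#' @param s A [spike_train_set()].
#' @param min_rate_hz,max_rate_hz Inclusive rate bounds in Hz;
#'   `max_rate_hz` may be `Inf`.
#' @param duration_s Session duration used as the rate denominator; default
#'   the latest spike or event time.
#' @return A [spike_train_set()] containing only retained neurons, with a
#'   `dropped` attribute (tibble of dropped neurons and their rates).
#' @export
prescreen_neurons <- function(s, min_rate_hz = 0.5, max_rate_hz = 50,
                              duration_s = NULL) {
  stopifnot(inherits(s, "spike_train_set"))
  if (!(max_rate_hz > min_rate_hz) || min_rate_hz < 0) {
    abort("need max_rate_hz > min_rate_hz >= 0")
  }
  duration_s <- duration_s %||%
    max(c(s$spikes$spike_time_s, s$events$event_time_s, 0))
  if (duration_s <= 0) duration_s <- 1
  rates <- dplyr::count(s$spikes, .data$neuron_id, name = "n_spikes")
  rates <- dplyr::left_join(s$neurons, rates, by = "neuron_id")
  rates$n_spikes[is.na(rates$n_spikes)] <- 0L
  rates$rate_hz <- rates$n_spikes / duration_s
  keep <- rates$rate_hz >= min_rate_hz & rates$rate_hz <= max_rate_hz
  dropped <- rates[!keep, ]
  if (!any(keep)) {
    warn("all neurons dropped by rate pre-screening; returning empty set")
  }
  out <- s
  out$spikes <- dplyr::filter(s$spikes,
                              .data$neuron_id %in% rates$neuron_id[keep])
  out$neurons <- s$neurons[s$neurons$neuron_id %in% rates$neuron_id[keep], ]
  attr(out, "dropped") <- tibble::as_tibble(dropped)
  out
}

#' Bin one trial's spike trains into a binary matrix
#'
#' Discretizes spike times into half-open bins
#' `[t_start + i * bin_width_s, t_start + (i+1) * bin_width_s)`, 0-based.
#' Any bin containing one or more spikes is set to 1 (the per-bin Bernoulli
#' model requires a binary series; multiple spikes inside a 2 ms bin are
#' rare at hippocampal rates). Spikes outside `[t_start, t_end)` are
#' ignored.
#'
#' @param s A [spike_train_set()].
#' @param bin_width_s Bin width in seconds (default 0.002).
#' @param t_start,t_end Window bounds in seconds (absolute session time).
#' @param trial_id Which trial to bin.
#' @param neuron_ids Neurons to include, in row order; defaults to all
#'   neurons of `s` in directory order.
#' @return A `binned_spike_matrix`: a binary N x T matrix with attributes
#'   `bin_width_s`, `t0` and `neuron_ids`.
#' @export
bin_spikes <- function(s, bin_width_s = 0.002, t_start, t_end, trial_id,
                       neuron_ids = NULL) {
  stopifnot(inherits(s, "spike_train_set"))
  if (!(t_end > t_start) || bin_width_s <= 0) {
    abort("need t_end > t_start and bin_width_s > 0")
  }
  all_trials <- unique(c(s$spikes$trial_id, s$events$trial_id))
  if (!(trial_id %in% all_trials)) {
    abort(sprintf("unknown trial_id: %s", trial_id),
          class = "memodecode_lookup_error")
  }
  neuron_ids <- neuron_ids %||% s$neurons$neuron_id
  T_bins <- round((t_end - t_start) / bin_width_s)
  mat <- matrix(0L, nrow = length(neuron_ids), ncol = T_bins,
                dimnames = list(neuron_ids, NULL))
  sp <- s$spikes[s$spikes$trial_id == trial_id &
                   s$spikes$neuron_id %in% neuron_ids &
                   s$spikes$spike_time_s >= t_start &
                   s$spikes$spike_time_s < t_end, ]
  if (nrow(sp)) {
    col <- floor((sp$spike_time_s - t_start) / bin_width_s) + 1L
    col <- pmin(col, T_bins) # guard right-edge rounding
    row <- match(sp$neuron_id, neuron_ids)
    mat[cbind(row, col)] <- 1L
  }
  structure(mat, bin_width_s = bin_width_s, t0 = t_start,
            neuron_ids = neuron_ids, class = c("binned_spike_matrix",
                                               class(mat)))
}

#' Extract labeled perievent spike patterns
#'
#' For every trial with exactly one event of the requested phase, cuts the
#' perievent window (default -2 to +2 s around the event) for all neurons
#' of a region and bins it at `bin_width_s`, producing the N x M binary
#' spatio-temporal pattern the decoder consumes (M = 2000 at the defaults).
#' Patterns are labeled by event side: left = 1, right = 0.
#'
#' @param s A [spike_train_set()].
#' @param region `"CA3"` or `"CA1"`.
#' @param phase `"sample"` (events LS/RS) or `"nonmatch"` (LN/RN).
#' @param window_s Length-2 numeric, window relative to the event (seconds).
#' @param bin_width_s Bin width in seconds.
#' @return A `perievent_patterns` list; each element has `$pattern`
#'   (N x M binary matrix), `$label` (1 left / 0 right), `$trial_id`,
#'   `$event_code`. Trials with zero or multiple phase events are skipped
#'   with a warning.
#' @export
extract_perievent_patterns <- function(s, region = c("CA3", "CA1"),
                                       phase = c("sample", "nonmatch"),
                                       window_s = c(-2, 2),
                                       bin_width_s = 0.002) {
  stopifnot(inherits(s, "spike_train_set"))
  region <- match.arg(region)
  phase <- match.arg(phase)
  codes <- if (phase == "sample") c("LS", "RS") else c("LN", "RN")
  neuron_ids <- s$neurons$neuron_id[s$neurons$region == region]
  if (!length(neuron_ids)) {
    abort(sprintf("no %s neurons in this set", region))
  }
  ev <- s$events[s$events$event_code %in% codes, ]
  trials <- unique(ev$trial_id)
  out <- list()
  skipped <- character()
  for (tr in trials) {
    e <- ev[ev$trial_id == tr, ]
    if (nrow(e) != 1L) {
      skipped <- c(skipped, as.character(tr))
      next
    }
    bm <- bin_spikes(s, bin_width_s,
                     t_start = e$event_time_s + window_s[1],
                     t_end = e$event_time_s + window_s[2],
                     trial_id = tr, neuron_ids = neuron_ids)
    out[[length(out) + 1L]] <- structure(
      list(pattern = unclass(bm), label = as.integer(startsWith(e$event_code, "L")),
           trial_id = tr, event_code = e$event_code),
      class = "perievent_pattern")
  }
  if (length(skipped)) {
    warn(sprintf("skipped %d trial(s) without a unique %s event: %s",
                 length(skipped), phase, toString(utils::head(skipped, 5))))
  }
  structure(out, class = "perievent_patterns", region = region,
            phase = phase, window_s = window_s, bin_width_s = bin_width_s)
}

#' Labels of a pattern list
#' @param patterns A `perievent_patterns` list.
#' @return Integer vector of 1 (left) / 0 (right) labels.
#' @export
pattern_labels <- function(patterns) {
  vapply(patterns, function(p) as.integer(p$label), integer(1))
}

#' Concatenate perievent trials into one session
#'
#' Column-binds per-trial input (e.g. CA3) and output (e.g. CA1) patterns in
#' trial order and records the 0-based start index of every trial segment,
#' so that downstream convolutions can reset their history at each boundary
#' (perievent windows are not contiguous in real time).
#'
#' @param patterns_in,patterns_out `perievent_patterns` lists over the same
#'   trials in the same order, with equal column counts.
#' @return A `concatenated_session` with `$inputs` (N_in x T_total),
#'   `$outputs` (N_out x T_total), `$segment_bounds` (0-based start
#'   indices), `$trial_ids`, `$labels` and `$bin_width_s`.
#' @export
concatenate_trials <- function(patterns_in, patterns_out) {
  if (!length(patterns_in)) abort("empty pattern list")
  t_in <- vapply(patterns_in, function(p) as.character(p$trial_id), "")
  t_out <- vapply(patterns_out, function(p) as.character(p$trial_id), "")
  if (!identical(t_in, t_out)) {
    abort("input and output pattern lists cover different trials",
          class = "memodecode_alignment_error")
  }
  M <- unique(c(vapply(patterns_in, function(p) ncol(p$pattern), 0L),
                vapply(patterns_out, function(p) ncol(p$pattern), 0L)))
  if (length(M) != 1L) abort("patterns differ in column count")
  inputs <- do.call(cbind, lapply(patterns_in, `[[`, "pattern"))
  outputs <- do.call(cbind, lapply(patterns_out, `[[`, "pattern"))
  structure(
    list(inputs = inputs, outputs = outputs,
         segment_bounds = as.integer(M * (seq_along(patterns_in) - 1L)),
         trial_ids = t_in,
         labels = pattern_labels(patterns_in),
         bin_width_s = attr(patterns_in, "bin_width_s") %||% 0.002),
    class = "concatenated_session")
}

#' Export a binned matrix as Matrix Market plus JSON sidecar
#'
#' Writes the sparse coordinate form of a binary binned matrix to `path`
#' (MTX) and its binning metadata (bin width, window start, neuron order)
#' to `paste0(path, ".json")`.
#'
#' @param m A `binned_spike_matrix` from [bin_spikes()].
#' @param path Output `.mtx` path.
#' @return Invisibly, the MTX path.
#' @export
write_binned_matrix <- function(m, path) {
  stopifnot(inherits(m, "binned_spike_matrix"))
  Matrix::writeMM(methods::as(Matrix::Matrix(unclass(m), sparse = TRUE),
                              "generalMatrix"), path)
  meta <- list(bin_width_s = attr(m, "bin_width_s"), t0 = attr(m, "t0"),
               neuron_ids = attr(m, "neuron_ids"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
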