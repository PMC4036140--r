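test_that("CSV loading validates and sorts spike tables", {
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "spikes.csv")
  ev <- file.path(dir, "events.csv")

  # empty spikes file with a valid header
  writeLines("trial_id,neuron_id,region,spike_time_s", sp)
  writeLines(c("trial_id,event_code,event_time_s", "1,LS,2"), ev)
  s <- load_spike_times(sp, ev)
  expect_s3_class(s, "spike_train_set")
  expect_equal(nrow(s$spikes), 0)

  # out-of-order times are sorted within (trial, neuron)
  writeLines(c("trial_id,neuron_id,region,spike_time_s",
               "1,n1,CA3,0.1", "1,n1,CA3,0.2", "1,n1,CA3,0.15"), sp)
  s <- load_spike_times(sp, ev)
  expect_equal(s$spikes$spike_time_s, c(0.1, 0.15, 0.2))

  # invalid event code cites the row
  writeLines(c("trial_id,event_code,event_time_s", "1,LS,2", "2,XX,8"), ev)
  expect_error(load_spike_times(sp, ev), "row 2",
               class = "memodecode_validation_error")

  # missing column is a format error; negative time names the row
  writeLines(c("trial_id,neuron_id,spike_time_s", "1,n1,0.1"), sp)
  writeLines(c("trial_id,event_code,event_time_s", "1,LS,2"), ev)
  expect_error(load_spike_times(sp, ev), "region",
               class = "memodecode_format_error")
  writeLines(c("trial_id,neuron_id,region,spike_time_s", "1,n1,CA3,-0.1"),
             sp)
  expect_error(load_spike_times(sp, ev), "row 1",
               class = "memodecode_validation_error")
})

test_that("write then read round-trips a spike-train set", {
  dat <- generate_dnms_dataset(scenario_spec("hard", seed = 3))
  dir <- withr::local_tempdir()
  write_spike_times(dat$set, dir)
  back <- load_spike_times(file.path(dir, "spikes.csv"),
                           file.path(dir, "events.csv"))
  expect_equal(as.data.frame(back$spikes), as.data.frame(dat$set$spikes))
  expect_equal(as.data.frame(back$events), as.data.frame(dat$set$events))
})

test_that("rate pre-screening keeps neurons inside the band", {
  s <- make_tiny_set() # session span 8 s
  # n1 has 3 spikes, n2 has 2: rates 0.375 and 0.25 Hz
  kept <- prescreen_neurons(s, min_rate_hz = 0.3, max_rate_hz = 10)
  expect_equal(kept$neurons$neuron_id, "n1")
  expect_equal(attr(kept, "dropped")$neuron_id, "n2")
  # a 2 Hz neuron is retained in [1, 10]
  sp <- data.frame(trial_id = 1, neuron_id = "a", region = "CA3",
                   spike_time_s = seq(0.5, 50, by = 0.5))
  ev <- data.frame(trial_id = 1, event_code = "LS", event_time_s = 50)
  s2 <- spike_train_set(sp, ev)
  expect_equal(nrow(prescreen_neurons(s2, 1, 10)$neurons), 1)
  # no-op bounds are the identity; all-dropped warns and returns empty
  expect_equal(prescreen_neurons(s, 0, Inf)$neurons, s$neurons)
  expect_warning(out <- prescreen_neurons(s, 100, 200), "dropped")
  expect_equal(nrow(out$neurons), 0)
})

test_that("binning follows half-open 0-based bins with clipping", {
  ev <- data.frame(trial_id = 1, event_code = "LS", event_time_s = 2)
  mk <- function(times) {
    spike_train_set(data.frame(trial_id = 1, neuron_id = "n1",
                               region = "CA3", spike_time_s = times), ev)
  }
  # empty window
  m <- bin_spikes(mk(5), 0.002, t_start = 0, t_end = 0.01, trial_id = 1)
  expect_equal(sum(m), 0)
  expect_equal(ncol(m), 5)
  # spike at 0.003 with delta = 0.002 falls in bin index 1 (0-based)
  m <- bin_spikes(mk(0.003), 0.002, 0, 0.01, 1)
  expect_equal(which(m[1, ] == 1) - 1L, 1L)
  # two spikes in one bin clip to a single 1
  m <- bin_spikes(mk(c(0.0005, 0.0015)), 0.002, 0, 0.01, 1)
  expect_equal(unname(m[1, 1]), 1L)
  expect_equal(sum(m), 1)
  # spikes outside [t_start, t_end) are ignored; sum bounded by count
  m <- bin_spikes(mk(c(0.001, 0.02)), 0.002, 0, 0.01, 1)
  expect_equal(sum(m), 1)
  expect_error(bin_spikes(mk(0.001), 0.002, 0, 0.01, trial_id = 99),
               class = "memodecode_lookup_error")
})

test_that("perievent extraction yields labeled 2000-column patterns", {
  dat <- generate_dnms_dataset(scenario_spec("hard", seed = 5))
  pats <- extract_perievent_patterns(dat$set, "CA3", "sample")
  expect_length(pats, 100)
  expect_true(all(vapply(pats, function(p) ncol(p$pattern), 0L) == 2000L))
  # labels follow the event side: LS -> 1, RS -> 0
  codes <- vapply(pats, function(p) p$event_code, "")
  expect_equal(pattern_labels(pats), as.integer(codes == "LS"))
  # spike exactly at the event time lands in 0-based column 1000
  sp <- data.frame(trial_id = 1, neuron_id = "n1", region = "CA3",
                   spike_time_s = 10)
  ev <- data.frame(trial_id = 1, event_code = "LS", event_time_s = 10)
  p <- extract_perievent_patterns(spike_train_set(sp, ev), "CA3", "sample")
  expect_equal(which(p[[1]]$pattern[1, ] == 1) - 1L, 1000L)
  # trials without a unique sample event are skipped with a warning
  ev2 <- data.frame(trial_id = c(1, 1), event_code = c("LS", "RS"),
                    event_time_s = c(10, 20))
  expect_warning(
    out <- extract_perievent_patterns(spike_train_set(sp, ev2),
                                      "CA3", "sample"),
    "skipped")
  expect_length(out, 0)
})

test_that("trial concatenation records bounds and is sliceable", {
  pin <- make_patterns(2, 3, 2000, seed = 11)
  pout <- make_patterns(2, 2, 2000, seed = 12)
  ses <- concatenate_trials(pin, pout)
  expect_equal(ncol(ses$inputs), 4000)
  expect_equal(ses$segment_bounds, c(0L, 2000L))
  # slicing at the bounds recovers each input pattern exactly
  expect_equal(unname(ses$inputs[, 1:2000]), unname(pin[[1]]$pattern))
  expect_equal(unname(ses$outputs[, 2001:4000]), unname(pout[[2]]$pattern))
  # single trial is the identity with bounds 0
  one <- concatenate_trials(pin[1], pout[1])
  expect_equal(unname(one$inputs), unname(pin[[1]]$pattern))
  expect_equal(one$segment_bounds, 0L)
  # mismatched trials and empty input are errors
  bad <- pin
  bad[[2]]$trial_id <- 99
  expect_error(concatenate_trials(bad, pout),
               class = "memodecode_alignment_error")
  expect_error(concatenate_trials(list(), list()), "empty")
})

test_that("binned matrices export as MTX with a JSON sidecar", {
  s <- make_tiny_set()
  m <- bin_spikes(s, 0.002, 0, 0.5, 1)
  path <- file.path(withr::local_tempdir(), "m.mtx")
  write_binned_matrix(m, path)
  back <- as.matrix(Matrix::readMM(path))
  storage.mode(back) <- "integer"
  expect_equal(unname(back), unname(unclass(m)), ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$bin_width_s, 0.002)
  expect_equal(meta$neuron_ids, attr(m, "neuron_ids"))
})
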