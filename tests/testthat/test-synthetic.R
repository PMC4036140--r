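test_that("ground-truth models are seeded, sparse, and symmetric", {
  cfg <- glvm_config(J = 3, L = 2, memory_bins = 100, fb_memory_bins = 100,
                     ff_alpha = 0.95, fb_alpha = 0.95)
  g1 <- make_ground_truth_model(4, 2, sparsity = 0.5, seed = 7,
                                config = cfg)
  g2 <- make_ground_truth_model(4, 2, sparsity = 0.5, seed = 7,
                                config = cfg)
  expect_equal(lapply(g1$fits, memodecode:::coef_pack),
               lapply(g2$fits, memodecode:::coef_pack))
  # the sparsity mask zeroes whole inputs, both orders
  for (i in 1:2) {
    zero <- g1$truth$masks[[i]]$zero
    expect_length(zero, 2)
    expect_true(all(g1$fits[[i]]$c1[zero, ] == 0))
    expect_true(all(g1$fits[[i]]$c2s[zero, ] == 0))
  }
  # sparsity = 1: outputs depend only on bias and feedback
  gs <- make_ground_truth_model(3, 1, sparsity = 1, seed = 2, config = cfg)
  expect_true(all(gs$fits[[1]]$c1 == 0) && all(gs$fits[[1]]$c2s == 0))
  expect_true(any(gs$fits[[1]]$ch != 0))
  # reconstructed second-order kernels are exactly symmetric
  k <- reconstruct_kernels(g1$fits[[1]])
  expect_equal(k$k2s[1, , ], t(k$k2s[1, , ]))
  # the feedback kernel is refractory (negative at short lags)
  expect_lt(k$h[1], 0)
})

test_that("session generation is deterministic and label-balanced", {
  spec <- scenario_spec("hard", seed = 13)
  d1 <- generate_dnms_dataset(spec)
  d2 <- generate_dnms_dataset(scenario_spec("hard", seed = 13))
  expect_identical(d1$session$inputs, d2$session$inputs)
  expect_identical(d1$session$outputs, d2$session$outputs)
  expect_equal(as.data.frame(d1$set$spikes), as.data.frame(d2$set$spikes))
  # 100 trials at p_left = 0.5 give exactly 50 left labels
  expect_equal(sum(d1$labels$label), 50)
  expect_equal(nrow(d1$labels), 100)
})

test_that("generated CA1 is exactly the model applied to generated CA3", {
  spec <- scenario_spec("hard", seed = 17)
  dat <- generate_dnms_dataset(spec)
  gen <- dat$session
  gen$outputs <- NULL
  for (i in seq_len(spec$n_ca1)) {
    sim <- simulate_output(dat$ground_truth$fits[[i]], gen, 1,
                           seed = memodecode:::derive_seed(spec$seed,
                                                           10L + i))
    expect_identical(unname(sim$spikes[1, ]),
                     unname(dat$session$outputs[i, ]))
  }
  # and perievent extraction reproduces the generating windows exactly
  p3 <- extract_perievent_patterns(dat$set, "CA3", "sample")
  ses <- concatenate_trials(p3,
                            extract_perievent_patterns(dat$set, "CA1",
                                                       "sample"))
  expect_identical(unname(ses$inputs), unname(dat$session$inputs))
  expect_identical(unname(ses$outputs), unname(dat$session$outputs))
})

test_that("modulation controls the left/right difference", {
  # a gain that pushes per-bin probability past 1 is rejected
  spec <- scenario_spec("hard", seed = 1)
  spec$modulation <- tibble::tibble(neuron = 1L, side = "left",
                                    gain = 200, center_s = 0,
                                    width_s = 0.2)
  expect_error(generate_dnms_dataset(spec),
               class = "memodecode_spec_error")
  # null scenario: left and right CA3 rate profiles are indistinguishable
  nul <- generate_dnms_dataset(scenario_spec("null", seed = 23))
  rates <- function(side) {
    idx <- which(nul$labels$label == side)
    cols <- unlist(lapply(idx, function(i) (i - 1) * 2000 + 1:2000))
    mean(nul$session$inputs[, cols])
  }
  expect_equal(rates(1), rates(0), tolerance = 0.03)
})

test_that("scenario YAML presets load and datasets serialize", {
  path <- system.file("extdata", "scenarios", "hard.yaml",
                      package = "memodecode")
  expect_true(nzchar(path))
  spec <- read_scenario_yaml(path)
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(spec$n_ca3, 6)
  dat <- generate_dnms_dataset(spec)
  dir <- withr::local_tempdir()
  write_dnms_dataset(dat, dir)
  expect_true(all(file.exists(file.path(dir,
    c("spikes.csv", "events.csv", "labels.csv",
      "ground_truth_model.json")))))
  gt <- read_mimo_model(file.path(dir, "ground_truth_model.json"))
  expect_equal(gt$fits[[1]]$c1, dat$ground_truth$fits[[1]]$c1,
               tolerance = 1e-12)
})
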