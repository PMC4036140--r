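ffb <- laguerre_basis(0.9, 3, 50)
fbb <- laguerre_basis(0.9, 2, 50)

test_that("intensity prediction matches closed forms and brute force", {
  ses <- make_toy_session(n_trials = 2, M = 150, seed = 31)
  zero <- glvm_coefficients(0, matrix(0, 2, 3), matrix(0, 2, 6), c(0, 0),
                            ffb, fbb)
  tr <- predict_intensity(zero, ses, mode = "input_only")
  expect_true(all(tr$p == 0.5))
  neg <- zero
  neg$c0 <- -5
  tr <- predict_intensity(neg, ses, mode = "input_only")
  expect_equal(unique(tr$p), pnorm(-5))

  # single input spike: brute-force double sum over the kernel lags
  co <- withr::with_seed(32, glvm_coefficients(
    -2, matrix(rnorm(6, sd = 0.5), 2, 3),
    matrix(rnorm(12, sd = 0.2), 2, 6), c(-0.5, 0.3), ffb, fbb))
  imp <- ses
  imp$inputs[,] <- 0L
  imp$inputs[1, 10] <- 1L
  k <- reconstruct_kernels(co)
  tr <- predict_intensity(co, imp, mode = "input_only")
  for (t in c(10, 25, 60, 59 + 2)) {
    x <- as.numeric(imp$inputs[1, 1:t])
    u_bf <- k$k0
    for (tau in 0:min(t - 1, 50)) {
      u_bf <- u_bf + k$k1[1, tau + 1] * x[t - tau]
      for (tau2 in 0:min(t - 1, 50)) {
        u_bf <- u_bf + k$k2s[1, tau + 1, tau2 + 1] * x[t - tau] * x[t - tau2]
      }
    }
    expect_equal(tr$u[t], u_bf, tolerance = 1e-10)
  }

  # teacher-forced mode needs an observed output
  expect_error(predict_intensity(co, imp, mode = "teacher"), "observed")
  tr2 <- predict_intensity(co, imp, mode = "teacher", output_neuron = 1)
  expect_true(all(is.finite(tr2$a)))
})

test_that("free-run simulation is seeded, consistent, and refractory", {
  ses <- make_toy_session(n_trials = 2, M = 500, seed = 33)
  co <- glvm_coefficients(qnorm(0.2), matrix(0, 2, 3), matrix(0, 2, 6),
                          c(0, 0), ffb, fbb)
  # p approximately 0 gives empty realizations
  lo <- co; lo$c0 <- -8
  sim <- simulate_output(lo, ses, n_realizations = 3, seed = 1)
  expect_equal(sum(sim$spikes), 0)
  expect_error(simulate_output(co, ses), "seed")

  # without feedback the empirical rate matches p = 0.2 within 3 s.e.
  sim <- simulate_output(co, ses, n_realizations = 1000, seed = 2)
  se <- sqrt(0.2 * 0.8 / 1000)
  frac_ok <- mean(abs(colMeans(sim$spikes) - 0.2) <= 3 * se)
  expect_gt(frac_ok, 0.99 - 0.02)
  # same seed reproduces the realization exactly
  sim2 <- simulate_output(co, ses, n_realizations = 2, seed = 7)
  sim3 <- simulate_output(co, ses, n_realizations = 2, seed = 7)
  expect_identical(sim2$spikes, sim3$spikes)

  # strongly negative feedback suppresses short inter-spike intervals
  refr <- co
  refr$ch <- drop(solve(tcrossprod(fbb$values[, -1]),
                        fbb$values[, -1] %*% (-6 * exp(-(1:50) / 3))))
  isi_of <- function(s) {
    unlist(apply(s$spikes, 1, function(r) diff(which(r == 1)),
                 simplify = FALSE))
  }
  s_ref <- simulate_output(refr, ses, n_realizations = 30, seed = 3)
  s_ctl <- simulate_output(co, ses, n_realizations = 30, seed = 3)
  frac1 <- function(isi) mean(isi <= 2)
  expect_lt(frac1(isi_of(s_ref)), 0.5 * frac1(isi_of(s_ctl)))
})
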