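test_that("clamped B-spline basis follows the recursion and counts", {
  # degree 0 with one interior knot at 5: indicators of [0,5) and [5,10]
  b0 <- bspline_basis(m = 1, d = 0, M = 10)
  expect_equal(b0$J, 2L)
  expect_equal(b0$values[1, ], as.numeric(0:10 < 5))
  expect_equal(b0$values[2, ], as.numeric(0:10 >= 5))
  # J = m + d + 1
  b <- bspline_basis(m = 16, d = 3, M = 1999)
  expect_equal(b$J, 20L)
  # partition of unity on the whole grid for several (m, d)
  for (cfg in list(c(0, 0), c(3, 1), c(5, 2), c(16, 3), c(40, 3))) {
    bb <- bspline_basis(m = cfg[1], d = cfg[2], M = 500)
    expect_lt(max(abs(colSums(bb$values) - 1)), 1e-10)
    expect_true(all(bb$values >= 0))
  }
})

test_that("basis values agree with splines::splineDesign", {
  for (cfg in list(c(4, 2), c(16, 3), c(10, 1))) {
    b <- bspline_basis(m = cfg[1], d = cfg[2], M = 300)
    ref <- t(splines::splineDesign(b$knots, x = 0:300, ord = cfg[2] + 1))
    expect_lt(max(abs(b$values - ref)), 1e-12)
  }
})

test_that("feature projection is the per-neuron inner product", {
  b <- bspline_basis(m = 6, d = 3, M = 199)
  # zero pattern, impulse, and additivity
  z <- project_features(matrix(0L, 3, 200), b)
  expect_true(all(z == 0))
  imp <- matrix(0L, 3, 200)
  imp[2, 51] <- 1L
  z <- project_features(imp, b)
  expect_equal(unname(z[(b$J + 1):(2 * b$J)]), b$values[, 51])
  expect_true(all(z[-((b$J + 1):(2 * b$J))] == 0))
  two <- imp
  two[2, 120] <- 1L
  imp2 <- matrix(0L, 3, 200)
  imp2[2, 120] <- 1L
  expect_equal(project_features(two, b),
               project_features(imp, b) + project_features(imp2, b))
  expect_error(project_features(matrix(0L, 3, 100), b), "columns")
})

test_that("L1 logistic decoder handles the penalty limits", {
  pats <- make_patterns(24, 4, 200, p = 0.05, seed = 41)
  b <- bspline_basis(m = 2, d = 3, M = 199)
  feats <- project_features(pats, b)
  labs <- pattern_labels(pats)
  # large penalty: all weights zero, probability = class prevalence
  hi <- fit_decoder(feats, labs, b, lambda = 1e6)
  expect_true(all(hi$w == 0))
  expect_equal(unique(decode(feats, hi)$p_left), mean(labs),
               tolerance = 1e-6)
  expect_error(fit_decoder(feats, rep(1, 24), b, 1), "class")

  # linearly separable toy trains to 100% at a tiny penalty
  X <- cbind(c(rep(2, 4), rep(-2, 4)), withr::with_seed(5, rnorm(8)))
  yy <- c(rep(1, 4), rep(0, 4))
  bsep <- bspline_basis(m = 0, d = 1, M = 10)
  fit <- fit_decoder(X, yy, bsep, lambda = 1e-4, n_neurons = 1)
  expect_equal(decode(X, fit)$label, yy)
})

test_that("decoder solution matches an independent L1 path solver", {
  skip_if_not_installed("glmnet")
  pats <- make_patterns(40, 5, 200, p = 0.05, seed = 42)
  b <- bspline_basis(m = 2, d = 3, M = 199)
  X <- project_features(pats, b)
  y <- pattern_labels(pats)
  for (lam in c(8, 2, 0.5)) {
    fit <- fit_decoder(X, y, b, lambda = lam)
    ref <- glmnet::glmnet(X, y, family = "binomial",
                          lambda = lam / nrow(X), standardize = FALSE,
                          thresh = 1e-14, maxit = 1e6)
    expect_lt(max(abs(c(fit$w0, as.numeric(t(fit$w))) -
                        as.numeric(stats::coef(ref)))), 1e-4)
  }
})

test_that("decoder cross-validation picks by held-out accuracy", {
  dat <- generate_dnms_dataset(scenario_spec("hard", seed = 8))
  pats <- extract_perievent_patterns(dat$set, "CA3", "sample")
  b <- bspline_basis(m = 6, d = 3, M = 1999)
  feats <- project_features(pats, b)
  labs <- pattern_labels(pats)
  one <- cross_validate_decoder(feats, labs, b, lambda_grid = 1,
                                seed = 2)
  expect_equal(one$lambda, 1)
  cv <- cross_validate_decoder(feats, labs, b, seed = 2)
  expect_equal(cv$accuracy, max(cv$cv$mean_accuracy))
  # permuted labels decode at chance (binomial 95% band around 0.5)
  perm <- withr::with_seed(3, sample(labs))
  cvp <- cross_validate_decoder(feats, perm, b, seed = 2)
  band <- 1.96 * sqrt(0.25 / length(labs))
  expect_lt(abs(cvp$accuracy - 0.5), band + 0.05)
})

test_that("basis-size selection matches the class-difference timescale", {
  # class difference lives at a ~100-bin timescale: a fine basis is needed
  M <- 1000
  pats <- withr::with_seed(44, lapply(1:40, function(i) {
    lab <- i %% 2L
    p <- rep(0.02, M)
    centers <- if (lab == 1L) c(200, 500, 800) else c(350, 650, 950)
    for (cc in centers) p <- p + 0.10 * exp(-(seq_len(M) - cc)^2 / (2 * 30^2))
    structure(list(pattern = matrix(as.integer(runif(M) < p), 1, M),
                   label = lab, trial_id = i, event_code = "LS"),
              class = "perievent_pattern")
  }))
  class(pats) <- c("perievent_patterns", "list")
  single <- select_J(pats, J_candidates = 20, seed = 5)
  expect_equal(single$J, 20)
  sel <- select_J(pats, J_candidates = c(5, 20, 50), seed = 5)
  expect_equal(max(sel$curve$accuracy),
               sel$curve$accuracy[sel$curve$J == sel$J])
  expect_gt(sel$J, 5) # the coarsest basis cannot resolve the difference
})

test_that("feature-matrix reconstruction is equivalent to feature space", {
  b <- bspline_basis(m = 8, d = 3, M = 499)
  W <- withr::with_seed(45, matrix(rnorm(3 * b$J) *
                                     rbinom(3 * b$J, 1, 0.4), 3, b$J))
  W[2, ] <- 0
  mod <- structure(list(w0 = 0.4, w = W, lambda = 1, basis = b,
                        n_neurons = 3L,
                        label_convention = c(left = 1, right = 0)),
                   class = "decoder_model")
  Fm <- reconstruct_feature_matrix(mod)
  expect_true(all(Fm[2, ] == 0)) # zero-weight neurons give zero rows
  # all-zero weights give the zero matrix
  mod0 <- mod; mod0$w[] <- 0
  expect_true(all(reconstruct_feature_matrix(mod0) == 0))
  # indicator weight reproduces a basis row
  mod1 <- mod0; mod1$w[3, 5] <- 1
  expect_equal(unclass(reconstruct_feature_matrix(mod1))[3, ],
               b$values[5, ])
  # <F, x> == <w, z(x)> on random binary patterns
  for (s in 1:20) {
    x <- withr::with_seed(100 + s,
                          matrix(as.integer(runif(3 * 500) < 0.05), 3, 500))
    lhs <- sum(unclass(Fm) * x)
    rhs <- sum(as.numeric(t(W)) * project_features(x, b))
    expect_lt(abs(lhs - rhs), 1e-8)
  }
})

test_that("decoding follows the logistic rule with boundary to right", {
  b <- bspline_basis(m = 2, d = 3, M = 99)
  mod <- structure(list(w0 = 0, w = matrix(0, 2, b$J), lambda = 0,
                        basis = b, n_neurons = 2L,
                        label_convention = c(left = 1, right = 0)),
                   class = "decoder_model")
  x <- matrix(0L, 2, 100)
  out <- decode(x, mod)
  expect_equal(out$p_left, 0.5)
  expect_equal(out$label, 0L) # exact boundary goes to the right class
  mod$w0 <- 3
  out <- decode(x, mod)
  expect_equal(out$p_left, 1 / (1 + exp(-3)))
  expect_equal(out$label, 1L)
  # P(left) + P(right) = 1 and neuron-permutation invariance
  W <- withr::with_seed(46, matrix(rnorm(2 * b$J), 2, b$J))
  mod$w <- W
  xs <- withr::with_seed(47, matrix(as.integer(runif(200) < 0.1), 2, 100))
  p1 <- decode(xs, mod)$p_left
  modp <- mod
  modp$w <- W[c(2, 1), ]
  p2 <- decode(xs[c(2, 1), ], modp)$p_left
  expect_equal(p1, p2)
  expect_error(decode(matrix(0, 1, 10), mod), "dimension")
})
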