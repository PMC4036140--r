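ffb <- laguerre_basis(0.9, 3, 50)
fbb <- laguerre_basis(0.9, 2, 50)

test_that("likelihood closed forms and additivity hold", {
  ses <- make_toy_session(n_trials = 2, M = 100, seed = 6)
  des <- build_design(ses, ffb, fbb, 1)
  zero <- memodecode:::coef_unpack(numeric(ncol(des$X)), des)
  nl <- glvm_neg_log_likelihood(zero, des)
  expect_equal(nl$nll, length(des$y) * log(2), tolerance = 1e-12)
  # duplicating the data doubles the NLL
  des2 <- des
  des2$X <- rbind(des$X, des$X)
  des2$y <- c(des$y, des$y)
  expect_equal(glvm_neg_log_likelihood(zero, des2)$nll, 2 * nl$nll)
  expect_error(glvm_neg_log_likelihood(zero, des, y = des$y + 0.5),
               "binary")
})

test_that("analytic gradient matches central finite differences", {
  ses <- make_toy_session(n_trials = 2, M = 100, seed = 7)
  des <- build_design(ses, ffb, fbb, 1)
  cvec <- withr::with_seed(8, rnorm(ncol(des$X), sd = 0.2))
  g <- glvm_neg_log_likelihood(cvec, des)$gradient
  eps <- 1e-6
  for (j in sample(seq_along(cvec), 8)) {
    cp <- cvec; cp[j] <- cp[j] + eps
    cm <- cvec; cm[j] <- cm[j] - eps
    fd <- (glvm_neg_log_likelihood(cp, des)$nll -
             glvm_neg_log_likelihood(cm, des)$nll) / (2 * eps)
    expect_equal(g[j], fd, tolerance = 1e-6)
  }
})

test_that("penalty limits: lambda_max zeroes groups, lambda=0 is the MLE", {
  ses <- make_toy_session(n_trials = 4, M = 200, seed = 9)
  des <- build_design(ses, ffb, fbb, 1)
  pen <- unlist(des$groups$penalized)

  lmax <- memodecode:::glvm_lambda_max(des)$lambda_max
  fit_hi <- fit_miso_glvm(des, lambda = lmax * 1.001)
  expect_true(all(memodecode:::coef_pack(fit_hi)[pen] == 0))
  # the model reduces to intercept + feedback
  expect_true(fit_hi$c0 != 0)

  # unpenalized fit matches an independent probit optimizer
  fit0 <- fit_miso_glvm(des, lambda = 0, tol = 1e-12, max_iter = 500)
  ref <- suppressWarnings(
    stats::glm.fit(des$X, des$y, family = stats::binomial("probit"),
                   control = list(epsilon = 1e-12, maxit = 200)))
  expect_lt(max(abs(memodecode:::coef_pack(fit0) - ref$coefficients)), 1e-4)
  # penalized objective at lambda = 0 equals the NLL
  expect_equal(fit0$diagnostics$objective, fit0$diagnostics$nll)
})

test_that("group sparsity endpoints and objective monotonicity", {
  td <- make_support_toy(101)
  ffb2 <- laguerre_basis(0.95, 3, 100)
  fbb2 <- laguerre_basis(0.95, 2, 100)
  des <- build_design(td$session, ffb2, fbb2, 1)
  grid <- glvm_lambda_grid(des, n_lambda = 8, min_ratio = 1e-3)
  pen <- unlist(des$groups$penalized)
  n_active <- integer(length(grid))
  init <- NULL
  objs <- numeric(length(grid))
  for (k in seq_along(grid)) {
    f <- fit_miso_glvm(des, lambda = grid[k], init = init)
    init <- memodecode:::coef_pack(f)
    n_active[k] <- sum(vapply(des$groups$penalized,
                              function(idx) any(init[idx] != 0), NA))
    objs[k] <- f$diagnostics$objective
  }
  expect_equal(n_active[1], 0)                 # all zero at lambda_max
  expect_gt(n_active[length(grid)], 0)         # active at small lambda
  # NLL part can only improve as the penalty relaxes
  expect_true(all(diff(objs) < 1e-6))
})

test_that("penalty cross-validation selects by held-out likelihood", {
  td <- make_support_toy(102)
  ffb2 <- laguerre_basis(0.95, 3, 100)
  fbb2 <- laguerre_basis(0.95, 2, 100)
  des <- build_design(td$session, ffb2, fbb2, 1)
  # singleton grid is returned as-is
  one <- cross_validate_lambda(des, lambda_grid = 0.5, n_folds = 2)
  expect_equal(one$lambda, 0.5)
  # chosen lambda attains the minimum of the reported curve
  cv <- suppressWarnings(cross_validate_lambda(
    des, lambda_grid = glvm_lambda_grid(des, n_lambda = 10,
                                        min_ratio = 1e-2),
    n_folds = 2))
  expect_equal(min(cv$cv$mean_nll_per_bin),
               cv$cv$mean_nll_per_bin[cv$cv$lambda == cv$lambda])
  # U-shape: both grid ends are worse than the interior minimum
  expect_gt(cv$cv$mean_nll_per_bin[1], min(cv$cv$mean_nll_per_bin))
  expect_gt(cv$cv$mean_nll_per_bin[nrow(cv$cv)],
            min(cv$cv$mean_nll_per_bin))
  expect_error(cross_validate_lambda(des, n_folds = 50), "folds")
})

test_that("MIMO fits outputs independently with shared inputs", {
  td <- make_support_toy(103, n_tr = 6)
  ses <- td$session
  ses$outputs <- rbind(ses$outputs,
                       withr::with_seed(11, as.integer(
                         runif(ncol(ses$outputs)) < 0.02)))
  rownames(ses$outputs) <- c("o1", "o2")
  cfg <- glvm_config(J = 3, L = 2, ff_alpha = 0.95, fb_alpha = 0.95,
                     memory_bins = 100, fb_memory_bins = 100,
                     n_lambda = 6, lambda_min_ratio = 1e-2)
  m <- fit_mimo(ses, cfg)
  expect_length(m$fits, 2)
  # permuting the output order permutes the fits but leaves each identical
  ses_perm <- ses
  ses_perm$outputs <- ses$outputs[c(2, 1), ]
  m2 <- fit_mimo(ses_perm, cfg)
  expect_equal(memodecode:::coef_pack(m2$fits[[2]]), memodecode:::coef_pack(m$fits[[1]]),
               tolerance = 1e-8)
  expect_equal(memodecode:::coef_pack(m2$fits[[1]]), memodecode:::coef_pack(m$fits[[2]]),
               tolerance = 1e-8)
  # single output wraps exactly one MISO fit
  ses1 <- ses
  ses1$outputs <- ses$outputs[1, , drop = FALSE]
  m1 <- fit_mimo(ses1, cfg)
  expect_equal(memodecode:::coef_pack(m1$fits[[1]]), memodecode:::coef_pack(m$fits[[1]]),
               tolerance = 1e-8)
  expect_error(fit_mimo(structure(list(inputs = ses$inputs,
                                       outputs = ses$outputs[0, , drop = FALSE],
                                       segment_bounds = ses$segment_bounds,
                                       bin_width_s = 0.002),
                                  class = "concatenated_session"), cfg),
               "output")
})
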