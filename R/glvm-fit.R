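#' Coefficients of a single-output Laguerre-Volterra spiking model
#'
#' Container for the Laguerre-domain coefficients of one output neuron:
#' `c0` (bias / zeroth-order kernel), `c1` (N x J first-order block),
#' `c2s` (N x J(J+1)/2 second-order self block, lower-triangular order
#' (j1, j2 <= j1)), and `ch` (length-L feedback block). The probit noise
#' scale and threshold are fixed at `sigma = 1`, `theta = 0`: only
#' `(c0 - theta) / sigma` is identified, so `c0` absorbs the threshold.
#'
#' @param c0 Scalar bias.
#' @param c1 N x J matrix of first-order coefficients.
#' @param c2s N x J(J+1)/2 matrix of second-order self coefficients.
#' @param ch Length-L feedback coefficient vector.
#' @param ff_basis,fb_basis The [laguerre_basis()] pair the coefficients
#'   refer to.
#' @param lambda Penalty at which the fit was obtained (NA if constructed).
#' @return A `glvm_coefficients` object.
#' @export
glvm_coefficients <- function(c0, c1, c2s, ch, ff_basis, fb_basis,
                              lambda = NA_real_) {
  stopifnot(is.matrix(c1), is.matrix(c2s), nrow(c1) == nrow(c2s))
  J <- ff_basis$n_basis
  stopifnot(ncol(c1) == J, ncol(c2s) == J * (J + 1) / 2,
            length(ch) == fb_basis$n_basis)
  structure(list(c0 = as.numeric(c0), c1 = c1, c2s = c2s,
                 ch = as.numeric(ch), sigma = 1, theta = 0,
                 ff_basis = ff_basis, fb_basis = fb_basis,
                 lambda = lambda, diagnostics = NULL),
            class = "glvm_coefficients")
}

#' @exportS3Method print glvm_coefficients
print.glvm_coefficients <- function(x, ...) {
  nz <- apply(x$c1, 1, function(r) any(r != 0)) |
    apply(x$c2s, 1, function(r) any(r != 0))
  cat(sprintf("<glvm_coefficients> %d inputs (%d active) | J = %d, L = %d | lambda = %s\n",
              nrow(x$c1), sum(nz), ncol(x$c1), length(x$ch),
              format(x$lambda)))
  invisible(x)
}

# pack coefficients into the design's column order and back
coef_pack <- function(coeffs) {
  c(coeffs$c0, as.numeric(t(coeffs$c1)), as.numeric(t(coeffs$c2s)),
    coeffs$ch)
}

coef_unpack <- function(cvec, design) {
  N <- design$n_inputs
  J <- design$ff_basis$n_basis
  K <- J * (J + 1) / 2
  L <- design$fb_basis$n_basis
  c1 <- matrix(cvec[1L + seq_len(N * J)], nrow = N, byrow = TRUE)
  c2s <- matrix(cvec[1L + N * J + seq_len(N * K)], nrow = N, byrow = TRUE)
  ch <- cvec[1L + N * J + N * K + seq_len(L)]
  glvm_coefficients(cvec[1L], c1, c2s, ch, design$ff_basis, design$fb_basis)
}

# probit pieces: negative log-likelihood, gradient and curvature wrt eta
probit_nll_parts <- function(eta, y, what = c("nll", "grad", "curv")) {
  p <- clip_prob(pnorm(eta))
  out <- list()
  if ("nll" %in% what) {
    out$nll <- -sum(y * log(p) + (1 - y) * log1p(-p))
  }
  if (any(c("grad", "curv") %in% what)) {
    phi <- dnorm(eta)
    g <- -(y - p) * phi / (p * (1 - p))
    if ("grad" %in% what) out$grad <- g
    if ("curv" %in% what) {
      # exact -d2 loglik/deta2, bounded in (0, 1) for the probit
      r1 <- phi / p        # inverse Mills for y = 1
      r0 <- phi / (1 - p)  # for y = 0
      curv <- ifelse(y == 1, r1 * (r1 + eta), r0 * (r0 - eta))
      out$curv <- pmin(pmax(curv, 1e-10), 1)
    }
  }
  out
}

#' Penalized likelihood pieces of the spiking model
#'
#' Bernoulli negative log-likelihood of a binary output series under the
#' probit-linked Laguerre-Volterra model, with its exact analytic gradient
#' in coefficient space. Per-bin firing probability is
#' `Phi(c0 + sum c * v)`; probabilities are clipped away from 0 and 1 by
#' 1e-12 so both values stay finite.
#'
#' @param coeffs A [glvm_coefficients()] (or packed numeric vector).
#' @param design A [build_design()] result.
#' @param y Binary output series; defaults to the design's own output.
#' @return List with `nll` (scalar) and `gradient` (length-P vector in
#'   design column order).
#' @export
glvm_neg_log_likelihood <- function(coeffs, design, y = NULL) {
  y <- y %||% design$y
  assert_binary(y)
  if (length(y) != nrow(design$X)) abort("design and y lengths differ")
  cvec <- if (inherits(coeffs, "glvm_coefficients")) coef_pack(coeffs) else coeffs
  eta <- drop(design$X %*% cvec)
  parts <- probit_nll_parts(eta, y, c("nll", "grad"))
  list(nll = parts$nll, gradient = drop(crossprod(design$X, parts$grad)))
}

group_soft_threshold <- function(v, t) {
  nv <- sqrt(sum(v^2))
  if (nv <= t) rep(0, length(v)) else (1 - t / nv) * v
}

# exact minimizer of 1/2 w'Hw - b'w + lambda ||w||_2 for a small block:
# w = 0 iff ||b|| <= lambda, else w = (H + (lambda/||w||) I)^-1 b with
# ||w|| found by monotone root-finding
group_quad_solve <- function(H, b, lambda) {
  if (lambda <= 0) return(drop(solve(H, b)))
  nb <- sqrt(sum(b^2))
  if (nb <= lambda) return(numeric(length(b)))
  ee <- eigen(H, symmetric = TRUE)
  d <- pmax(ee$values, 1e-12)
  bt <- drop(crossprod(ee$vectors, b))
  norm_w <- function(t) sqrt(sum((bt / (d + lambda / t))^2))
  upper <- nb / min(d)
  f <- function(t) norm_w(t) - t
  t_star <- stats::uniroot(f, lower = upper * 1e-12, upper = upper,
                           tol = 1e-12 * max(upper, 1))$root
  drop(ee$vectors %*% (bt / (d + lambda / t_star)))
}

penalty_value <- function(cvec, groups, lambda) {
  if (lambda == 0) return(0)
  lambda * sum(vapply(groups$penalized,
                      function(idx) sqrt(sum(cvec[idx]^2)), 0))
}

#' Fit one output neuron by group-LASSO penalized probit likelihood
#'
#' Minimizes `-l(c) + lambda * sum_g ||c_g||_2` where the groups are each
#' input's first-order coefficient block and each input's second-order
#' block; the bias `c0` and the feedback block `ch` are unpenalized. The
#' optimizer alternates an outer quadratic (IRLS-type) approximation using
#' the exact probit curvature with an inner block coordinate descent: a
#' damped Newton step for the unpenalized block and a group soft-threshold
#' proximal step for every penalized group, with curvature-inflation
#' backtracking that keeps the penalized objective monotonically
#' non-increasing.
#'
#' @param design A [build_design()] result.
#' @param y Binary output series (defaults to the design's output).
#' @param lambda Non-negative penalty weight.
#' @param tol Convergence tolerance on the relative objective change.
#' @param max_iter Maximum outer iterations.
#' @param init Optional warm-start packed coefficient vector.
#' @param H_env Optional environment carrying the curvature metric across
#'   warm-started path fits (internal speed-up; safe to omit).
#' @return A [glvm_coefficients()] with a `$diagnostics` list
#'   (`objective`, `nll`, `n_iter`, `converged`, `lambda`).
#' @export
fit_miso_glvm <- function(design, y = NULL, lambda = 0, tol = 1e-6,
                          max_iter = 200, init = NULL, H_env = NULL) {
  stopifnot(inherits(design, "glvm_design"), lambda >= 0)
  y <- y %||% design$y
  assert_binary(y)
  X <- design$X
  groups <- design$groups
  P <- ncol(X)
  cvec <- init %||% numeric(P)
  eta <- if (is.null(init)) numeric(nrow(X)) else drop(X %*% cvec)

  obj_of <- function(eta, cvec) {
    probit_nll_parts(eta, y, "nll")$nll + penalty_value(cvec, groups, lambda)
  }
  obj <- obj_of(eta, cvec)
  blocks <- c(list(unpenalized = groups$unpenalized), groups$penalized)
  block_lambda <- c(0, rep(lambda, length(groups$penalized)))
  P_cols <- ncol(X)
  # curvature metric H = X' D X, refreshed lazily: warm starts along a
  # penalty path reuse it (proximal quasi-Newton); a damped line search or
  # old age forces a refresh at the current iterate
  if (is.null(H_env)) H_env <- new.env(parent = emptyenv())
  refresh_H <- function(D) {
    H_env$H <- crossprod(X * sqrt(D)) + diag(1e-8, P_cols)
    H_env$age <- 0L
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    parts <- probit_nll_parts(eta, y, "grad")
    if (is.null(H_env$H) || (H_env$age %||% 0L) >= 25L) {
      refresh_H(probit_nll_parts(eta, y, "curv")$curv)
    }
    H <- H_env$H
    H_env$age <- H_env$age + 1L
    grad_c <- drop(crossprod(X, parts$grad))
    q <- drop(H %*% cvec) - grad_c # surrogate: 1/2 c'Hc - q'c + penalty
    # inner block coordinate descent with the exact group-penalized
    # block minimizer
    c_try <- cvec
    Hc <- drop(H %*% c_try)
    for (sweep in 1:100) {
      max_move <- 0
      for (g in seq_along(blocks)) {
        idx <- blocks[[g]]
        Hgg <- H[idx, idx, drop = FALSE]
        bg <- q[idx] - Hc[idx] + drop(Hgg %*% c_try[idx])
        newc <- group_quad_solve(Hgg, bg, block_lambda[g])
        dc <- newc - c_try[idx]
        if (any(dc != 0)) {
          Hc <- Hc + drop(H[, idx, drop = FALSE] %*% dc)
          c_try[idx] <- newc
          max_move <- max(max_move, max(abs(dc)))
        }
      }
      if (max_move < 1e-10 * (1 + max(abs(c_try)))) break
    }
    eta_m <- eta + drop(X %*% (c_try - cvec))
    # line search on the true penalized objective (convex in c)
    step <- 1
    repeat {
      c_new <- cvec + step * (c_try - cvec)
      eta_new <- eta + step * (eta_m - eta)
      obj_new <- obj_of(eta_new, c_new)
      if (obj_new <= obj + 1e-9 * (abs(obj) + 1) || step < 1e-8) break
      step <- step / 2
    }
    if (obj_new > obj + 1e-6 * (abs(obj) + 1)) {
      abort("penalized objective increased and backtracking failed",
            class = "memodecode_internal_error")
    }
    if (step < 1) { # stale metric: refresh at the accepted iterate
      H_env$H <- NULL
    }
    delta_obj <- obj - obj_new
    # a damped step breaks exact group zeros; keep them exact when the
    # full step was accepted
    cvec <- if (step == 1) c_try else c_new
    eta <- if (step == 1) eta_m else eta_new
    obj <- obj_new
    if (delta_obj >= 0 && delta_obj < tol * (abs(obj) + 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("group-LASSO probit fit did not converge in %d iterations (objective %.6g)",
                 max_iter, obj))
  }
  out <- coef_unpack(cvec, design)
  out$lambda <- lambda
  out$diagnostics <- list(objective = obj,
                          nll = probit_nll_parts(eta, y, "nll")$nll,
                          n_iter = it, converged = converged,
                          lambda = lambda)
  out
}

# smallest lambda that zeroes every penalized group: the largest group
# gradient norm at the null (intercept + feedback only) solution
glvm_lambda_max <- function(design, y = NULL, tol = 1e-8) {
  y <- y %||% design$y
  X <- design$X
  groups <- design$groups
  cvec <- numeric(ncol(X))
  eta <- numeric(nrow(X))
  Xu <- X[, groups$unpenalized, drop = FALSE]
  for (i in 1:100) { # Newton on the unpenalized block only
    parts <- probit_nll_parts(eta, y, c("nll", "grad", "curv"))
    gu <- drop(crossprod(Xu, parts$grad))
    Hu <- crossprod(Xu, Xu * parts$curv) + diag(1e-8, ncol(Xu))
    delta <- drop(solve(Hu, -gu))
    step <- 1
    repeat {
      eta_try <- eta + drop(Xu %*% (step * delta))
      if (probit_nll_parts(eta_try, y, "nll")$nll <= parts$nll + 1e-12 ||
          step < 1e-6) break
      step <- step / 2
    }
    cvec[groups$unpenalized] <- cvec[groups$unpenalized] + step * delta
    eta <- eta + drop(Xu %*% (step * delta))
    if (sqrt(sum(gu^2)) < tol * (abs(parts$nll) + 1)) break
  }
  g_eta <- probit_nll_parts(eta, y, "grad")$grad
  lam <- max(vapply(groups$penalized, function(idx) {
    sqrt(sum(drop(crossprod(X[, idx, drop = FALSE], g_eta))^2))
  }, 0))
  list(lambda_max = lam, null_coef = cvec)
}

#' Default penalty grid for the spiking model
#'
#' Thirty log-spaced values from the analytic `lambda_max` (the smallest
#' penalty that zeroes every group at the null model) down four decades.
#'
#' @param design A [build_design()] result.
#' @param y Binary output series.
#' @param n_lambda Grid length.
#' @param min_ratio Ratio of the smallest to the largest grid value.
#' @return Decreasing numeric vector of penalties.
#' @export
glvm_lambda_grid <- function(design, y = NULL, n_lambda = 30,
                             min_ratio = 1e-4) {
  lmax <- glvm_lambda_max(design, y)$lambda_max
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Two-fold cross-validation of the group-LASSO penalty
#'
#' Splits the trial segments into `n_folds` contiguous blocks, fits the
#' penalty path on each training block with warm starts, and scores the
#' mean held-out negative log-likelihood per bin. Returns the penalty
#' minimizing the mean held-out NLL; ties go to the larger (sparser)
#' penalty.
#'
#' @param design A [build_design()] result.
#' @param y Binary output series.
#' @param lambda_grid Decreasing penalty grid; default [glvm_lambda_grid()].
#' @param n_folds Number of contiguous segment folds (default 2).
#' @param seed Unused for contiguous folds; kept for interface stability.
#' @param tol,max_iter Passed to [fit_miso_glvm()].
#' @return List with `lambda` (chosen), `cv` (tibble of `lambda`,
#'   `mean_nll_per_bin`), and `lambda_grid`.
#' @export
cross_validate_lambda <- function(design, y = NULL, lambda_grid = NULL,
                                  n_folds = 2, seed = NULL, tol = 1e-6,
                                  max_iter = 200) {
  y <- y %||% design$y
  n_seg <- length(design$segment_bounds)
  if (n_seg < n_folds) abort("fewer trial segments than folds")
  lambda_grid <- lambda_grid %||% glvm_lambda_grid(design, y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  starts <- design$segment_bounds + 1L
  ends <- c(design$segment_bounds[-1L], nrow(design$X))
  fold_of_seg <- cut(seq_len(n_seg), breaks = n_folds, labels = FALSE)
  held_nll <- matrix(NA_real_, nrow = n_folds, ncol = length(lambda_grid))
  held_n <- numeric(n_folds)
  warm1 <- matrix(0, nrow = length(lambda_grid), ncol = ncol(design$X))
  for (f in seq_len(n_folds)) {
    test_rows <- unlist(lapply(which(fold_of_seg == f),
                               function(s) starts[s]:ends[s]))
    train_rows <- setdiff(seq_len(nrow(design$X)), test_rows)
    sub <- design
    sub$X <- design$X[train_rows, , drop = FALSE]
    sub$y <- y[train_rows]
    # segment bookkeeping is only used for fold construction; the features
    # themselves are segment-local, so row subsetting keeps them valid
    sub$segment_bounds <- 0L
    Xte <- design$X[test_rows, , drop = FALSE]
    yte <- y[test_rows]
    held_n[f] <- length(test_rows)
    init <- NULL
    H_env <- new.env(parent = emptyenv())
    for (k in seq_along(lambda_grid)) {
      fit <- fit_miso_glvm(sub, sub$y, lambda_grid[k], tol = tol,
                           max_iter = max_iter, init = init, H_env = H_env)
      init <- coef_pack(fit)
      if (f == 1L) warm1[k, ] <- init
      eta_te <- drop(Xte %*% init)
      held_nll[f, k] <- probit_nll_parts(eta_te, yte, "nll")$nll /
        length(yte)
    }
  }
  mean_nll <- colMeans(held_nll)
  best <- which(mean_nll <= min(mean_nll) + 1e-12)[1L] # grid is decreasing
  list(lambda = lambda_grid[best],
       cv = tibble::tibble(lambda = lambda_grid,
                           mean_nll_per_bin = mean_nll),
       lambda_grid = lambda_grid,
       warm_start = warm1[best, ])
}

#' Fit the full MIMO model, one penalized probit fit per output neuron
#'
#' A MIMO model is a concatenation of independent single-output models: for
#' every output neuron the penalty is chosen by contiguous two-fold
#' cross-validation and the final fit uses the whole session. One
#' coefficient set serves both left and right trials.
#'
#' @param session A [concatenate_trials()] result.
#' @param config List of settings; see [glvm_config()].
#' @param progress Print one line per output neuron.
#' @return A `mimo_model`: list with `$fits` (per-output
#'   [glvm_coefficients()]), `$cv` (per-output CV tables), `$config`,
#'   `$input_neuron_ids`, `$output_neuron_ids`.
#' @export
fit_mimo <- function(session, config = glvm_config(), progress = FALSE) {
  stopifnot(inherits(session, "concatenated_session"))
  n_out <- nrow(session$outputs)
  if (n_out < 1) abort("session has no output neurons")
  ffb <- laguerre_basis(config$ff_alpha, config$J, config$memory_bins)
  fbb <- laguerre_basis(config$fb_alpha, config$L, config$fb_memory_bins)
  fits <- vector("list", n_out)
  cvs <- vector("list", n_out)
  des <- NULL
  for (i in seq_len(n_out)) {
    # input features are shared across outputs; only the feedback columns
    # and the response change
    des <- if (is.null(des)) build_design(session, ffb, fbb,
                                          output_neuron = i)
           else update_design_output(des, session, i)
    grid <- config$lambda_grid %||%
      glvm_lambda_grid(des, n_lambda = config$n_lambda,
                       min_ratio = config$lambda_min_ratio)
    cv <- cross_validate_lambda(des, lambda_grid = grid,
                                n_folds = config$n_folds,
                                tol = config$cv_tol %||% config$tol,
                                max_iter = config$max_iter)
    # final fit on the full session, warm-started from the fold solution
    # at the chosen penalty (the objective is convex: the optimum does not
    # depend on the start)
    fit <- fit_miso_glvm(des, lambda = cv$lambda, tol = config$tol,
                         max_iter = config$max_iter,
                         init = cv$warm_start)
    fits[[i]] <- fit
    cvs[[i]] <- cv$cv
    if (progress) {
      message(sprintf("output %d/%d: lambda = %.4g, NLL = %.1f",
                      i, n_out, cv$lambda, fit$diagnostics$nll))
    }
  }
  structure(list(fits = fits, cv = cvs, config = config,
                 input_neuron_ids = rownames(session$inputs),
                 output_neuron_ids = rownames(session$outputs),
                 bin_width_s = session$bin_width_s),
            class = "mimo_model")
}

#' Settings for the Laguerre-Volterra MIMO model
#'
#' @param J,L Number of feedforward / feedback Laguerre functions.
#' @param ff_alpha,fb_alpha Laguerre decay poles.
#' @param memory_bins,fb_memory_bins Kernel memories in bins (default 1000
#'   bins = 2 s at 2 ms).
#' @param n_folds Cross-validation folds for the penalty (default 2).
#' @param lambda_grid Optional explicit penalty grid.
#' @param n_lambda,lambda_min_ratio Grid size and span when the grid is
#'   derived from `lambda_max`.
#' @param tol,max_iter Optimizer settings for final fits.
#' @param cv_tol Looser tolerance used inside the penalty cross-validation
#'   (the held-out score is insensitive to the last digits of the fit).
#' @return A named list of settings.
#' @export
glvm_config <- function(J = 3, L = 3, ff_alpha = 0.99, fb_alpha = 0.99,
                        memory_bins = 1000, fb_memory_bins = 1000,
                        n_folds = 2, lambda_grid = NULL, n_lambda = 30,
                        lambda_min_ratio = 1e-4, tol = 1e-6,
                        cv_tol = 1e-5, max_iter = 200) {
  list(J = J, L = L, ff_alpha = ff_alpha, fb_alpha = fb_alpha,
       memory_bins = memory_bins, fb_memory_bins = fb_memory_bins,
       n_folds = n_folds, lambda_grid = lambda_grid, n_lambda = n_lambda,
       lambda_min_ratio = lambda_min_ratio, tol = tol, max_iter = max_iter)
}

#' @exportS3Method print mimo_model
print.mimo_model <- function(x, ...) {
  cat(sprintf("<mimo_model> %d output neurons | %d inputs | J = %d, L = %d\n",
              length(x$fits), nrow(x$fits[[1]]$c1), x$config$J, x$config$L))
  invisible(x)
}
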