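#' Clamped B-spline basis on a bin grid
#'
#' Builds the `J = m + d + 1` B-spline basis functions of degree `d` with
#' `m` uniform interior knots on the domain `[0, M]`, evaluated on the
#' integer grid `0..M`, via the Cox-de Boor recursion over the clamped knot
#' vector (boundary knots repeated `d + 1` times; `0/0` terms defined as
#' 0). Degree-0 indicators use half-open intervals `[eta_j, eta_{j+1})`
#' with the final interval closed, so the functions form an exact partition
#' of unity on the whole grid.
#'
#' @param m Number of interior knots (>= 0).
#' @param d Spline degree (>= 0).
#' @param M Domain upper end in bins (grid is `0..M`).
#' @param knot_placement Only `"uniform"` is implemented.
#' @return A `bspline_basis`: list with `$values` (J x (M+1) matrix),
#'   `$degree`, `$interior_knots`, `$knots` (full clamped vector), `$M`,
#'   `$J`.
#' @examples
#' b <- bspline_basis(m = 16, d = 3, M = 1999)
#' b$J                    # 20
#' range(colSums(b$values)) # 1 1
#' @export
bspline_basis <- function(m, d, M, knot_placement = "uniform") {
  stopifnot(m >= 0, d >= 0, M > 0)
  knot_placement <- match.arg(knot_placement)
  interior <- if (m > 0) seq_len(m) * (M / (m + 1)) else numeric(0)
  if (any(diff(interior) <= 0)) abort("knots must be strictly increasing")
  kn <- c(rep(0, d + 1), interior, rep(M, d + 1))
  J <- m + d + 1L
  tau <- 0:M
  n_spans <- length(kn) - 1L
  # degree 0: indicator of [kn[j], kn[j+1]), final interval closed at M
  Bd <- matrix(0, nrow = n_spans, ncol = M + 1L)
  for (j in seq_len(n_spans)) {
    lo <- kn[j]; hi <- kn[j + 1L]
    if (hi > lo) {
      inside <- (tau >= lo) & (tau < hi | (hi == M & tau == M))
      Bd[j, inside] <- 1
    }
  }
  if (d > 0) {
    for (deg in seq_len(d)) {
      n_new <- n_spans - deg
      Bn <- matrix(0, nrow = n_new, ncol = M + 1L)
      for (j in seq_len(n_new)) {
        den1 <- kn[j + deg] - kn[j]
        den2 <- kn[j + deg + 1L] - kn[j + 1L]
        term <- 0
        if (den1 > 0) term <- term + (tau - kn[j]) / den1 * Bd[j, ]
        if (den2 > 0) term <- term + (kn[j + deg + 1L] - tau) / den2 * Bd[j + 1L, ]
        Bn[j, ] <- term
      }
      Bd <- Bn
    }
  }
  stopifnot(nrow(Bd) == J)
  structure(list(values = Bd, degree = as.integer(d),
                 interior_knots = interior, knots = kn,
                 M = as.integer(M), J = as.integer(J)),
            class = "bspline_basis")
}

#' @exportS3Method print bspline_basis
print.bspline_basis <- function(x, ...) {
  cat(sprintf("<bspline_basis> J = %d (m = %d interior knots, degree %d) on [0, %d]\n",
              x$J, length(x$interior_knots), x$degree, x$M))
  invisible(x)
}

#' Project spatio-temporal spike patterns onto a B-spline feature space
#'
#' The feature value of neuron `n` under basis function `j` is the inner
#' product `z^(n)(j) = sum_tau B_j(tau) x_n(tau)` — a temporally smoothed
#' spike count. Features are ordered neuron-major (all `J` basis features
#' of neuron 1, then neuron 2, ...), giving a `1 x (J * N)` vector per
#' pattern.
#'
#' @param pattern A single `perievent_pattern`, a bare N x (M+1) binary
#'   matrix, or a `perievent_patterns` list.
#' @param basis A [bspline_basis()] whose grid length matches the pattern
#'   column count.
#' @return For a single pattern, a named numeric feature vector; for a
#'   list, an `n_trials x (J * N)` matrix with one row per trial.
#' @export
project_features <- function(pattern, basis) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (inherits(pattern, "perievent_patterns") ||
      (is.list(pattern) && !inherits(pattern, "perievent_pattern") &&
       !is.matrix(pattern))) {
    rows <- lapply(pattern, project_features, basis = basis)
    return(do.call(rbind, rows))
  }
  x <- if (inherits(pattern, "perievent_pattern")) pattern$pattern else pattern
  if (!is.matrix(x)) abort("pattern must be a matrix")
  if (ncol(x) != basis$M + 1L) {
    abort(sprintf("pattern has %d columns; basis grid is 0..%d",
                  ncol(x), basis$M))
  }
  Z <- x %*% t(basis$values)            # N x J
  z <- as.numeric(t(Z))                 # neuron-major, basis-minor
  names(z) <- as.vector(t(outer(rownames(x) %||% seq_len(nrow(x)),
                                seq_len(basis$J), paste, sep = ".b")))
  z
}

# logistic pieces on the linear predictor scale
logistic_nll <- function(eta, y) {
  # -sum log p(y | eta), numerically stable
  sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}

#' Fit the L1-penalized logistic memory decoder
#'
#' Minimizes `-l(w) + lambda * sum |w|` (bias unpenalized) by cyclic
#' coordinate descent with soft-thresholding, using the global 1/4 bound
#' on the logistic curvature as the per-coordinate majorizer, which makes
#' every update monotone. Labels follow the global convention 1 = left,
#' 0 = right.
#'
#' @param features Trials x (J*N) feature matrix from [project_features()].
#' @param labels Binary labels (1 left / 0 right), one per row.
#' @param basis The [bspline_basis()] that produced the features.
#' @param lambda Non-negative L1 penalty.
#' @param tol Convergence tolerance on the objective change.
#' @param max_iter Maximum full coordinate passes.
#' @param n_neurons Number of neurons (defaults to `ncol(features) /
#'   basis$J`).
#' @param init Optional warm start `c(w0, w)`.
#' @return A `decoder_model`: list with `$w0`, `$w` (N x J matrix),
#'   `$lambda`, `$basis`, `$n_neurons` and `$diagnostics`.
#' @export
fit_decoder <- function(features, labels, basis, lambda = 0, tol = 1e-7,
                        max_iter = 100, n_neurons = NULL, init = NULL) {
  stopifnot(is.matrix(features), lambda >= 0)
  y <- as.numeric(labels)
  assert_binary(y, "labels")
  if (length(y) != nrow(features)) abort("labels and features differ in length")
  if (length(unique(y)) < 2) {
    abort("need both classes present to fit the decoder")
  }
  n_neurons <- n_neurons %||% (ncol(features) / basis$J)
  if (n_neurons != round(n_neurons)) {
    abort("feature count is not a multiple of the basis size")
  }
  X1 <- cbind(1, features) # column 1: unpenalized bias
  n <- nrow(X1)
  P1 <- ncol(X1)
  w <- if (is.null(init)) numeric(P1) else init
  eta <- drop(X1 %*% w)
  obj_of <- function(eta, w) logistic_nll(eta, y) + lambda * sum(abs(w[-1L]))
  obj <- obj_of(eta, w)
  converged <- FALSE
  it <- 0L
  # outer IRLS (Newton) + inner coordinate descent with exact
  # soft-threshold updates on the quadratic surrogate
  while (it < max_iter) {
    it <- it + 1L
    p <- plogis(eta)
    D <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X1 * sqrt(D)) + diag(1e-10, P1)
    grad <- drop(crossprod(X1, p - y))
    q <- drop(H %*% w) - grad
    w_try <- w
    Hw <- drop(H %*% w_try)
    sweep_over <- function(cols) {
      max_move <- 0
      for (j in cols) {
        bj <- q[j] - Hw[j] + H[j, j] * w_try[j]
        nj <- if (j == 1L) bj / H[j, j] else
          sign(bj) * max(0, abs(bj) - lambda) / H[j, j]
        dj <- nj - w_try[j]
        if (dj != 0) {
          Hw <<- Hw + H[, j] * dj
          w_try[j] <<- nj
          max_move <- max(max_move, abs(dj))
        }
      }
      max_move
    }
    # full sweep, then active-set sweeps, then a verification full sweep
    all_cols <- seq_len(P1)
    for (cycle in 1:10) {
      mv <- sweep_over(all_cols)
      tol_in <- 1e-7 * (1 + max(abs(w_try)))
      if (mv < tol_in) break
      for (sweep in 1:30) {
        act <- c(1L, which(w_try[-1L] != 0) + 1L)
        if (sweep_over(act) < tol_in) break
      }
    }
    eta_try <- drop(X1 %*% w_try)
    step <- 1
    repeat {
      w_new <- w + step * (w_try - w)
      eta_new <- eta + step * (eta_try - eta)
      obj_new <- obj_of(eta_new, w_new)
      if (obj_new <= obj + 1e-10 * (abs(obj) + 1) || step < 1e-8) break
      step <- step / 2
    }
    delta <- obj - obj_new
    w <- if (step == 1) w_try else w_new
    eta <- if (step == 1) eta_try else eta_new
    obj <- obj_new
    if (delta >= 0 && delta < tol * (abs(obj) + 1e-10)) {
      converged <- TRUE
      break
    }
    if (logistic_nll(eta, y) < 1e-6) { # perfectly separated: done
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("decoder coordinate descent did not converge in %d outer iterations",
                 max_iter))
  }
  obj_new <- obj
  W <- matrix(w[-1L], nrow = n_neurons, byrow = TRUE)
  structure(list(w0 = w[1L], w = W, lambda = lambda, basis = basis,
                 n_neurons = as.integer(n_neurons),
                 label_convention = c(left = 1, right = 0),
                 diagnostics = list(objective = obj_new,
                                    nll = logistic_nll(eta, y),
                                    n_iter = it, converged = converged)),
            class = "decoder_model")
}

#' @exportS3Method print decoder_model
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d neurons x %d basis functions | %d nonzero weights | lambda = %.4g\n",
              nrow(x$w), ncol(x$w), sum(x$w != 0), x$lambda))
  invisible(x)
}

decoder_lambda_max <- function(features, labels) {
  y <- as.numeric(labels)
  max(abs(drop(crossprod(features, y - mean(y))))) + 1e-12
}

#' Default penalty grid for the decoder
#' @param features,labels Training data.
#' @param n_lambda Grid length (default 30).
#' @param min_ratio Smallest/largest grid ratio (default 1e-3).
#' @return Decreasing numeric grid below the analytic `lambda_max`.
#' @export
decoder_lambda_grid <- function(features, labels, n_lambda = 30,
                                min_ratio = 1e-3) {
  lmax <- decoder_lambda_max(features, labels)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Four-fold cross-validation of the decoder penalty
#'
#' Stratified trial-level folds; fits the penalty path per fold with warm
#' starts and scores held-out classification accuracy. Returns the penalty
#' maximizing mean held-out accuracy; ties go to the larger (sparser)
#' penalty.
#'
#' @param features,labels Training data.
#' @param basis The [bspline_basis()] behind the features.
#' @param lambda_grid Decreasing grid; default [decoder_lambda_grid()].
#' @param n_folds Number of folds (default 4).
#' @param seed Seed for the fold assignment.
#' @param tol,max_iter Passed to [fit_decoder()].
#' @return List with `lambda`, `accuracy` (mean held-out accuracy at the
#'   chosen penalty), `cv` (tibble `lambda`, `mean_accuracy`) and `folds`.
#' @export
cross_validate_decoder <- function(features, labels, basis,
                                   lambda_grid = NULL, n_folds = 4,
                                   seed = 1, tol = 1e-6, max_iter = 60) {
  y <- as.numeric(labels)
  if (min(table(y)) < n_folds) {
    abort("need at least `n_folds` trials in each class")
  }
  lambda_grid <- sort(lambda_grid %||% decoder_lambda_grid(features, y),
                      decreasing = TRUE)
  plan <- make_trial_splits(seq_len(nrow(features)), y, n_folds,
                            stratified = TRUE, seed = seed)
  acc <- matrix(NA_real_, n_folds, length(lambda_grid))
  for (f in seq_len(n_folds)) {
    te <- which(plan$fold == f)
    tr <- which(plan$fold != f)
    init <- NULL
    for (k in seq_along(lambda_grid)) {
      fit <- fit_decoder(features[tr, , drop = FALSE], y[tr], basis,
                         lambda = lambda_grid[k], tol = tol,
                         max_iter = max_iter, init = init)
      init <- c(fit$w0, as.numeric(t(fit$w)))
      pred <- decode(features[te, , drop = FALSE], fit)
      acc[f, k] <- mean(pred$label == y[te])
    }
  }
  mean_acc <- colMeans(acc)
  best <- which(mean_acc >= max(mean_acc) - 1e-12)[1L] # decreasing grid
  list(lambda = lambda_grid[best], accuracy = mean_acc[best],
       cv = tibble::tibble(lambda = lambda_grid, mean_accuracy = mean_acc),
       folds = plan)
}

#' Select the number of B-spline basis functions by cross-validation
#'
#' For each candidate `J` builds the basis (with `m = J - d - 1` interior
#' knots), projects the patterns, cross-validates the penalty, and keeps
#' the `J` with the best out-of-sample accuracy; ties go to the smaller
#' (coarser) `J`. The candidate range 5-100 spans temporal resolutions
#' from ~800 ms to ~40 ms per basis function on the default 4 s window.
#'
#' @param patterns A `perievent_patterns` list.
#' @param labels Binary labels; default from the patterns.
#' @param J_candidates Candidate basis counts.
#' @param d Spline degree (default 3).
#' @param n_folds,seed,lambda_grid,tol Passed to
#'   [cross_validate_decoder()].
#' @return List with `J` (chosen), `curve` (tibble `J`, `accuracy`,
#'   `lambda`).
#' @export
select_J <- function(patterns, labels = NULL,
                     J_candidates = c(5, 10, 20, 50, 100), d = 3,
                     n_folds = 4, seed = 1, lambda_grid = NULL,
                     tol = 1e-7) {
  if (!length(J_candidates)) abort("empty candidate list")
  if (any(J_candidates - d - 1 < 0)) {
    abort("every candidate J must satisfy m = J - d - 1 >= 0")
  }
  labels <- labels %||% pattern_labels(patterns)
  M <- ncol(patterns[[1]]$pattern) - 1L
  J_candidates <- sort(unique(J_candidates))
  rows <- lapply(J_candidates, function(J) {
    bs <- bspline_basis(m = J - d - 1, d = d, M = M)
    feats <- project_features(patterns, bs)
    cv <- cross_validate_decoder(feats, labels, bs,
                                 lambda_grid = lambda_grid,
                                 n_folds = n_folds, seed = seed, tol = tol)
    tibble::tibble(J = J, accuracy = cv$accuracy, lambda = cv$lambda)
  })
  curve <- dplyr::bind_rows(rows)
  best <- which(curve$accuracy >= max(curve$accuracy) - 1e-12)[1L]
  list(J = curve$J[best], curve = curve)
}

#' Reconstruct the time-domain classification feature matrix
#'
#' `F^(n)(tau) = sum_j B_j(tau) w^(n)(j)`: the decoder weights mapped back
#' to the neuron x time grid. Decoding with `F` against the raw pattern is
#' algebraically identical to decoding with the projected features;
#' neurons whose weights are all zero give exactly-zero rows, exposing the
#' sparse spatio-temporal structure of the memory code.
#'
#' @param model A [fit_decoder()] result.
#' @return A `feature_matrix`: N x (M+1) numeric matrix with the basis
#'   attached as an attribute.
#' @export
reconstruct_feature_matrix <- function(model) {
  stopifnot(inherits(model, "decoder_model"))
  F_mat <- model$w %*% model$basis$values
  structure(F_mat, class = c("feature_matrix", class(F_mat)),
            basis = model$basis, w0 = model$w0)
}

#' Decode memory category from patterns or features
#'
#' Computes `P(beta = 1 | x)` through the logistic link and the hard label
#' (1 = left iff the linear predictor is strictly positive; the exact
#' boundary `P = 0.5` maps to 0/right).
#'
#' @param x A feature matrix/vector from [project_features()], a single
#'   `perievent_pattern`, or a `perievent_patterns` list (projected with
#'   the model's own basis).
#' @param model A [fit_decoder()] result.
#' @return A tibble with columns `p_left` and `label`, one row per trial.
#' @export
decode <- function(x, model) {
  stopifnot(inherits(model, "decoder_model"))
  wvec <- as.numeric(t(model$w))
  if (inherits(x, "perievent_patterns") ||
      (is.list(x) && !is.matrix(x) && !inherits(x, "perievent_pattern"))) {
    x <- project_features(x, model$basis)
  } else if (inherits(x, "perievent_pattern")) {
    x <- matrix(project_features(x, model$basis), nrow = 1)
  } else if (is.matrix(x) && ncol(x) == model$basis$M + 1L &&
             nrow(x) == nrow(model$w)) {
    # a bare neuron x time pattern: project it first
    x <- matrix(project_features(x, model$basis), nrow = 1)
  } else if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1)
  }
  if (ncol(x) != length(wvec)) {
    abort("feature dimension does not match the decoder")
  }
  eta <- model$w0 + drop(x %*% wvec)
  tibble::tibble(p_left = plogis(eta), label = as.integer(eta > 0))
}
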