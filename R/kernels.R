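#' Reconstruct time-domain Volterra kernels from Laguerre coefficients
#'
#' Maps a coefficient set back to the time domain: the first-order kernels
#' `k1^(n)(tau) = sum_j c1(n, j) b_j(tau)` on lags `0..M_k`, the symmetric
#' second-order self kernels (off-diagonal basis products split evenly
#' between `(tau1, tau2)` and `(tau2, tau1)`), and the feedback
#' after-potential kernel `h(tau) = sum_j ch(j) b_j(tau)` on lags
#' `1..M_h`. `k0` equals `c0`.
#'
#' @param coeffs A [glvm_coefficients()].
#' @param second_order Also materialize the (large) second-order arrays.
#' @return A `volterra_kernels`: list with `$k0`, `$k1` (N x (M_k + 1)),
#'   `$k2s` (N x (M_k+1) x (M_k+1) array, or `NULL`), `$h` (length M_h).
#' @export
reconstruct_kernels <- function(coeffs, second_order = TRUE) {
  stopifnot(inherits(coeffs, "glvm_coefficients"))
  B <- coeffs$ff_basis$values            # J x (Mk + 1)
  J <- nrow(B)
  k1 <- coeffs$c1 %*% B
  Bh <- coeffs$fb_basis$values[, -1L, drop = FALSE] # lags 1..Mh
  h <- drop(crossprod(Bh, coeffs$ch))
  k2s <- NULL
  if (second_order) {
    N <- nrow(coeffs$c1)
    Mk1 <- ncol(B)
    k2s <- array(0, dim = c(N, Mk1, Mk1))
    pairs <- lower_tri_pairs(J)
    for (n in seq_len(N)) {
      K <- matrix(0, Mk1, Mk1)
      for (k in seq_len(nrow(pairs))) {
        j1 <- pairs[k, 1L]; j2 <- pairs[k, 2L]
        cc <- coeffs$c2s[n, k]
        if (cc == 0) next
        O <- outer(B[j1, ], B[j2, ])
        K <- K + if (j1 == j2) cc * O else cc * (O + t(O)) / 2
      }
      k2s[n, , ] <- K
    }
  }
  structure(list(k0 = coeffs$c0, k1 = k1, k2s = k2s, h = h,
                 ff_basis = coeffs$ff_basis, fb_basis = coeffs$fb_basis),
            class = "volterra_kernels")
}

lower_tri_pairs <- function(J) {
  p <- which(lower.tri(matrix(0, J, J), diag = TRUE), arr.ind = TRUE)
  p[order(p[, "row"], p[, "col"]), , drop = FALSE]
}

#' Project time-domain kernels back onto a Laguerre basis
#'
#' Least-squares projection (exact when the kernels lie in the span of the
#' basis): recovers `c1`, `c2s` and `ch` from `k1`, `k2s` and `h`. Used to
#' verify that reconstruction and projection are mutual inverses.
#'
#' @param kernels A [reconstruct_kernels()] result (with second order).
#' @return A [glvm_coefficients()].
#' @export
project_kernels <- function(kernels) {
  stopifnot(inherits(kernels, "volterra_kernels"))
  B <- kernels$ff_basis$values
  G <- tcrossprod(B)
  c1 <- t(solve(G, B %*% t(kernels$k1)))
  J <- nrow(B)
  pairs <- lower_tri_pairs(J)
  K_n <- nrow(pairs)
  N <- nrow(kernels$k1)
  c2s <- matrix(0, N, K_n)
  if (!is.null(kernels$k2s)) {
    # inner products between symmetrized basis outer products reduce to
    # Gram-matrix products; solve the small normal system per input
    # every symmetrized product is (O + t(O)) / 2, including the diagonal
    A <- matrix(0, K_n, K_n)
    for (a in seq_len(K_n)) {
      for (b in seq_len(K_n)) {
        i1 <- pairs[a, 1L]; i2 <- pairs[a, 2L]
        j1 <- pairs[b, 1L]; j2 <- pairs[b, 2L]
        A[a, b] <- 0.5 * (G[i1, j1] * G[i2, j2] + G[i1, j2] * G[i2, j1])
      }
    }
    for (n in seq_len(N)) {
      K <- kernels$k2s[n, , ]
      bvec <- vapply(seq_len(K_n), function(a) {
        drop(B[pairs[a, 1L], ] %*% K %*% B[pairs[a, 2L], ])
      }, 0)
      c2s[n, ] <- drop(solve(A, bvec))
    }
  }
  Bh <- kernels$fb_basis$values[, -1L, drop = FALSE]
  ch <- drop(solve(tcrossprod(Bh), Bh %*% kernels$h))
  glvm_coefficients(kernels$k0, c1, c2s, ch, kernels$ff_basis,
                    kernels$fb_basis)
}

#' Per-kernel normalized recovery error
#'
#' Compares two kernel sets: `||k_hat - k||_2 / ||k||_2` per first-order
#' kernel and for the feedback kernel; kernels whose true norm is zero are
#' reported as absolute L2 error.
#'
#' @param true,est [reconstruct_kernels()] results of equal dimensions.
#' @return A tibble with columns `kernel`, `type` (`relative` or
#'   `absolute`), `error`.
#' @export
kernel_recovery_error <- function(true, est) {
  stopifnot(inherits(true, "volterra_kernels"),
            inherits(est, "volterra_kernels"))
  if (!all(dim(true$k1) == dim(est$k1)) ||
      length(true$h) != length(est$h)) {
    abort("kernel dimensions do not match")
  }
  one <- function(tr, es, name) {
    nt <- sqrt(sum(tr^2))
    d <- sqrt(sum((es - tr)^2))
    tibble::tibble(kernel = name,
                   type = if (nt > 0) "relative" else "absolute",
                   error = if (nt > 0) d / nt else d)
  }
  rows <- lapply(seq_len(nrow(true$k1)), function(n) {
    one(true$k1[n, ], est$k1[n, ], sprintf("k1.in%d", n))
  })
  rows[[length(rows) + 1L]] <- one(true$h, est$h, "feedback")
  dplyr::bind_rows(rows)
}
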