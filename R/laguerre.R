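#' Discrete orthonormal Laguerre basis
#'
#' Builds the first `n_basis` discrete-time Laguerre functions with decay
#' pole `alpha`, evaluated at lags `0..memory_bins`. The family is the
#' impulse response of a first-order low-pass filter followed by repeated
#' all-pass sections, which makes the functions exactly orthonormal on the
#' infinite lag axis; truncation at `memory_bins` keeps them orthonormal to
#' numerical accuracy whenever the memory greatly exceeds the effective
#' decay length `-1/log(alpha)` bins. Volterra kernels are expanded on this
#' basis to reduce the number of free parameters from the memory length to
#' a handful of coefficients.
#'
#' @param alpha Decay pole in (0, 1); larger values give slower decay.
#' @param n_basis Number of basis functions (orders `0..n_basis-1`).
#' @param memory_bins Truncation lag M (kernel support is `0..M` bins).
#' @return A `laguerre_basis`: list with `$values` (`n_basis` x
#'   `memory_bins + 1` matrix, one function per row), `$alpha`, `$n_basis`,
#'   `$memory_bins`.
#' @examples
#' b <- laguerre_basis(0.9, 3, 200)
#' tcrossprod(b$values) # ~ identity
#' @export
laguerre_basis <- function(alpha, n_basis, memory_bins) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly inside (0, 1).",
          class = "memodecode_parameter_error")
  }
  stopifnot(n_basis >= 1, memory_bins >= 1)
  p <- alpha
  L <- memory_bins + 1L
  vals <- matrix(0, nrow = n_basis, ncol = L)
  # order 0: impulse response of sqrt(1 - p^2) / (1 - p z^-1)
  b <- sqrt(1 - p^2) * p^(0:memory_bins)
  vals[1L, ] <- b
  if (n_basis > 1L) {
    for (j in 2:n_basis) {
      # all-pass section (z^-1 - p) / (1 - p z^-1) applied to previous order
      x <- vals[j - 1L, ]
      y <- numeric(L)
      y[1L] <- -p * x[1L]
      for (n in 2:L) y[n] <- p * y[n - 1L] + x[n - 1L] - p * x[n]
      vals[j, ] <- y
    }
  }
  structure(list(alpha = alpha, n_basis = as.integer(n_basis),
                 memory_bins = as.integer(memory_bins), values = vals),
            class = "laguerre_basis")
}

#' @exportS3Method print laguerre_basis
print.laguerre_basis <- function(x, ...) {
  cat(sprintf("<laguerre_basis> %d functions | alpha = %g | memory = %d bins\n",
              x$n_basis, x$alpha, x$memory_bins))
  invisible(x)
}
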