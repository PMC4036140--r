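# synaptic potential u(t) from the inputs alone (zeroth + first + second
# order terms), with convolution history reset at segment bounds
compute_synaptic_potential <- function(coeffs, inputs, bounds) {
  B <- coeffs$ff_basis$values
  J <- nrow(B)
  N <- nrow(coeffs$c1)
  stopifnot(nrow(inputs) == N)
  T_total <- ncol(inputs)
  u <- rep(coeffs$c0, T_total)
  pairs <- lower_tri_pairs(J)
  for (n in seq_len(N)) {
    first_nz <- any(coeffs$c1[n, ] != 0)
    second_nz <- any(coeffs$c2s[n, ] != 0)
    if (!first_nz && !second_nz) next
    v <- matrix(0, T_total, J)
    for (j in seq_len(J)) {
      v[, j] <- conv_segments(as.numeric(inputs[n, ]), B[j, ], bounds)
    }
    if (first_nz) u <- u + drop(v %*% coeffs$c1[n, ])
    if (second_nz) {
      for (k in seq_len(nrow(pairs))) {
        cc <- coeffs$c2s[n, k]
        if (cc != 0) {
          u <- u + cc * v[, pairs[k, 1L]] * v[, pairs[k, 2L]]
        }
      }
    }
  }
  u
}

# after-potential kernel on lags 1..Mh
feedback_kernel <- function(coeffs) {
  drop(crossprod(coeffs$fb_basis$values[, -1L, drop = FALSE], coeffs$ch))
}

#' Per-bin intensity of the spiking model
#'
#' Computes the synaptic potential `u(t)` from the input spike trains, the
#' after-potential `a(t)`, and the per-bin firing probability
#' `p(t) = Phi(u + a - theta)` with `sigma = 1`. In teacher-forced mode the
#' after-potential is driven by the observed output spike train; in
#' input-only mode `a(t) = 0`.
#'
#' @param coeffs A [glvm_coefficients()].
#' @param session A `concatenated_session` (only `$inputs` and
#'   `$segment_bounds` are used in input-only mode).
#' @param mode `"teacher"` (needs an observed output) or `"input_only"`.
#' @param observed_output Binary series for teacher forcing; defaults to
#'   `session$outputs[output_neuron, ]`.
#' @param output_neuron Row of `session$outputs` used when
#'   `observed_output` is missing.
#' @return An `intensity_trace` tibble with columns `bin`, `u`, `a`, `p`.
#' @export
predict_intensity <- function(coeffs, session,
                              mode = c("teacher", "input_only"),
                              observed_output = NULL, output_neuron = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(coeffs, "glvm_coefficients"),
            inherits(session, "concatenated_session"))
  bounds <- session$segment_bounds
  u <- compute_synaptic_potential(coeffs, session$inputs, bounds)
  if (mode == "teacher") {
    if (is.null(observed_output)) {
      if (is.null(output_neuron)) {
        abort("teacher-forced mode needs `observed_output` or `output_neuron`")
      }
      observed_output <- as.numeric(session$outputs[output_neuron, ])
    }
    assert_binary(observed_output, "observed_output")
    h <- feedback_kernel(coeffs)
    a <- conv_segments(lag_segments(observed_output, 1L, bounds), h, bounds)
  } else {
    a <- numeric(length(u))
  }
  out <- tibble::tibble(bin = seq_along(u), u = u, a = a,
                        p = pnorm(u + a - coeffs$theta))
  class(out) <- c("intensity_trace", class(out))
  out
}

#' Stochastic simulation of output spike trains
#'
#' Free-run Monte Carlo generation: per bin, the synaptic potential from
#' the inputs is added to the after-potential driven by the realization's
#' *own* simulated spike history, and a spike is drawn as
#' `Bernoulli(Phi(u + a))` — the threshold-crossing probability of the
#' latent Gaussian membrane potential. Feedback state is independent per
#' realization and reset at every trial segment boundary.
#'
#' @param coeffs A [glvm_coefficients()].
#' @param session A `concatenated_session` (inputs + segment bounds).
#' @param n_realizations Number of independent realizations.
#' @param seed Integer seed (required: simulation is stochastic).
#' @return A `glvm_simulation`: list with `$spikes` (realizations x T
#'   binary matrix), `$p_mean` (per-bin mean of the realized conditional
#'   probabilities) and `$u` (deterministic input drive).
#' @export
simulate_output <- function(coeffs, session, n_realizations = 1, seed) {
  stopifnot(inherits(coeffs, "glvm_coefficients"),
            inherits(session, "concatenated_session"))
  if (missing(seed)) abort("`seed` is required for reproducible simulation")
  bounds <- session$segment_bounds
  u <- compute_synaptic_potential(coeffs, session$inputs, bounds)
  h <- feedback_kernel(coeffs)
  T_total <- length(u)
  starts <- bounds + 1L
  ends <- c(bounds[-1L], T_total)
  Y <- matrix(0L, nrow = n_realizations, ncol = T_total)
  p_acc <- numeric(T_total)
  withr::with_seed(seed, {
    if (all(h == 0)) {
      p <- pnorm(u)
      for (r in seq_len(n_realizations)) {
        Y[r, ] <- as.integer(runif(T_total) < p)
      }
      p_acc <- p * n_realizations
    } else {
      Mh <- length(h)
      for (r in seq_len(n_realizations)) {
        # spike iff runif < Phi(u + a), i.e. iff qnorm(runif) < u + a:
        # pre-drawn Gaussian thresholds keep the sequential loop cheap
        zs <- qnorm(runif(T_total))
        for (s in seq_along(starts)) {
          i0 <- starts[s]; i1 <- ends[s]
          n <- i1 - i0 + 1L
          a <- numeric(n)
          useg <- u[i0:i1]
          for (t in seq_len(n)) {
            if (zs[i0 + t - 1L] < useg[t] + a[t]) {
              Y[r, i0 + t - 1L] <- 1L
              hi <- min(t + Mh, n)
              if (hi > t) {
                a[(t + 1L):hi] <- a[(t + 1L):hi] + h[seq_len(hi - t)]
              }
            }
          }
          p_acc[i0:i1] <- p_acc[i0:i1] + pnorm(useg + a)
        }
      }
    }
  })
  structure(list(spikes = Y, p_mean = p_acc / n_realizations, u = u,
                 seed = seed),
            class = "glvm_simulation")
}
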