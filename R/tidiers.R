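#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-output Laguerre-Volterra fit
#'
#' One row per coefficient with its input, order (`first`, `second`,
#' `feedback`, `bias`) and basis indices.
#'
#' @param x A [glvm_coefficients()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `input`, `order`, `j1`, `j2`,
#'   `estimate`.
#' @export
tidy.glvm_coefficients <- function(x, ...) {
  J <- ncol(x$c1)
  N <- nrow(x$c1)
  pairs <- lower_tri_pairs(J)
  rows <- list(tibble::tibble(term = "c0", input = NA_integer_,
                              order = "bias", j1 = NA_integer_,
                              j2 = NA_integer_, estimate = x$c0))
  for (n in seq_len(N)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = sprintf("c1[%d,%d]", n, seq_len(J)), input = n,
      order = "first", j1 = seq_len(J), j2 = NA_integer_,
      estimate = x$c1[n, ])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = sprintf("c2s[%d,%d,%d]", n, pairs[, 1L], pairs[, 2L]),
      input = n, order = "second", j1 = as.integer(pairs[, 1L]),
      j2 = as.integer(pairs[, 2L]), estimate = x$c2s[n, ])
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    term = sprintf("ch[%d]", seq_along(x$ch)), input = NA_integer_,
    order = "feedback", j1 = seq_along(x$ch), j2 = NA_integer_,
    estimate = x$ch)
  dplyr::bind_rows(rows)
}

#' Fit summary of a single-output Laguerre-Volterra fit
#' @param x A [glvm_coefficients()].
#' @param ... Unused.
#' @return A one-row tibble: `lambda`, `nll`, `objective`, `n_iter`,
#'   `converged`, `n_inputs`, `n_active_inputs`.
#' @export
glance.glvm_coefficients <- function(x, ...) {
  active <- apply(x$c1, 1, function(r) any(r != 0)) |
    apply(x$c2s, 1, function(r) any(r != 0))
  d <- x$diagnostics %||% list()
  tibble::tibble(lambda = x$lambda,
                 nll = d$nll %||% NA_real_,
                 objective = d$objective %||% NA_real_,
                 n_iter = d$n_iter %||% NA_integer_,
                 converged = d$converged %||% NA,
                 n_inputs = nrow(x$c1),
                 n_active_inputs = sum(active))
}

#' Tidy a MIMO model (one row per coefficient per output neuron)
#' @param x A `mimo_model`.
#' @param ... Unused.
#' @return A tibble; `tidy()` of each output fit with an `output` column.
#' @export
tidy.mimo_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$fits), function(i) {
    dplyr::mutate(tidy(x$fits[[i]]),
                  output = x$output_neuron_ids[i] %||% i, .before = 1)
  }))
}

#' Per-output fit summaries of a MIMO model
#' @param x A `mimo_model`.
#' @param ... Unused.
#' @return A tibble with one row per output neuron.
#' @export
glance.mimo_model <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$fits), function(i) {
    dplyr::mutate(glance(x$fits[[i]]),
                  output = x$output_neuron_ids[i] %||% i, .before = 1)
  }))
}

#' Tidy a fitted memory decoder (one row per weight)
#' @param x A [fit_decoder()] result.
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `basis_j`, `weight`.
#' @export
tidy.decoder_model <- function(x, ...) {
  tibble::tibble(
    neuron = rep(seq_len(nrow(x$w)), each = ncol(x$w)),
    basis_j = rep(seq_len(ncol(x$w)), nrow(x$w)),
    weight = as.numeric(t(x$w)))
}

#' Fit summary of a memory decoder
#' @param x A [fit_decoder()] result.
#' @param ... Unused.
#' @return A one-row tibble: `lambda`, `n_neurons`, `J`, `n_nonzero`,
#'   `nll`, `converged`.
#' @export
glance.decoder_model <- function(x, ...) {
  d <- x$diagnostics %||% list()
  tibble::tibble(lambda = x$lambda, n_neurons = nrow(x$w),
                 J = ncol(x$w), n_nonzero = sum(x$w != 0),
                 nll = d$nll %||% NA_real_,
                 converged = d$converged %||% NA)
}
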