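#' Build the Laguerre-Volterra design for one output neuron
#'
#' Convolves every input spike train with the feedforward Laguerre basis to
#' obtain the first-order features `v_j^(n)(t)`, forms the second-order
#' self-features as elementwise products `v_{j1}^(n) v_{j2}^(n)` (lower
#' triangle, `j2 <= j1`), and convolves the observed output spike train
#' with the feedback basis at lags `>= 1` (teacher forcing) to obtain the
#' after-potential features. Convolution history is reset at every trial
#' segment boundary, since perievent windows are not contiguous in time.
#'
#' @param session A `concatenated_session` from [concatenate_trials()].
#' @param ff_basis,fb_basis Feedforward / feedback [laguerre_basis()].
#' @param output_neuron Row index or row name of `session$outputs` to model.
#' @return A `glvm_design`: list with `$X` (T x P feature matrix, column 1
#'   the intercept), `$y` (binary output series), `$groups` (list with
#'   `penalized`: named list of column-index vectors, one per input
#'   first-order block and one per input second-order block, and
#'   `unpenalized`: intercept + feedback columns), `$col_info` (tibble
#'   describing each column), `$segment_bounds`, and the bases.
#' @export
build_design <- function(session, ff_basis, fb_basis, output_neuron = 1L) {
  stopifnot(inherits(session, "concatenated_session"),
            inherits(ff_basis, "laguerre_basis"),
            inherits(fb_basis, "laguerre_basis"))
  seg_len <- diff(c(session$segment_bounds, ncol(session$inputs)))
  if (max(ff_basis$memory_bins, fb_basis$memory_bins) > min(seg_len)) {
    abort("basis memory exceeds the shortest trial segment",
          class = "memodecode_config_error")
  }
  X_in <- session$inputs
  N <- nrow(X_in)
  T_total <- ncol(X_in)
  J <- ff_basis$n_basis
  L <- fb_basis$n_basis
  bounds <- session$segment_bounds

  if (is.character(output_neuron)) {
    output_neuron <- match(output_neuron, rownames(session$outputs))
  }
  y <- as.numeric(session$outputs[output_neuron, ])

  n_v1 <- N * J
  n_v2 <- N * J * (J + 1) / 2
  P <- 1L + n_v1 + n_v2 + L
  X <- matrix(0, nrow = T_total, ncol = P)
  X[, 1L] <- 1
  col_region <- character(P)
  col_region[1L] <- "intercept"

  # first-order features
  v1_cols <- vector("list", N)
  col <- 1L
  for (n in seq_len(N)) {
    idx <- col + seq_len(J)
    for (j in seq_len(J)) {
      X[, idx[j]] <- conv_segments(as.numeric(X_in[n, ]),
                                   ff_basis$values[j, ], bounds)
    }
    v1_cols[[n]] <- idx
    col_region[idx] <- sprintf("v1.in%d", n)
    col <- col + J
  }
  # second-order self features: products of the input's own v1 columns
  v2_cols <- vector("list", N)
  pairs <- which(lower.tri(matrix(0, J, J), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  for (n in seq_len(N)) {
    idx <- col + seq_len(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      j1 <- pairs[k, "row"]; j2 <- pairs[k, "col"]
      X[, idx[k]] <- X[, v1_cols[[n]][j1]] * X[, v1_cols[[n]][j2]]
    }
    v2_cols[[n]] <- idx
    col_region[idx] <- sprintf("v2.in%d", n)
    col <- col + nrow(pairs)
  }
  # feedback features v_j^(h)(t) = sum_{tau=1..Mh} b_j(tau) y(t - tau):
  # shift y by one bin, then convolve with the basis sampled at lags 1..Mh
  fb_idx <- col + seq_len(L)
  y_lag1 <- lag_segments(y, 1L, bounds)
  Mh <- fb_basis$memory_bins
  for (j in seq_len(L)) {
    X[, fb_idx[j]] <- conv_segments(y_lag1, fb_basis$values[j, 2:(Mh + 1)],
                                    bounds)
  }
  col_region[fb_idx] <- "feedback"

  penalized <- c(
    stats::setNames(v1_cols, sprintf("in%d.first", seq_len(N))),
    stats::setNames(v2_cols, sprintf("in%d.second", seq_len(N)))
  )
  structure(
    list(X = X, y = y,
         groups = list(penalized = penalized,
                       unpenalized = c(1L, fb_idx)),
         col_info = tibble::tibble(column = seq_len(P), role = col_region),
         segment_bounds = bounds,
         n_inputs = N, ff_basis = ff_basis, fb_basis = fb_basis,
         v2_pairs = pairs, output_neuron = output_neuron),
    class = "glvm_design")
}

# swap the modelled output neuron of an existing design: the input
# feature columns are identical across outputs, so only the feedback
# columns and the response need recomputing
update_design_output <- function(design, session, output_neuron) {
  if (is.character(output_neuron)) {
    output_neuron <- match(output_neuron, rownames(session$outputs))
  }
  y <- as.numeric(session$outputs[output_neuron, ])
  fb_idx <- design$groups$unpenalized[-1L]
  y_lag1 <- lag_segments(y, 1L, design$segment_bounds)
  Mh <- design$fb_basis$memory_bins
  for (j in seq_along(fb_idx)) {
    design$X[, fb_idx[j]] <- conv_segments(
      y_lag1, design$fb_basis$values[j, 2:(Mh + 1)], design$segment_bounds)
  }
  design$y <- y
  design$output_neuron <- output_neuron
  design
}

#' @exportS3Method print glvm_design
print.glvm_design <- function(x, ...) {
  cat(sprintf("<glvm_design> %d bins x %d features | %d inputs | %d penalized groups\n",
              nrow(x$X), ncol(x$X), x$n_inputs, length(x$groups$penalized)))
  invisible(x)
}
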