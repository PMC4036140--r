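#' Serialize a MIMO model to JSON
#'
#' Writes basis parameters, per-output coefficient arrays (row-major:
#' `c1` and `c2s` rows are inputs, `c2s` columns follow the
#' lower-triangular order `(j1, j2 <= j1)`), chosen penalties and fit
#' diagnostics.
#'
#' @param model A `mimo_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mimo_model <- function(model, path) {
  stopifnot(inherits(model, "mimo_model"))
  ser_fit <- function(f) {
    list(c0 = f$c0, c1 = as.numeric(t(f$c1)), c2s = as.numeric(t(f$c2s)),
         ch = f$ch, n_inputs = nrow(f$c1), lambda = f$lambda,
         diagnostics = f$diagnostics)
  }
  obj <- list(
    type = "memodecode_mimo_model",
    config = model$config[c("J", "L", "ff_alpha", "fb_alpha",
                            "memory_bins", "fb_memory_bins")],
    bin_width_s = model$bin_width_s,
    input_neuron_ids = model$input_neuron_ids,
    output_neuron_ids = model$output_neuron_ids,
    fits = lapply(model$fits, ser_fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a MIMO model from JSON
#' @param path Path written by [write_mimo_model()].
#' @return A `mimo_model`.
#' @export
read_mimo_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- do.call(glvm_config, obj$config)
  ffb <- laguerre_basis(cfg$ff_alpha, cfg$J, cfg$memory_bins)
  fbb <- laguerre_basis(cfg$fb_alpha, cfg$L, cfg$fb_memory_bins)
  J <- cfg$J
  K <- J * (J + 1) / 2
  fits <- lapply(obj$fits, function(f) {
    N <- f$n_inputs
    co <- glvm_coefficients(
      f$c0, matrix(unlist(f$c1), N, J, byrow = TRUE),
      matrix(unlist(f$c2s), N, K, byrow = TRUE),
      unlist(f$ch), ffb, fbb,
      lambda = if (is.null(f$lambda)) NA_real_ else f$lambda)
    co
  })
  structure(list(fits = fits, cv = NULL, config = cfg,
                 input_neuron_ids = unlist(obj$input_neuron_ids),
                 output_neuron_ids = unlist(obj$output_neuron_ids),
                 bin_width_s = obj$bin_width_s),
            class = "mimo_model")
}

#' Serialize a decoder model to JSON
#' @param model A `decoder_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  obj <- list(
    type = "memodecode_decoder_model",
    degree = model$basis$degree,
    m = length(model$basis$interior_knots),
    M = model$basis$M,
    w0 = model$w0,
    w = as.numeric(t(model$w)),
    n_neurons = model$n_neurons,
    lambda = model$lambda,
    label_convention = as.list(model$label_convention))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decoder model from JSON
#' @param path Path written by [write_decoder()].
#' @return A `decoder_model`.
#' @export
read_decoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- bspline_basis(m = obj$m, d = obj$degree, M = obj$M)
  W <- matrix(unlist(obj$w), nrow = obj$n_neurons, byrow = TRUE)
  structure(list(w0 = obj$w0, w = W, lambda = obj$lambda, basis = basis,
                 n_neurons = obj$n_neurons,
                 label_convention = unlist(obj$label_convention),
                 diagnostics = NULL),
            class = "decoder_model")
}
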