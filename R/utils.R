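#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm dnorm qnorm plogis rbinom runif convolve
#' @importFrom methods as
NULL

# Derive a child seed from a user seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}

# Causal FIR convolution of a series with `kernel[1 + lag]`, lag = 0..M,
# restarted at each segment boundary so history never crosses trials.
# `bounds` are 0-based segment start indices (first = 0); x is a vector.
# Spike trains are sparse, so event-triggered accumulation is exact
# (structural zeros stay zero) and cheap; dense series fall back to FFT.
conv_segments <- function(x, kernel, bounds) {
  T_total <- length(x)
  out <- numeric(T_total)
  starts <- bounds + 1L
  ends <- c(bounds[-1L], T_total)
  M <- length(kernel) - 1L
  nz <- which(x != 0)
  if (length(nz) <= T_total / 4) {
    seg_of <- findInterval(nz, starts)
    for (k in seq_along(nz)) {
      i <- nz[k]
      hi <- min(i + M, ends[seg_of[k]])
      out[i:hi] <- out[i:hi] + x[i] * kernel[seq_len(hi - i + 1L)]
    }
  } else {
    for (s in seq_along(starts)) {
      seg <- x[starts[s]:ends[s]]
      n <- length(seg)
      full <- convolve(seg, rev(kernel), type = "open")
      out[starts[s]:ends[s]] <- full[seq_len(n)]
    }
  }
  out
}

# Lagged version of a series within segments: y(t - lag), zeros before the
# segment start. Used for feedback features (lags >= 1).
lag_segments <- function(x, lag, bounds) {
  T_total <- length(x)
  out <- numeric(T_total)
  starts <- bounds + 1L
  ends <- c(bounds[-1L], T_total)
  for (s in seq_along(starts)) {
    n <- ends[s] - starts[s] + 1L
    if (lag < n) {
      out[(starts[s] + lag):ends[s]] <- x[starts[s]:(ends[s] - lag)]
    }
  }
  out
}

clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_binary <- function(y, what = "y") {
  if (!is.numeric(y) || any(!(y %in% c(0, 1)))) {
    abort(sprintf("`%s` must be a binary (0/1) series.", what))
  }
  invisible(y)
}
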