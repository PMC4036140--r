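#' Time-rescaling Kolmogorov-Smirnov goodness-of-fit test
#'
#' Under the time-rescaling theorem, integrating the conditional intensity
#' between successive spikes of a well-specified point-process model gives
#' unit-rate exponential intervals; the transform `1 - exp(-ISI)` then
#' gives uniform variates. Per discrete bin the integrated intensity mass
#' is `-log(1 - p)` (not `p` itself — the discrete correction matters at
#' 2 ms bins with non-negligible probabilities). The KS statistic is the
#' sup distance between the sorted rescaled quantiles and the uniform
#' positions `(i - 0.5) / n`, compared with the asymptotic 95% band
#' `1.36 / sqrt(n)` (99%: `1.63 / sqrt(n)`).
#'
#' Binned data make the rescaled intervals discrete; the within-bin
#' correction draws each spike's position inside its bin from the
#' truncated exponential implied by the bin's intensity mass and carries
#' the remainder of the spiking bin into the next interval, removing the
#' O(p) discreteness bias. Applied by default under a fixed seed.
#'
#' @param spikes Binary output series.
#' @param p Per-bin firing probability trace in (0, 1), same length.
#' @param jitter Apply the within-bin uniform correction (default TRUE).
#' @param seed Seed for the jitter draws.
#' @return A `ks_result`: list with `$rescaled_quantiles` (sorted, in
#'   `[0, 1]`), `$ks_statistic`, `$band_95`, `$band_99`, `$inside_band`
#'   (95%), `$n_intervals`.
#' @export
ks_time_rescaling <- function(spikes, p, jitter = TRUE, seed = 1) {
  assert_binary(spikes, "spikes")
  if (length(spikes) != length(p)) abort("series lengths differ")
  if (any(p <= 0 | p >= 1)) {
    abort("probabilities must lie strictly inside (0, 1)")
  }
  idx <- which(spikes == 1)
  if (length(idx) < 2) {
    abort("need at least 2 spikes to form rescaled intervals")
  }
  lam <- -log1p(-p) # per-bin intensity mass
  cum <- cumsum(lam)
  if (jitter) {
    # the interval restarts at the boundary after the spiking bin (bins
    # are independent); survival to the end of bin k is exp(-sum lam)
    # exactly, and the truncated-exponential draw fills in the position
    # within the final bin, making the rescaled interval exactly Exp(1)
    delta <- withr::with_seed(seed, {
      -log1p(-runif(length(idx)) * p[idx])
    })
    k0 <- idx[-length(idx)]
    k1 <- idx[-1L]
    between <- cum[k1 - 1L] - cum[k0] # full bins strictly between spikes
    taus <- between + delta[-1L]
  } else {
    taus <- diff(cum[idx])
  }
  z <- sort(1 - exp(-taus))
  n <- length(z)
  pos <- (seq_len(n) - 0.5) / n
  ks <- max(abs(z - pos))
  band95 <- 1.36 / sqrt(n)
  structure(list(rescaled_quantiles = z, ks_statistic = ks,
                 band_95 = band95, band_99 = 1.63 / sqrt(n),
                 inside_band = ks <= band95, n_intervals = n),
            class = "ks_result")
}

#' @exportS3Method print ks_result
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> KS = %.4f | 95%% band = %.4f (%s) | n = %d intervals\n",
              x$ks_statistic, x$band_95,
              if (x$inside_band) "inside" else "OUTSIDE", x$n_intervals))
  invisible(x)
}

#' Classification accuracy with a binomial confidence interval
#'
#' @param labels,predictions Equal-length binary vectors.
#' @param conf_level Confidence level for the Wilson score interval.
#' @return A tibble with `accuracy`, `n`, `n_correct`, `ci_lower`,
#'   `ci_upper`.
#' @export
classification_accuracy <- function(labels, predictions,
                                    conf_level = 0.95) {
  if (!length(labels)) abort("empty label vector")
  if (length(labels) != length(predictions)) abort("lengths differ")
  n <- length(labels)
  k <- sum(labels == predictions)
  phat <- k / n
  zq <- qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + zq^2 / n
  center <- (phat + zq^2 / (2 * n)) / denom
  half <- zq * sqrt(phat * (1 - phat) / n + zq^2 / (4 * n^2)) / denom
  tibble::tibble(accuracy = phat, n = n, n_correct = k,
                 ci_lower = max(0, center - half),
                 ci_upper = min(1, center + half))
}

#' Deterministic trial-level cross-validation folds
#'
#' Assigns each trial to one of `n_folds` folds, optionally stratified so
#' that class proportions per fold stay within one trial of the overall
#' proportions. Deterministic for a fixed seed.
#'
#' @param trials Vector of trial identifiers.
#' @param labels Binary labels (required when `stratified`).
#' @param n_folds Number of folds.
#' @param stratified Balance classes across folds.
#' @param seed Integer seed.
#' @return A `split_plan`: tibble with columns `trial`, `label`, `fold`,
#'   plus attributes `n_folds`, `stratified`, `seed`.
#' @export
make_trial_splits <- function(trials, labels = NULL, n_folds,
                              stratified = TRUE, seed = 1) {
  n <- length(trials)
  if (n_folds > n) abort("more folds than trials")
  fold <- integer(n)
  withr::with_seed(seed, {
    if (stratified) {
      if (is.null(labels)) abort("stratified splits need labels")
      if (min(table(labels)) < n_folds) {
        abort("stratification infeasible: a class has fewer trials than folds")
      }
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- sample(idx)
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold <- rep_len(seq_len(n_folds), n)[sample.int(n)]
    }
  })
  out <- tibble::tibble(trial = trials,
                        label = if (is.null(labels)) NA else labels,
                        fold = fold)
  attr(out, "n_folds") <- n_folds
  attr(out, "stratified") <- stratified
  attr(out, "seed") <- seed
  class(out) <- c("split_plan", class(out))
  out
}
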