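#' Confidence-interval configuration
#'
#' @param confidence_level coverage in `(0, 1)`, default 0.95.
#' @return object of class `ci_config` with the normal quantile `z` at
#'   `(1 + level) / 2` (1.959964 at 0.95).
#' @export
ci_config <- function(confidence_level = 0.95) {
  stopifnot(confidence_level > 0, confidence_level < 1)
  structure(list(confidence_level = confidence_level,
                 z = stats::qnorm((1 + confidence_level) / 2)),
            class = "ci_config")
}

proportion_ci <- function(numerator, denominator, estimate, lower, upper, method) {
  structure(list(numerator = numerator, denominator = denominator,
                 estimate = estimate, lower = lower, upper = upper,
                 method = method),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.proportion_ci <- function(x, ...) {
  sprintf("%s/%s = %.1f%% (%.1f-%.1f) [%s]",
          format(x$numerator), format(x$denominator), 100 * x$estimate,
          100 * x$lower, 100 * x$upper, x$method)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-test inversion interval (no continuity correction): center
#' `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clipped to `[0, 1]`.
#' This is the interval behind every category-level CI in the validation
#' results it reproduces. `k` may be non-integer (used by the Rao-Scott
#' effective-count adjustment).
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `> 0`.
#' @param config a [ci_config()].
#' @return a `proportion_ci`.
#' @export
wilson_ci <- function(k, n, config = ci_config()) {
  stopifnot(length(k) == 1, length(n) == 1)
  if (n <= 0) stop("wilson_ci: n must be positive")
  if (k < 0 || k > n) stop("wilson_ci: k must lie in [0, n]")
  z <- config$z
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  proportion_ci(k, n, p, max(0, center - half), min(1, center + half), "wilson")
}

#' Clopper-Pearson exact interval
#'
#' Tail-inversion (beta-quantile) interval: lower bound 0 at `k = 0`,
#' upper bound 1 at `k = n`.
#'
#' @inheritParams wilson_ci
#' @return a `proportion_ci`.
#' @export
clopper_pearson_ci <- function(k, n, config = ci_config()) {
  if (n <= 0) stop("clopper_pearson_ci: n must be positive")
  if (k < 0 || k > n) stop("clopper_pearson_ci: k must lie in [0, n]")
  alpha <- 1 - config$confidence_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  proportion_ci(k, n, k / n, lower, upper, "clopper_pearson")
}

#' Rao-Scott interval for a clustered proportion
#'
#' For within-scan correlated binary outcomes (several nodules on one
#' scan). The proportion is the ratio estimate `sum(k_i) / sum(n_i)`; its
#' variance uses the with-replacement cluster formula
#' `m / ((m - 1) n^2) * sum((k_i - p n_i)^2)` with `m` clusters. The design
#' effect `d` (ratio variance over binomial variance) rescales the sample
#' to `n_eff = n / d`, and a Wilson interval is computed at
#' `(p * n_eff, n_eff)`. A design effect below 1 is kept as computed, with
#' a warning.
#'
#' @param k per-cluster success counts.
#' @param n per-cluster sizes (all `>= 1`).
#' @param config a [ci_config()].
#' @return a `proportion_ci` with method `"rao_scott"`.
#' @export
rao_scott_ci <- function(k, n, config = ci_config()) {
  stopifnot(length(k) == length(n))
  m <- length(k)
  if (m < 2) stop("rao_scott_ci: at least 2 clusters required (variance undefined)")
  if (any(n < 1)) stop("rao_scott_ci: all cluster sizes must be >= 1")
  if (any(k < 0 | k > n)) stop("rao_scott_ci: k_i must lie in [0, n_i]")
  N <- sum(n); K <- sum(k)
  p <- K / N
  v <- m / ((m - 1) * N^2) * sum((k - p * n)^2)
  vbin <- p * (1 - p) / N
  if (vbin == 0) {
    d <- 1  # degenerate p in {0,1}: no clustering information
  } else {
    d <- v / vbin
    if (d < 1)
      warning("rao_scott_ci: design effect ", signif(d, 4),
              " < 1 kept as computed (negative intra-cluster correlation)")
    if (d <= 0) d <- 1
  }
  n_eff <- N / d
  w <- wilson_ci(p * n_eff, n_eff, config)
  proportion_ci(K, N, p, w$lower, w$upper, "rao_scott")
}
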