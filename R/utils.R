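#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(length(x) == length(n), all(x >= 0), all(n > 0), all(x <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(estimate = p, lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Derive a per-stage seed from a global seed
#'
#' Counter-based fan-out: every pipeline stage draws from its own stream, so
#' stages stay reproducible when run in isolation. Derived seeds stay below
#' 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name: one of cohort, preprocess, network, cluster,
#'   outcomes, varnet, validate, stability.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 11L, preprocess = 23L, network = 37L, cluster = 53L,
    outcomes = 71L, varnet = 89L, validate = 101L, stability = 131L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-rank p-value from a survival::survdiff fit
survdiff_p <- function(sd_fit) {
  df <- length(sd_fit$n) - 1L
  stats::pchisq(sd_fit$chisq, df = df, lower.tail = FALSE)
}
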