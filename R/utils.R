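#' Derive a reproducible child seed from a master seed and a tag
#'
#' All stochastic operations in the package take explicit integer seeds.
#' Sessions hold one master seed; per-component streams are derived from it
#' with this helper so that components can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param tag character label of the component stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (b in utf8ToInt(tag)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps package randomness out of the user's RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, center - half), upper = min(1, center + half))
}

#' Beta-distribution (Jeffreys) confidence interval for a proportion
#'
#' @inheritParams wilson_ci
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
beta_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  a <- (1 - conf) / 2
  c(estimate = x / n,
    lower = stats::qbeta(a, x + 0.5, n - x + 0.5),
    upper = stats::qbeta(1 - a, x + 0.5, n - x + 0.5))
}

#' Two-proportion z-test (pooled variance)
#'
#' Compares success fractions `x1/n1` and `x2/n2` with the classical pooled
#' standard error. Returns the signed z statistic and two-sided p value.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return List with `z`, `p`, `p1`, `p2`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

# Welch two-sample t-test with a directional success flag: "a exceeds b".
welch_gt <- function(a, b, alpha, alternative = "two.sided") {
  tt <- stats::t.test(a, b, alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value,
       success = is.finite(tt$p.value) && tt$p.value < alpha &&
         mean(a) > mean(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
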