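#' @title CMA-ES optimizer
#'
#' @description Covariance matrix adaptation evolution strategy (rank-mu
#' update with cumulative step-size adaptation), used as the closed-loop
#' optimizer for both generator latent spaces. Scores are *maximized* and
#' the update is rank-based, so it is invariant to monotone (affine,
#' positive-scale) transformations of the scores.
#'
#' Sampling convention: each generation draws a `dim x popsize` matrix of
#' standard normals column by column (`rnorm(dim * popsize)` filled
#' column-wise); candidate `j` is `mean + sigma * B %*% (D * Z[, j])`. The
#' reference cross-check in the test suite shares only this convention.
#'
#' @name cma_es
NULL

#' Initialize a CMA-ES optimizer state
#'
#' @param dim search dimensionality.
#' @param mean0 initial mean (default zero vector).
#' @param sigma0 initial step size (> 0).
#' @param popsize population size per generation (default
#'   `4 + floor(3 * log(dim))`).
#' @param seed integer seed for the optimizer's private RNG stream.
#' @return Object of class `cma_state`.
#' @export
cma_init <- function(dim, mean0 = rep(0, dim), sigma0 = 1,
                     popsize = 4L + floor(3 * log(dim)), seed = 1L) {
  stopifnot(dim >= 1, sigma0 > 0, length(mean0) == dim, popsize >= 2)
  mu <- floor(popsize / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  st <- list(
    dim = as.integer(dim), popsize = as.integer(popsize), mu = mu,
    weights = w, mueff = mueff,
    cc = (4 + mueff / dim) / (dim + 4 + 2 * mueff / dim),
    cs = (mueff + 2) / (dim + mueff + 5),
    c1 = 2 / ((dim + 1.3)^2 + mueff),
    cmu = min(1 - 2 / ((dim + 1.3)^2 + mueff),
              2 * (mueff - 2 + 1 / mueff) / ((dim + 2)^2 + mueff)),
    chiN = sqrt(dim) * (1 - 1 / (4 * dim) + 1 / (21 * dim^2)),
    mean = as.numeric(mean0), sigma = sigma0,
    C = diag(dim), B = diag(dim), D = rep(1, dim),
    invsqrtC = diag(dim),
    pc = rep(0, dim), ps = rep(0, dim),
    generation = 0L,
    rng_state = NULL, seed = as.integer(seed),
    expand = NULL, offset = NULL, # set by project_to_subspace
    last_Z = NULL, last_X = NULL,
    n_excluded = 0L
  )
  st$damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (dim + 1)) - 1) + st$cs
  class(st) <- "cma_state"
  st
}

#' @export
print.cma_state <- function(x, ...) {
  cat(sprintf("<cma_state> dim=%d pop=%d gen=%d sigma=%.4g |mean|=%.4g%s\n",
              x$dim, x$popsize, x$generation, x$sigma,
              sqrt(sum(x$mean^2)),
              if (is.null(x$expand)) "" else
                sprintf(" (subspace of %d)", nrow(x$expand))))
  invisible(x)
}

cma_with_rng <- function(state, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  caller <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", caller, envir = globalenv()), add = TRUE)
  if (is.null(state$rng_state)) {
    set.seed(state$seed)
  } else {
    assign(".Random.seed", state$rng_state, envir = globalenv())
  }
  val <- expr
  list(value = val, rng_state = get(".Random.seed", envir = globalenv()))
}

#' Sample the next candidate population
#'
#' @param state a `cma_state`.
#' @return List with updated `state` and `X`, a `full_dim x popsize` matrix
#'   of candidate vectors (expanded through the subspace basis if one is
#'   attached).
#' @export
cma_ask <- function(state) {
  r <- cma_with_rng(state, matrix(stats::rnorm(state$dim * state$popsize),
                                  nrow = state$dim))
  state$rng_state <- r$rng_state
  Z <- r$value
  Y <- state$B %*% (state$D * Z)
  X <- state$mean + state$sigma * Y
  state$last_Z <- Z
  state$last_X <- X
  Xout <- if (is.null(state$expand)) X else state$offset + state$expand %*% X
  list(state = state, X = Xout)
}

#' Update the optimizer with scored candidates
#'
#' Standard rank-based CMA-ES update (recombination, step-size and
#' covariance adaptation) treating larger scores as better. Candidates with
#' non-finite scores are excluded from recombination (recombination weights
#' renormalized over the remaining ranks) and counted in `state$n_excluded`.
#'
#' @param state a `cma_state` that has `cma_ask()` output pending.
#' @param scores numeric vector of length `popsize`, aligned with the
#'   columns of the last asked `X`.
#' @return The updated `cma_state`.
#' @export
cma_tell <- function(state, scores) {
  stopifnot(length(scores) == state$popsize, !is.null(state$last_Z))
  valid <- which(is.finite(scores))
  if (length(valid) < state$popsize) {
    state$n_excluded <- state$n_excluded +
      as.integer(state$popsize - length(valid))
  }
  if (length(valid) < 2) {
    stop("fewer than two finite scores in generation; cannot update")
  }
  d <- state$dim
  ord <- valid[order(scores[valid], decreasing = TRUE)]
  mu_use <- min(state$mu, length(ord))
  w <- state$weights[seq_len(mu_use)]
  w <- w / sum(w)
  mueff <- if (mu_use == state$mu) state$mueff else 1 / sum(w^2)
  sel <- ord[seq_len(mu_use)]
  Ysel <- state$B %*% (state$D * state$last_Z[, sel, drop = FALSE])
  ybar <- as.numeric(Ysel %*% w)
  state$mean <- state$mean + state$sigma * ybar
  state$ps <- (1 - state$cs) * state$ps +
    sqrt(state$cs * (2 - state$cs) * mueff) *
    as.numeric(state$invsqrtC %*% ybar)
  g <- state$generation + 1L
  hsig <- sqrt(sum(state$ps^2)) /
    sqrt(1 - (1 - state$cs)^(2 * g)) / state$chiN < 1.4 + 2 / (d + 1)
  state$pc <- (1 - state$cc) * state$pc +
    (if (hsig) sqrt(state$cc * (2 - state$cc) * mueff) else 0) * ybar
  rank_mu <- Ysel %*% (w * t(Ysel))
  state$C <- (1 - state$c1 - state$cmu) * state$C +
    state$c1 * (tcrossprod(state$pc) +
                  (1 - hsig) * state$cc * (2 - state$cc) * state$C) +
    state$cmu * rank_mu
  state$C <- (state$C + t(state$C)) / 2
  state$sigma <- state$sigma *
    exp((state$cs / state$damps) * (sqrt(sum(state$ps^2)) / state$chiN - 1))
  eg <- eigen(state$C, symmetric = TRUE)
  state$D <- sqrt(pmax(eg$values, 1e-20))
  state$B <- eg$vectors
  state$invsqrtC <- eg$vectors %*% ((1 / state$D) * t(eg$vectors))
  state$generation <- g
  state$last_Z <- NULL
  state$last_X <- NULL
  state
}

#' One full CMA-ES step: incorporate scores, propose the next batch
#'
#' Convenience wrapper pairing [cma_tell()] and [cma_ask()].
#'
#' @param state a `cma_state` with a pending population.
#' @param scores scores for the pending population (larger is better).
#' @return List with updated `state` and next candidate matrix `X`.
#' @export
cma_es_update <- function(state, scores) {
  cma_ask(cma_tell(state, scores))
}

#' Restrict a CMA-ES state to an orthonormal subspace
#'
#' Optimization proceeds in the `k` reduced coordinates; candidates returned
#' by [cma_ask()] are expanded through the basis before use (the component
#' of the current mean orthogonal to the subspace is held fixed).
#'
#' @param state a freshly initialized `cma_state` over the full space.
#' @param basis `full_dim x k` matrix with orthonormal columns
#'   (Gram deviation from identity must be <= 1e-8).
#' @return A `cma_state` of dimension `k` carrying the expansion basis.
#' @export
project_to_subspace <- function(state, basis) {
  basis <- as.matrix(basis)
  stopifnot(nrow(basis) == length(state$mean))
  k <- ncol(basis)
  gram_dev <- max(abs(crossprod(basis) - diag(k)))
  if (gram_dev > 1e-8) {
    stop(sprintf("basis not orthonormal (Gram deviation %.3g > 1e-8)", gram_dev))
  }
  mean_red <- as.numeric(crossprod(basis, state$mean))
  red <- cma_init(dim = k, mean0 = mean_red, sigma0 = state$sigma,
                  popsize = state$popsize, seed = state$seed)
  red$rng_state <- state$rng_state
  red$expand <- basis
  red$offset <- state$mean - as.numeric(basis %*% mean_red)
  red
}

#' Run CMA-ES on a black-box objective
#'
#' Small driver used in tests and for in-silico checks.
#'
#' @param fn objective `function(x) -> numeric` to maximize.
#' @param state a `cma_state`.
#' @param generations number of generations.
#' @return List with final `state`, `trace` (data frame of per-generation
#'   `sigma`, best and mean score), `means` matrix, and the best candidate
#'   ever evaluated (`best_x`, `best_score`).
#' @export
cma_optimize <- function(fn, state, generations) {
  trace <- data.frame(generation = integer(), sigma = numeric(),
                      best = numeric(), mean_score = numeric())
  means <- matrix(NA_real_, nrow = generations, ncol = state$dim)
  best_x <- NULL
  best_score <- -Inf
  for (g in seq_len(generations)) {
    a <- cma_ask(state)
    state <- a$state
    scores <- apply(a$X, 2, fn)
    j <- which.max(scores)
    if (length(j) && scores[j] > best_score) {
      best_score <- scores[j]
      best_x <- a$X[, j]
    }
    state <- cma_tell(state, scores)
    trace <- rbind(trace, data.frame(
      generation = g, sigma = state$sigma, best = max(scores, na.rm = TRUE),
      mean_score = mean(scores, na.rm = TRUE)))
    means[g, ] <- state$mean
  }
  list(state = state, trace = trace, means = means,
       best_x = best_x, best_score = best_score)
}
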