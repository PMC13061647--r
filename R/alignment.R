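#' @title Alignment metrics
#'
#' @description Alignment between a neuron's tuning and a generator's latent
#' space is quantified three ways: ease of hill climbing (evolution success),
#' the start and end points of the climb (normalized activation before and
#' after optimization), and climbing speed (convergence time of the smoothed
#' trajectory), plus per-generation win rates between the two spaces.
#'
#' @name alignment
NULL

as_score_list <- function(thread) {
  if (inherits(thread, "evolution_thread")) thread$scores
  else if (is.list(thread)) thread
  else stop("expected an evolution_thread or a list of per-block score vectors")
}

#' Test whether an evolution succeeded
#'
#' Success means neuronal activity in two consecutive blocks exceeded that
#' of the first two blocks: image scores of every candidate pair of
#' consecutive blocks (pairs disjoint from the baseline, i.e. starting at
#' block 3) are pooled, the pair with the highest pooled mean is tested
#' against the pooled first two blocks (Welch t-test), and success requires
#' both a mean increase and `p < alpha`.
#'
#' Note the max-over-pairs selection makes the null success rate exceed the
#' nominal `alpha` level; the calibration is characterized in the test
#' suite against an independent Monte-Carlo oracle.
#'
#' @param thread an `evolution_thread` or list of per-block score vectors
#'   (>= 4 blocks).
#' @param alpha significance level (default 0.01, the strict criterion; the
#'   lenient criterion uses 0.05).
#' @param alternative sidedness of the t-test (default two-sided, with the
#'   direction enforced separately).
#' @return List with `success`, `p`, `t`, and `pair` (first block index of
#'   the winning pair).
#' @export
evolution_success <- function(thread, alpha = 0.01,
                              alternative = "two.sided") {
  sc <- lapply(as_score_list(thread), function(s) s[is.finite(s)])
  B <- length(sc)
  if (B < 4) stop("evolution_success needs at least 4 blocks")
  baseline <- c(sc[[1]], sc[[2]])
  starts <- seq(3, B - 1)
  pooled_means <- vapply(starts, function(b) mean(c(sc[[b]], sc[[b + 1]])),
                         numeric(1))
  best <- starts[which.max(pooled_means)]
  res <- welch_gt(c(sc[[best]], sc[[best + 1]]), baseline, alpha, alternative)
  list(success = res$success, p = res$p, t = res$t, pair = best)
}

#' Normalize, pad and average evolution trajectories
#'
#' Each thread's block-mean trajectory is normalized by the session's
#' maximum block mean across both threads (so the session max is exactly 1),
#' shorter sessions are padded to the longest length with the mean of their
#' last two blocks, and mean and s.e.m. across sessions are returned per
#' thread/generator.
#'
#' @param sessions list of `evolution_session` objects (>= 1).
#' @return List with per-thread (`a`, `b`) elements, each containing
#'   `trajectories` (sessions x blocks matrix), `mean`, and `sem`, plus
#'   `norm_constants` (per-session normalizers).
#' @export
normalize_and_pad <- function(sessions) {
  stopifnot(length(sessions) >= 1)
  bm <- lapply(sessions, function(s)
    list(a = block_means(s$threads$a), b = block_means(s$threads$b)))
  L <- max(vapply(bm, function(x) length(x$a), integer(1)),
           vapply(bm, function(x) length(x$b), integer(1)))
  norms <- vapply(bm, function(x) max(c(x$a, x$b)), numeric(1))
  pad <- function(v) {
    if (length(v) < L) {
      v <- c(v, rep(mean(v[(length(v) - 1):length(v)]), L - length(v)))
    }
    v
  }
  out <- list()
  for (th in c("a", "b")) {
    M <- do.call(rbind, lapply(seq_along(bm), function(i)
      pad(bm[[i]][[th]] / norms[i])))
    out[[th]] <- list(
      trajectories = M, mean = colMeans(M),
      sem = apply(M, 2, function(v) stats::sd(v) / sqrt(length(v))))
  }
  out$norm_constants <- norms
  out
}

# Squared-exponential + white-noise Gaussian-process regression smoother.
# Hyperparameters by marginal-likelihood maximization; falls back to a
# centered moving average if the optimization or factorization degenerates.
gpr_smooth <- function(x, y, xout = x) {
  n <- length(x)
  ybar <- mean(y)
  yc <- y - ybar
  nll <- function(par) {
    ell <- exp(par[1]); sf2 <- exp(2 * par[2]); sn2 <- exp(2 * par[3])
    K <- sf2 * exp(-0.5 * outer(x, x, "-")^2 / ell^2) + diag(sn2, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, forwardsolve(t(L), yc))
    0.5 * sum(yc * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1e-8
  fit <- tryCatch(
    stats::optim(log(c(diff(range(x)) / 5, sdy, 0.3 * sdy + 1e-9)), nll,
                 method = "Nelder-Mead", control = list(maxit = 300)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) {
    # moving-average fallback, window 3
    sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(y[1:2]); sm[n] <- mean(y[(n - 1):n])
    return(list(mean = stats::approx(x, as.numeric(sm), xout, rule = 2)$y,
                method = "movavg"))
  }
  ell <- exp(fit$par[1]); sf2 <- exp(2 * fit$par[2]); sn2 <- exp(2 * fit$par[3])
  jitter <- 1e-10 * max(sf2, 1)
  K <- sf2 * exp(-0.5 * outer(x, x, "-")^2 / ell^2) + diag(sn2 + jitter, n)
  Ks <- sf2 * exp(-0.5 * outer(xout, x, "-")^2 / ell^2)
  a <- tryCatch(solve(K, yc), error = function(e) NULL)
  if (is.null(a)) {
    sm <- stats::filter(y, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(y[1:2]); sm[n] <- mean(y[(n - 1):n])
    return(list(mean = stats::approx(x, as.numeric(sm), xout, rule = 2)$y,
                method = "movavg"))
  }
  list(mean = as.numeric(Ks %*% a) + ybar, method = "gpr",
       hyper = c(ell = ell, sf2 = sf2, sn2 = sn2))
}

#' Convergence time of an evolution trajectory
#'
#' Fits a Gaussian-process regression of block-mean score against block
#' number and returns the first block at which the smoothed curve reaches
#' 80% of the activation increase. Two definitions are implemented:
#' `"increase"` (default) thresholds at
#' `first-block level + 0.8 * (max smoothed increase above first-block
#' level)`, which is invariant to affine rescaling of the scores;
#' `"max"` thresholds at `0.8 * smoothed maximum`.
#'
#' @param trajectory numeric vector of block-mean scores (>= 4 blocks), or
#'   an `evolution_thread`.
#' @param definition `"increase"` or `"max"`.
#' @param smoother `"gpr"`, `"movavg"`, or `"none"` (raw trajectory; useful
#'   as an oracle).
#' @param level threshold fraction (default 0.8).
#' @return List with `block` (NA if undefined), `undefined` flag, and the
#'   smoothed curve.
#' @export
convergence_time <- function(trajectory, definition = c("increase", "max"),
                             smoother = c("gpr", "movavg", "none"),
                             level = 0.8) {
  definition <- match.arg(definition)
  smoother <- match.arg(smoother)
  if (inherits(trajectory, "evolution_thread")) {
    trajectory <- block_means(trajectory)
  }
  B <- length(trajectory)
  if (B < 4) stop("convergence_time needs at least 4 blocks")
  x <- seq_len(B)
  s <- switch(smoother,
              gpr = gpr_smooth(x, trajectory)$mean,
              movavg = {
                sm <- stats::filter(trajectory, rep(1 / 3, 3), sides = 2)
                sm[1] <- mean(trajectory[1:2])
                sm[B] <- mean(trajectory[(B - 1):B])
                as.numeric(sm)
              },
              none = trajectory)
  inc <- max(s) - s[1]
  if (definition == "increase") {
    if (inc <= 0) {
      return(list(block = NA_integer_, undefined = TRUE, smoothed = s))
    }
    thr <- s[1] + level * inc
  } else {
    if (inc <= 0) {
      return(list(block = NA_integer_, undefined = TRUE, smoothed = s))
    }
    thr <- level * max(s)
  }
  list(block = which(s >= thr)[1], undefined = FALSE, smoothed = s)
}

#' Per-generation win rate between the two threads
#'
#' For each session, the two threads' image scores in the given generation
#' are compared with a Welch t-test; a thread "wins" the session if its mean
#' is higher and the test is significant at `alpha`. Sessions lacking that
#' generation are skipped and counted.
#'
#' @param sessions list of `evolution_session` objects.
#' @param generation block index to compare.
#' @param alpha significance level (default 0.05).
#' @return List with fractions `a_wins`, `b_wins`, `ties` (summing to 1
#'   over included sessions), plus `n_included` and `n_skipped`.
#' @export
win_rate <- function(sessions, generation, alpha = 0.05) {
  a_w <- b_w <- tie <- 0L
  skipped <- 0L
  for (s in sessions) {
    sa <- as_score_list(s$threads$a)
    sb <- as_score_list(s$threads$b)
    if (generation > length(sa) || generation > length(sb)) {
      skipped <- skipped + 1L
      next
    }
    x <- sa[[generation]][is.finite(sa[[generation]])]
    y <- sb[[generation]][is.finite(sb[[generation]])]
    tt <- stats::t.test(x, y)
    if (is.finite(tt$p.value) && tt$p.value < alpha) {
      if (mean(x) > mean(y)) a_w <- a_w + 1L else b_w <- b_w + 1L
    } else {
      tie <- tie + 1L
    }
  }
  n <- a_w + b_w + tie
  if (n == 0) stop("no eligible sessions at that generation")
  list(a_wins = a_w / n, b_wins = b_w / n, ties = tie / n,
       n_included = n, n_skipped = skipped)
}

#' Z-score all image responses within a session
#'
#' Used for first-generation comparisons between spaces: spike rates are
#' z-scored with mean and s.d. taken over all image responses in the
#' session (both threads and references).
#'
#' @param session an `evolution_session`.
#' @return The session with thread scores and reference scores z-scored;
#'   the normalization constants are attached as `attr(, "zscore")`.
#' @export
session_zscore <- function(session) {
  all_scores <- c(unlist(session$threads$a$scores),
                  unlist(session$threads$b$scores),
                  as.numeric(session$ref$scores))
  mu <- mean(all_scores, na.rm = TRUE)
  sdv <- stats::sd(all_scores, na.rm = TRUE)
  for (th in c("a", "b")) {
    session$threads[[th]]$scores <- lapply(session$threads[[th]]$scores,
                                           function(s) (s - mu) / sdv)
  }
  session$ref$scores <- (session$ref$scores - mu) / sdv
  attr(session, "zscore") <- c(mean = mu, sd = sdv)
  session
}
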