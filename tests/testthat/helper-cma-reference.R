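# Independent transcription of the standard rank-mu CMA-ES equations
# (weighted recombination, cumulative step-size adaptation, rank-one plus
# rank-mu covariance update), written directly from the textbook
# pseudocode and sharing only the package's candidate-sampling convention:
# per generation, Z is a dim x lambda matrix of standard normals drawn
# column-wise, and candidate j is m + sigma * B %*% (D * Z[, j]).
# Used as the cross-check oracle for trajectory agreement under a shared
# seed; scores are maximized.
reference_cmaes <- function(fn, dim, mean0, sigma0, lambda, seed, generations) {
  mu <- floor(lambda / 2)
  w <- log(mu + 1 / 2) - log(1:mu)
  w <- w / sum(w)
  mueff <- sum(w)^2 / sum(w^2)
  cc <- (4 + mueff / dim) / (dim + 4 + 2 * mueff / dim)
  cs <- (mueff + 2) / (dim + mueff + 5)
  c1 <- 2 / ((dim + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((dim + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (dim + 1)) - 1) + cs
  chiN <- sqrt(dim) * (1 - 1 / (4 * dim) + 1 / (21 * dim^2))
  m <- mean0
  sigma <- sigma0
  C <- diag(dim)
  pc <- ps <- rep(0, dim)
  B <- diag(dim)
  Dd <- rep(1, dim)
  invsqrtC <- diag(dim)
  mean_trace <- matrix(NA_real_, generations, dim)
  sigma_trace <- numeric(generations)
  set.seed(seed)
  for (g in 1:generations) {
    Z <- matrix(rnorm(dim * lambda), nrow = dim)
    Y <- B %*% (Dd * Z)
    X <- m + sigma * Y
    fit <- apply(X, 2, fn)
    idx <- order(fit, decreasing = TRUE)[1:mu]
    yw <- as.numeric(Y[, idx, drop = FALSE] %*% w)
    m <- m + sigma * yw
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * (invsqrtC %*% yw)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (dim + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    Ymu <- Y[, idx, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %*% t(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ymu %*% diag(w, mu) %*% t(Ymu)
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    e <- eigen(C, symmetric = TRUE)
    Dd <- sqrt(pmax(e$values, 1e-20))
    B <- e$vectors
    invsqrtC <- B %*% diag(1 / Dd, dim) %*% t(B)
    mean_trace[g, ] <- m
    sigma_trace[g] <- sigma
  }
  list(mean = m, sigma = sigma, mean_trace = mean_trace,
       sigma_trace = sigma_trace)
}
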