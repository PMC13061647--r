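# Brute-force oracle for the evolution success procedure, coded separately
# from the package: Welch t statistic and two-sided p computed from the
# textbook formulas, every candidate consecutive pair enumerated, the pair
# with the highest pooled mean selected.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

oracle_evolution_success <- function(score_blocks, alpha) {
  B <- length(score_blocks)
  base <- c(score_blocks[[1]], score_blocks[[2]])
  best_mean <- -Inf
  best <- NULL
  for (b in 3:(B - 1)) {
    pool <- c(score_blocks[[b]], score_blocks[[b + 1]])
    if (mean(pool) > best_mean) {
      best_mean <- mean(pool)
      best <- pool
    }
  }
  wt <- oracle_welch_p(best, base)
  (mean(best) > mean(base)) && (wt$p < alpha)
}

# convergence-time oracle: the 80%-of-increase rule applied to the raw
# (unsmoothed) trajectory
oracle_convergence_block <- function(traj, level = 0.8) {
  inc <- max(traj) - traj[1]
  if (inc <= 0) return(NA_integer_)
  which(traj >= traj[1] + level * inc)[1]
}
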