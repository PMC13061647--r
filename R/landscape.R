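#' @title Tuning landscapes along pullback-metric eigen-axes
#'
#' @description After an evolution in the object generator's latent space,
#' the local geometry of the image manifold is charted by pulling an image
#' distance back to the latent space: the Hessian of
#' `dz -> D(G(z0), G(z0 + dz))` at zero acts as a local Riemannian metric,
#' and its eigenvectors within the class and noise sub-blocks give principal
#' directions of image change. Stimuli are sampled along each axis at nine
#' signed, distance-matched steps found by binary line search, responses are
#' measured, and tuning curves are classified as bell-shaped, ramp-shaped or
#' other.
#'
#' @name tuning_landscape
NULL

#' Summed squared pixel distance between two images
#'
#' The default metric for the pullback Hessian: for a linear generator
#' `G(z) = A z` it gives `H = 2 * t(A) %*% A` exactly.
#'
#' @param a,b image arrays of identical shape.
#' @return Non-negative scalar.
#' @export
pixel_sq_distance <- function(a, b) sum((a - b)^2)

#' Euclidean (root-sum-square) pixel distance between two images
#'
#' The default metric for distance-matched line search: monotone in the
#' step size near zero, and for a linear generator the step achieving
#' distance `d` along axis `v` is exactly `d / ||A v||`.
#'
#' @param a,b image arrays of identical shape.
#' @return Non-negative scalar.
#' @export
pixel_l2_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Pullback metric Hessian of an image distance
#'
#' Central finite-difference Hessian of `f(dz) = metric(G(z0), G(z0 + dz))`
#' at `dz = 0`, symmetrized as `(H + t(H)) / 2`.
#'
#' @param gen a `generator`.
#' @param metric image-distance function `function(a, b)`; must satisfy
#'   `metric(a, a) = 0` and symmetry.
#' @param z0 center latent vector.
#' @param h finite-difference step (> 0); a reasonable default is
#'   `0.01 * sigma0` for the space being probed.
#' @param check run a Richardson step-halving check on up to 10 random
#'   diagonal entries (default TRUE; warns if the two estimates disagree by
#'   more than 5% relative).
#' @return Object of class `pullback_metric` with `z0`, `H`, `h`, and
#'   `metric_name`.
#' @export
pullback_hessian <- function(gen, metric = pixel_sq_distance, z0, h = 1e-2,
                             check = TRUE) {
  stopifnot(h > 0, length(z0) == gen$latent_dim)
  img0 <- render_image(gen, z0)
  f <- function(dz) metric(img0, render_image(gen, z0 + dz))
  d <- gen$latent_dim
  H <- matrix(0, d, d)
  ei <- function(i, s) {
    v <- rep(0, d); v[i] <- s * h; v
  }
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    fp[i] <- f(ei(i, 1))
    fm[i] <- f(ei(i, -1))
    H[i, i] <- (fp[i] + fm[i]) / h^2 # f(0) = 0 by metric identity
    if (!is.finite(H[i, i])) {
      stop(sprintf("non-finite Hessian entry at coordinate pair (%d, %d)", i, i))
    }
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) {
      for (j in seq(i + 1, d)) {
        pp <- f(ei(i, 1) + ei(j, 1))
        pm <- f(ei(i, 1) + ei(j, -1))
        mp <- f(ei(i, -1) + ei(j, 1))
        mm <- f(ei(i, -1) + ei(j, -1))
        v <- (pp - pm - mp + mm) / (4 * h^2)
        if (!is.finite(v)) {
          stop(sprintf("non-finite Hessian entry at coordinate pair (%d, %d)",
                       i, j))
        }
        H[i, j] <- H[j, i] <- v
      }
    }
  }
  H <- (H + t(H)) / 2
  if (check) {
    idx <- sample.int(d, min(10, d))
    for (i in idx) {
      h2 <- h / 2
      v2 <- (f(ei(i, 1) / 2) + f(ei(i, -1) / 2)) / h2^2
      ref <- max(abs(H[i, i]), abs(v2), 1e-12)
      if (abs(v2 - H[i, i]) / ref > 0.05) {
        warning(sprintf(
          "Richardson check: diagonal %d differs by %.1f%% between h and h/2; consider a smaller h",
          i, 100 * abs(v2 - H[i, i]) / ref))
        break
      }
    }
  }
  structure(list(z0 = as.numeric(z0), H = H, h = h,
                 metric_name = deparse(substitute(metric))),
            class = "pullback_metric")
}

#' Eigen-axes of pullback-metric sub-blocks
#'
#' Eigen-decomposes each diagonal sub-block of the Hessian named in
#' `partition` (or the full matrix if `NULL`), sorts axes by descending
#' eigenvalue, and embeds the eigenvectors back into full latent
#' coordinates (zeros outside the block).
#'
#' @param pm a `pullback_metric` (or a plain symmetric matrix).
#' @param partition named list of index vectors (e.g. a generator's
#'   `$partition`), or `NULL` for the full space.
#' @return List of tuning axes; each a list with `subspace`, `index`,
#'   `lambda`, and unit vector `v` in full coordinates.
#' @export
subspace_eigendecomposition <- function(pm, partition = NULL) {
  H <- if (inherits(pm, "pullback_metric")) pm$H else pm
  d <- nrow(H)
  if (is.null(partition)) partition <- list(full = seq_len(d))
  axes <- list()
  for (nm in names(partition)) {
    idx <- partition[[nm]]
    stopifnot(all(idx >= 1), all(idx <= d))
    eg <- eigen(H[idx, idx, drop = FALSE], symmetric = TRUE)
    for (k in seq_along(idx)) {
      v <- rep(0, d)
      v[idx] <- eg$vectors[, k]
      axes[[length(axes) + 1L]] <- list(subspace = nm, index = k,
                                        lambda = eg$values[k], v = v)
    }
  }
  axes
}

#' Distance-matched step along a latent axis
#'
#' Finds the signed step `alpha` such that the image at `z0 + alpha * v`
#' sits at distance `d_target` from the center image, by doubling until the
#' distance brackets the target and then bisecting. The metric is checked
#' for monotonicity in `|alpha|` on the coarse doubling scan.
#'
#' @param gen a `generator`.
#' @param metric image-distance function (default [pixel_l2_distance()]).
#' @param z0 center latent vector.
#' @param v unit axis vector.
#' @param d_target target distance (> 0).
#' @param direction `+1` or `-1`.
#' @param tol distance tolerance (default 1e-3).
#' @param max_alpha bracket limit (default 1e3; beyond it the target is
#'   deemed unreachable and an error is raised).
#' @return The signed scalar `alpha`.
#' @export
line_search_alpha <- function(gen, metric = pixel_l2_distance, z0, v,
                              d_target, direction = 1, tol = 1e-3,
                              max_alpha = 1e3) {
  stopifnot(d_target > 0, direction %in% c(-1, 1))
  img0 <- render_image(gen, z0)
  g <- function(a) metric(img0, render_image(gen, z0 + direction * a * v))
  a <- tol
  prev <- 0
  repeat {
    val <- g(a)
    if (val < prev * (1 - 1e-6) - 1e-12) {
      stop(sprintf(
        "metric not monotone along axis: distance fell from %.4g to %.4g at alpha=%.4g",
        prev, val, a))
    }
    if (val >= d_target) break
    prev <- val
    a <- a * 2
    if (a > max_alpha) {
      stop(sprintf("target distance %.4g unreachable within |alpha| <= %g",
                   d_target, max_alpha))
    }
  }
  lo <- a / 2
  hi <- a
  # coarse monotonicity scan over the bracketed range (5% slack on the
  # running maximum tolerates numerical ripple, not genuine folds)
  scan <- vapply(seq(hi / 10, hi, length.out = 10), g, numeric(1))
  run_max <- cummax(scan)
  if (any(scan < run_max - 0.05 * pmax(run_max, 1e-12))) {
    k <- which(scan < run_max - 0.05 * pmax(run_max, 1e-12))[1]
    stop(sprintf(
      "metric not monotone along axis: coarse scan fell from %.4g to %.4g near alpha=%.4g",
      run_max[k], scan[k], direction * k * hi / 10))
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    val <- g(mid)
    if (abs(val - d_target) <= tol) return(direction * mid)
    if (val < d_target) lo <- mid else hi <- mid
  }
  stop("line search failed to converge within 200 bisections")
}

#' Nine distance-matched stimuli per tuning axis
#'
#' @param gen a `generator`.
#' @param z_star center latent (the mean of an evolution's final
#'   generation).
#' @param axes list of tuning axes from [subspace_eigendecomposition()].
#' @param distances signed target distances; the default nine include 0
#'   (the center image `G(z_star)` itself).
#' @param metric image-distance function for the matching.
#' @param tol line-search tolerance.
#' @return List of per-axis stimulus sets (`axis`, `distances`, `alphas`,
#'   `achieved`, `images`); axes whose line search fails are dropped with a
#'   message recorded in `attr(, "log")`.
#' @export
build_axis_stimuli <- function(gen, z_star, axes,
                               distances = c(0.40, 0.32, 0.24, 0.16, 0,
                                             -0.16, -0.24, -0.36, -0.40),
                               metric = pixel_l2_distance, tol = 1e-3) {
  out <- list()
  log_lines <- character()
  center <- render_image(gen, z_star)
  for (ax in axes) {
    res <- tryCatch({
      alphas <- vapply(distances, function(d) {
        if (d == 0) return(0)
        line_search_alpha(gen, metric, z_star, ax$v, abs(d),
                          direction = sign(d), tol = tol)
      }, numeric(1))
      imgs <- lapply(alphas, function(a) {
        if (a == 0) center else render_image(gen, z_star + a * ax$v)
      })
      achieved <- vapply(seq_along(alphas), function(i) {
        sign(distances[i]) * metric(center, imgs[[i]])
      }, numeric(1))
      list(axis = ax, distances = distances, alphas = alphas,
           achieved = achieved, images = imgs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_lines <- c(log_lines, sprintf(
        "axis %s#%d dropped: %s", ax$subspace, ax$index, conditionMessage(res)))
    } else {
      out[[length(out) + 1L]] <- res
    }
  }
  attr(out, "log") <- log_lines
  out
}

# Gaussian tuning fit r = b + a * exp(-(d - mu)^2 / (2 s^2)), a >= 0.
# Coarse grid over (mu, s) with closed-form (b, a) per node, then Nelder-Mead
# refinement. Robust against the tiny-n, noisy curves this pipeline sees.
fit_gaussian_curve <- function(d, r) {
  sse_ab <- function(mu, s) {
    g <- exp(-(d - mu)^2 / (2 * s^2))
    X <- cbind(1, g)
    cf <- tryCatch(qr.coef(qr(X), r), error = function(e) c(mean(r), 0))
    if (is.na(cf[2]) || cf[2] < 0) {
      cf <- c(mean(r), 0)
    }
    list(sse = sum((r - X %*% cf)^2), b = cf[1], a = cf[2])
  }
  best <- NULL
  for (mu in seq(-0.5, 0.5, by = 0.05)) {
    for (s in c(0.05, 0.1, 0.15, 0.2, 0.3, 0.45)) {
      cand <- sse_ab(mu, s)
      if (is.null(best) || cand$sse < best$sse) {
        best <- c(cand, mu = mu, s = s)
      }
    }
  }
  ref <- stats::optim(c(best$mu, log(best$s)), function(p) {
    sse_ab(p[1], exp(p[2]))$sse
  }, method = "Nelder-Mead")
  mu <- ref$par[1]
  s <- exp(ref$par[2])
  fin <- sse_ab(mu, s)
  sst <- sum((r - mean(r))^2)
  list(mu = mu, s = s, a = fin$a, b = fin$b,
       r2 = if (sst > 0) 1 - fin$sse / sst else 0)
}

#' Measure and classify a tuning curve along one axis
#'
#' Simulates `reps` trials per stimulus, runs a one-way ANOVA across the
#' nine distance levels, locates the peak of the trial-averaged response,
#' fits linear, Gaussian and Gaussian-process models, and classifies the
#' curve:
#'
#' * **bell** — significant ANOVA; Gaussian fit with interior peak
#'   (`|mu| < 0.4`), Gaussian R-squared exceeding the linear R-squared by at
#'   least 0.05, and unimodal GPR mean;
#' * **ramp** — significant ANOVA; significant linear slope (`p < 0.05`)
#'   and monotone GPR mean across the sampled range;
#' * **other** — significant ANOVA, neither shape;
#' * **nonsignificant** — ANOVA at or above `alpha` (fits skipped), also
#'   used for degenerate zero-variance responses.
#'
#' @param neuron a `neuron_model`.
#' @param stimuli one element of [build_axis_stimuli()] output.
#' @param reps trials per distance level (5-7; default 6).
#' @param seed integer seed.
#' @param alpha ANOVA significance level (default 0.01).
#' @param window scoring window in ms.
#' @return Object of class `tuning_curve`.
#' @export
measure_and_analyze <- function(neuron, stimuli, reps = 6, seed = 1L,
                                alpha = 0.01, window = c(50, 200)) {
  stopifnot(reps >= 2)
  d <- stimuli$distances
  nlev <- length(d)
  resp <- matrix(NA_real_, nrow = reps, ncol = nlev)
  for (k in seq_len(nlev)) {
    recs <- simulate_spikes(neuron, stimuli$images[[k]], n_trials = reps,
                            seed = derive_seed(seed, paste0("tc_", k)),
                            image_id = sprintf("d%+0.2f", d[k]))
    resp[, k] <- vapply(recs, function(r) {
      sum(r$spike_times >= window[1] & r$spike_times < window[2]) /
        ((window[2] - window[1]) / 1000)
    }, numeric(1))
  }
  means <- colMeans(resp)
  d_max <- d[which.max(means)]
  out <- list(axis = stimuli$axis, distances = d, responses = resp,
              means = means, d_max = d_max, reps = reps, alpha = alpha)
  if (stats::sd(as.numeric(resp)) == 0) {
    out$f <- NA_real_
    out$p <- NA_real_
    out$label <- "nonsignificant"
    class(out) <- "tuning_curve"
    return(out)
  }
  lev <- factor(rep(d, each = reps))
  av <- stats::anova(stats::lm(as.numeric(resp) ~ lev))
  out$f <- av$`F value`[1]
  out$p <- av$`Pr(>F)`[1]
  if (!is.finite(out$p) || out$p >= alpha) {
    out$label <- "nonsignificant"
    class(out) <- "tuning_curve"
    return(out)
  }
  dd <- rep(d, each = reps)
  rr <- as.numeric(resp)
  lin <- stats::lm(rr ~ dd)
  lin_r2 <- summary(lin)$r.squared
  lin_p <- summary(lin)$coefficients[2, 4]
  gau <- fit_gaussian_curve(dd, rr)
  grid <- seq(min(d), max(d), length.out = 81)
  gp <- gpr_smooth(d[order(d)], means[order(d)], xout = grid)
  dg <- diff(gp$mean)
  # monotonicity/unimodality judged against 2% of the curve's range, so
  # smoothing ripple at the noise floor does not flip the call
  slack <- 0.02 * diff(range(gp$mean)) + 1e-12
  n_peaks <- sum(dg[-length(dg)] > slack & dg[-1] < -slack)
  interior_max <- which.max(gp$mean) > 1 && which.max(gp$mean) < length(grid)
  unimodal <- n_peaks <= 1 && interior_max
  monotone <- all(dg >= -slack) || all(dg <= slack)
  out$fits <- list(
    linear = list(slope = unname(stats::coef(lin)[2]), r2 = lin_r2, p = lin_p),
    gaussian = gau,
    gpr = list(grid = grid, mean = gp$mean, method = gp$method))
  out$label <- if (abs(gau$mu) < 0.4 && gau$r2 >= lin_r2 + 0.05 && unimodal) {
    "bell"
  } else if (lin_p < 0.05 && monotone) {
    "ramp"
  } else {
    "other"
  }
  class(out) <- "tuning_curve"
  out
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s#%d  F=%.2f p=%.3g  d_max=%+.2f  label=%s\n",
              x$axis$subspace, x$axis$index,
              if (is.finite(x$f)) x$f else NA, x$p, x$d_max, x$label))
  invisible(x)
}

#' Population summary of tuning curves
#'
#' Among significantly modulated curves in each group, computes bell and
#' ramp fractions with beta-distribution confidence intervals, a
#' peak-location histogram with Wilson confidence intervals, two-proportion
#' z-tests contrasting the groups (bell and ramp), and a rank test on
#' absolute peak distances.
#'
#' @param curves list of `tuning_curve` objects.
#' @param success logical vector, one flag per curve (whether the preceding
#'   evolution succeeded).
#' @param conf confidence level for the intervals.
#' @return List with per-group summaries and group contrasts.
#' @export
summarize_population <- function(curves, success, conf = 0.95) {
  stopifnot(length(curves) == length(success))
  labels <- vapply(curves, `[[`, character(1), "label")
  d_max <- vapply(curves, `[[`, numeric(1), "d_max")
  sig <- labels != "nonsignificant"
  groups <- list(successful = success & sig, unsuccessful = !success & sig)
  if (any(vapply(groups, sum, integer(1)) == 0)) {
    stop("each group needs at least one significantly modulated curve")
  }
  dists <- sort(unique(unlist(lapply(curves, `[[`, "distances"))))
  summ <- lapply(groups, function(g) {
    n <- sum(g)
    nb <- sum(labels[g] == "bell")
    nr <- sum(labels[g] == "ramp")
    peaks <- vapply(dists, function(dd) sum(abs(d_max[g] - dd) < 1e-9),
                    numeric(1))
    list(n = n, bell = nb, ramp = nr,
         bell_frac = beta_ci(nb, n, conf), ramp_frac = beta_ci(nr, n, conf),
         peak_hist = data.frame(
           distance = dists, count = peaks,
           t(vapply(peaks, function(k) wilson_ci(k, n, conf), numeric(3)))),
         mean_abs_peak = mean(abs(d_max[g])))
  })
  z_bell <- two_proportion_z(summ$successful$bell, summ$successful$n,
                             summ$unsuccessful$bell, summ$unsuccessful$n)
  z_ramp <- two_proportion_z(summ$successful$ramp, summ$successful$n,
                             summ$unsuccessful$ramp, summ$unsuccessful$n)
  peak_rank <- tryCatch(
    suppressWarnings(stats::wilcox.test(abs(d_max[groups$successful]),
                                        abs(d_max[groups$unsuccessful]))),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_))
  list(groups = summ, z_bell = z_bell, z_ramp = z_ramp,
       peak_rank_test = list(w = unname(peak_rank$statistic),
                             p = peak_rank$p.value))
}

#' Full Hessian tuning experiment on a synthetic neuron
#'
#' Convenience driver: pullback Hessian at the evolution endpoint, top
#' eigen-axes per subspace, distance-matched stimuli, and one measured,
#' classified tuning curve per surviving axis.
#'
#' @param neuron a `neuron_model`.
#' @param gen a `generator` (normally the partitioned object generator).
#' @param z_star center latent vector.
#' @param n_axes_per_subspace top eigen-axes kept per subspace (default 10).
#' @param reps trials per distance level.
#' @param seed integer seed.
#' @param h finite-difference step for the Hessian.
#' @param alpha ANOVA level.
#' @param distances signed target distances.
#' @return List with the `pullback_metric`, the retained axes, and the list
#'   of `tuning_curve`s.
#' @export
run_hessian_tuning <- function(neuron, gen, z_star, n_axes_per_subspace = 10,
                               reps = 6, seed = 1L, h = 1e-3, alpha = 0.01,
                               distances = c(0.40, 0.32, 0.24, 0.16, 0,
                                             -0.16, -0.24, -0.36, -0.40)) {
  pm <- pullback_hessian(gen, pixel_sq_distance, z_star, h = h, check = FALSE)
  axes <- subspace_eigendecomposition(pm, gen$partition)
  keep <- unlist(lapply(split(axes, vapply(axes, `[[`, character(1), "subspace")),
                        function(g) g[seq_len(min(n_axes_per_subspace, length(g)))]),
                 recursive = FALSE)
  stim <- build_axis_stimuli(gen, z_star, keep)
  curves <- lapply(seq_along(stim), function(i) {
    measure_and_analyze(neuron, stim[[i]], reps = reps,
                        seed = derive_seed(seed, paste0("axis_", i)),
                        alpha = alpha)
  })
  list(metric = pm, axes = keep, stimuli_log = attr(stim, "log"),
       curves = curves)
}
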