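#' @title PSTH construction and temporal analyses
#'
#' @description Peri-stimulus time histograms are built on a 1 ms grid over
#' the recording window `[-50, 400)` ms by convolving discretized spike
#' times with a Gaussian density (sigma = 2 ms by default). The smoothing
#' kernel is truncated at the window edges and renormalized per source bin,
#' so spike mass is conserved exactly within the grid.
#'
#' @name psth
NULL

#' Compute a trial-averaged PSTH
#'
#' @param records list of spike records (>= 1 trial; all for one condition).
#' @param bin bin width in ms (fixed at 1).
#' @param sigma Gaussian smoothing s.d. in ms (default 2).
#' @return Object of class `psth`: `time` (bin left edges, ms), `rate`
#'   (spikes/s), `sigma`, `n_trials`.
#' @export
compute_psth <- function(records, bin = 1, sigma = 2) {
  if (length(records) == 0) stop("no spike records supplied")
  w <- resp_window()
  edges <- seq(w[1], w[2], by = bin)
  n <- length(edges) - 1
  counts <- rep(0, n)
  for (r in records) {
    if (length(r$spike_times)) {
      idx <- floor(r$spike_times - w[1]) + 1
      idx <- idx[idx >= 1 & idx <= n]
      counts <- counts + tabulate(idx, nbins = n)
    }
  }
  K <- ceiling(4 * sigma)
  offs <- seq(-K, K)
  kw <- stats::dnorm(offs, sd = sigma)
  kw <- kw / sum(kw)
  # per-source-bin renormalization: weight mass falling outside the grid is
  # redistributed so each spike contributes exactly 1
  inside <- rep(0, n)
  for (o in offs) {
    lo <- max(1, 1 - o); hi <- min(n, n - o)
    if (lo <= hi) inside[lo:hi] <- inside[lo:hi] + kw[o + K + 1]
  }
  src <- counts / inside
  sm <- rep(0, n)
  for (o in offs) {
    lo <- max(1, 1 + o); hi <- min(n, n + o)
    if (lo <= hi) sm[lo:hi] <- sm[lo:hi] + src[(lo - o):(hi - o)] * kw[o + K + 1]
  }
  structure(list(time = edges[-length(edges)],
                 rate = sm / length(records) / (bin / 1000),
                 sigma = sigma, bin = bin, n_trials = length(records)),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g ms, sigma=%g ms, %d trial(s), peak %.1f spk/s\n",
              length(x$time), x$bin, x$sigma, x$n_trials, max(x$rate)))
  invisible(x)
}

psth_mean_rate <- function(p, window) {
  sel <- p$time >= window[1] & p$time < window[2]
  mean(p$rate[sel])
}

#' Temporal attribution of an activation change
#'
#' Identifies the block with the highest mean PSTH rate in `[50, 200)` ms
#' (`B_hat`), forms the difference PSTH against the first block, normalizes
#' it by the summed 0-200 ms difference, and integrates it over
#' non-overlapping time bins. When the denominator is nonzero the bin
#' weights sum to 1.
#'
#' @param block_psths list of `psth` objects, one per block, in block order
#'   (>= 2 blocks).
#' @param bin_width attribution bin width in ms; one of 5, 10, 20, 25, 50.
#' @return List with `edges` (bin left edges over `[0, 200)`), `weights`
#'   (unitless fractions), `b_hat`, `b0`, and `undefined` flag (zero
#'   denominator).
#' @export
temporal_attribution <- function(block_psths, bin_width = 10) {
  stopifnot(length(block_psths) >= 2, bin_width %in% c(5, 10, 20, 25, 50))
  means <- vapply(block_psths, psth_mean_rate, numeric(1), window = c(50, 200))
  b_hat <- which.max(means)
  p1 <- block_psths[[b_hat]]
  p0 <- block_psths[[1]]
  sel <- p0$time >= 0 & p0$time < 200
  d <- p1$rate[sel] - p0$rate[sel]
  denom <- sum(d)
  edges <- seq(0, 200 - bin_width, by = bin_width)
  if (denom == 0) {
    return(list(edges = edges, weights = rep(NA_real_, length(edges)),
                b_hat = b_hat, b0 = 1L, undefined = TRUE))
  }
  t0 <- p0$time[sel]
  grp <- findInterval(t0, seq(0, 200, by = bin_width), rightmost.closed = FALSE)
  weights <- as.numeric(tapply(d, grp, sum)) / denom
  list(edges = edges, weights = weights, b_hat = b_hat, b0 = 1L,
       undefined = FALSE)
}

#' Session maximum block-averaged firing rate
#'
#' The normalization constant used for PSTH distances and time-binned
#' trajectories: the maximum over both threads of the block-mean score.
#'
#' @param session an `evolution_session`.
#' @return Scalar spikes/s.
#' @export
session_max_rate <- function(session) {
  max(c(block_means(session$threads$a), block_means(session$threads$b)))
}

#' Time-binned evolution trajectory of a session
#'
#' Per thread, block and time bin over `[0, 200)` ms, the mean firing rate
#' across that block's images, normalized by the session maximum over
#' threads, blocks, and bins inside `(50, 200)` ms.
#'
#' @param session an `evolution_session` with stored spike records.
#' @param bin_width time bin width in ms (default 10).
#' @return List with `rates` (array `thread x block x bin`, normalized),
#'   `raw` (same, spikes/s), `bin_edges`, and `norm` (the normalizer).
#' @export
time_binned_trajectory <- function(session, bin_width = 10) {
  stopifnot(!is.null(session$threads$a), !is.null(session$threads$b))
  edges <- seq(0, 200, by = bin_width)
  nb <- length(edges) - 1
  B <- session$config$blocks
  raw <- array(NA_real_, dim = c(2, B, nb),
               dimnames = list(c("a", "b"), NULL, NULL))
  for (ti in 1:2) {
    th <- c("a", "b")[ti]
    for (blk in seq_len(B)) {
      ids <- session$threads[[th]]$image_ids[[blk]]
      recs <- unlist(session$spikes[ids], recursive = FALSE)
      if (length(recs) == 0) next
      times <- unlist(lapply(recs, `[[`, "spike_times"))
      cnt <- if (length(times)) {
        tabulate(findInterval(times[times >= 0 & times < 200], edges),
                 nbins = nb)
      } else rep(0, nb)
      raw[ti, blk, ] <- cnt / length(recs) / (bin_width / 1000)
    }
  }
  centers <- edges[-length(edges)] + bin_width / 2
  in_win <- centers > 50 & centers < 200
  norm <- max(raw[, , in_win], na.rm = TRUE)
  list(rates = raw / norm, raw = raw, bin_edges = edges, norm = norm)
}

#' Compare time-binned trajectories across sessions
#'
#' For each time bin and block, runs a paired t-test across sessions between
#' the two threads' normalized binned rates, with Benjamini-Hochberg false
#' discovery rate correction across blocks within each bin.
#'
#' @param sessions list of `evolution_session` objects.
#' @param bin_width time bin width in ms (default 10).
#' @param alpha FDR level (default 0.05).
#' @return List with `mean_a`, `mean_b` (block x bin matrices of
#'   across-session means), `p` (raw p-values), `p_adj`, `significant`
#'   (logical, BH-corrected at `alpha`), and `bin_edges`.
#' @export
time_binned_comparison <- function(sessions, bin_width = 10, alpha = 0.05) {
  tbs <- lapply(sessions, time_binned_trajectory, bin_width = bin_width)
  B <- min(vapply(tbs, function(x) dim(x$rates)[2], integer(1)))
  nb <- dim(tbs[[1]]$rates)[3]
  p <- matrix(NA_real_, nrow = B, ncol = nb)
  mean_a <- mean_b <- matrix(NA_real_, nrow = B, ncol = nb)
  for (blk in seq_len(B)) {
    for (bin in seq_len(nb)) {
      va <- vapply(tbs, function(x) x$rates["a", blk, bin], numeric(1))
      vb <- vapply(tbs, function(x) x$rates["b", blk, bin], numeric(1))
      mean_a[blk, bin] <- mean(va)
      mean_b[blk, bin] <- mean(vb)
      if (length(va) >= 2 && stats::sd(va - vb) > 0) {
        p[blk, bin] <- stats::t.test(va, vb, paired = TRUE)$p.value
      } else if (length(va) >= 2) {
        p[blk, bin] <- 1
      }
    }
  }
  p_adj <- apply(p, 2, stats::p.adjust, method = "BH")
  list(mean_a = mean_a, mean_b = mean_b, p = p, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj < alpha,
       bin_edges = tbs[[1]]$bin_edges)
}

#' Distance measures between two PSTHs
#'
#' `d_psth` integrates the absolute difference between the curves;
#' `d_act` integrates the signed difference (equivalently the difference of
#' mean levels times the window length). Curves are expected to be
#' normalized by the neuron's maximum block-average rate beforehand (see
#' [session_max_rate()]); integration is over time in seconds.
#'
#' @param pa,pb `psth` objects on the same time grid.
#' @return Named numeric vector `c(d_psth, d_act)`; always
#'   `d_psth >= |d_act|`, with equality iff the difference never changes
#'   sign.
#' @export
psth_distance <- function(pa, pb) {
  if (length(pa$time) != length(pb$time) || any(pa$time != pb$time)) {
    stop("PSTH time grids do not match")
  }
  dt <- pa$bin / 1000
  d <- pa$rate - pb$rate
  c(d_psth = sum(abs(d)) * dt, d_act = sum(d) * dt)
}

#' Normalize a PSTH by a reference rate
#'
#' @param p a `psth`.
#' @param max_rate normalizing rate in spikes/s (e.g. [session_max_rate()]).
#' @return The PSTH with `rate` divided by `max_rate`.
#' @export
normalize_psth <- function(p, max_rate) {
  stopifnot(max_rate > 0)
  p$rate <- p$rate / max_rate
  p
}
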