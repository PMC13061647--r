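#' @title Synthetic visually tuned spiking neurons
#'
#' @description The package contains no recorded neural data; every analysis
#' is exercised against a synthetic neuron model that stands in for the
#' response function `f` driving closed-loop optimization. The model is a
#' stand-in by construction: it has a preferred local template, Gaussian
#' tuning in patch-similarity space, separate early and late temporal
#' response kernels (each optionally bound to its own feature preference,
#' emulating late-emerging selectivity), and inhomogeneous-Poisson spiking.
#'
#' The recording window is fixed at `[-50, 400)` ms around image onset
#' (`t = 0`), half-open, at 1 ms resolution.
#'
#' @name neurons
NULL

# recording window (ms, half-open) shared across the package
resp_window <- function() c(-50, 400)

#' Construct a synthetic tuned neuron
#'
#' The instantaneous rate for an image is
#' `lambda(t) = baseline + s * sum_k gain_k * kernel_k(t) * sim_k(image)`
#' where `kernel_k` is a Gaussian bump at `latency_k` (zero before onset),
#' `sim_k = exp(-delta_k^2 / (2 * tuning_width^2))` is Gaussian tuning in the
#' RMS distance `delta_k` between the image patch at the neuron's locus and
#' preference `k`, and `s` is fixed at construction so that a fully preferred
#' image peaks exactly at `peak_rate`.
#'
#' @param template preferred image patch, a `ph x pw x 3` array in `[0, 1]`
#'   (or a numeric vector reshaped to one).
#' @param locus integer `c(row, col)` of the patch's top-left corner inside
#'   the stimulus image.
#' @param tuning_width Gaussian tuning scale in RMS-pixel units.
#' @param baseline_rate,peak_rate firing rates in spikes/s,
#'   `0 <= baseline_rate <= peak_rate`.
#' @param kernels named list of temporal kernels; each a list with `latency`
#'   (ms), `width` (ms), `gain` (relative weight), optional `template`
#'   (an alternative patch preference bound to that kernel), and optional
#'   `tuning_width` overriding the neuron-level value (e.g. broad early,
#'   sharp late tuning, emulating coarse-to-fine response dynamics).
#' @param image_size integer `c(height, width)` of stimulus images this
#'   neuron expects.
#' @return Object of class `neuron_model`.
#' @export
neuron_model <- function(template, locus = c(1L, 1L), tuning_width = 0.25,
                         baseline_rate = 5, peak_rate = 80,
                         kernels = list(
                           early = list(latency = 70, width = 18, gain = 0.6),
                           late = list(latency = 140, width = 30, gain = 0.4)),
                         image_size = c(64L, 64L)) {
  stopifnot(baseline_rate >= 0, baseline_rate <= peak_rate)
  if (!is.array(template)) {
    side <- round(sqrt(length(template) / 3))
    stopifnot(side * side * 3 == length(template))
    template <- array(template, dim = c(side, side, 3))
  }
  stopifnot(length(dim(template)) == 3, dim(template)[3] == 3)
  for (k in kernels) {
    stopifnot(is.numeric(k$latency), is.numeric(k$width), k$width > 0,
              is.numeric(k$gain), k$gain >= 0)
  }
  # normalize the combined kernel so full similarity peaks at peak_rate
  tt <- seq(0, 399)
  prof <- rowSums(vapply(kernels, function(k) {
    k$gain * exp(-(tt - k$latency)^2 / (2 * k$width^2))
  }, numeric(length(tt))))
  scale <- if (max(prof) > 0) (peak_rate - baseline_rate) / max(prof) else 0
  structure(list(template = template, locus = as.integer(locus),
                 tuning_width = tuning_width, baseline_rate = baseline_rate,
                 peak_rate = peak_rate, kernels = kernels,
                 kernel_scale = scale, image_size = as.integer(image_size)),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf(
    "<neuron_model> locus=(%d,%d) patch=%dx%d width=%.3g rates=[%.3g, %.3g] spk/s, %d kernel(s)\n",
    x$locus[1], x$locus[2], dim(x$template)[1], dim(x$template)[2],
    x$tuning_width, x$baseline_rate, x$peak_rate, length(x$kernels)))
  invisible(x)
}

extract_locus_patch <- function(neuron, image, template) {
  ph <- dim(template)[1]
  pw <- dim(template)[2]
  r <- neuron$locus[1]
  c <- neuron$locus[2]
  if (r + ph - 1 > dim(image)[1] || c + pw - 1 > dim(image)[2]) {
    stop("neuron locus patch exceeds image bounds")
  }
  image[r:(r + ph - 1), c:(c + pw - 1), , drop = FALSE]
}

tuning_similarity <- function(neuron, image, template, width = NULL) {
  patch <- extract_locus_patch(neuron, image, template)
  delta <- sqrt(mean((patch - template)^2))
  w <- width %||% neuron$tuning_width
  exp(-delta^2 / (2 * w^2))
}

#' Instantaneous firing-rate profile for an image
#'
#' @param neuron a `neuron_model`.
#' @param image stimulus image array matching the neuron's `image_size`.
#' @return List with `time` (ms grid over `[-50, 400)`) and `rate`
#'   (spikes/s, non-negative).
#' @export
simulate_response <- function(neuron, image) {
  stopifnot(inherits(neuron, "neuron_model"))
  if (!all(dim(image)[1:2] == neuron$image_size)) {
    stop(sprintf("image size %dx%d does not match neuron's expected %dx%d",
                 dim(image)[1], dim(image)[2],
                 neuron$image_size[1], neuron$image_size[2]))
  }
  w <- resp_window()
  tt <- seq(w[1], w[2] - 1)
  rate <- rep(neuron$baseline_rate, length(tt))
  post <- tt >= 0
  for (k in neuron$kernels) {
    tmpl <- k$template %||% neuron$template
    sim <- tuning_similarity(neuron, image, tmpl, k$tuning_width)
    bump <- exp(-(tt[post] - k$latency)^2 / (2 * k$width^2))
    rate[post] <- rate[post] + neuron$kernel_scale * k$gain * bump * sim
  }
  list(time = tt, rate = pmax(rate, 0))
}

#' Simulate Poisson spike trains for an image
#'
#' Draws `n_trials` independent inhomogeneous-Poisson realizations of the
#' neuron's rate profile at 1 ms resolution (bin-wise Poisson counts with
#' uniform within-bin placement). Deterministic given `seed`.
#'
#' @inheritParams simulate_response
#' @param n_trials number of trials (>= 1).
#' @param seed integer seed.
#' @param image_id,block_id identifying tokens stored on each record.
#' @return List of spike records; each a list with `image_id`, `block_id`,
#'   `trial_id`, and sorted `spike_times` (ms in `[-50, 400)`).
#' @export
simulate_spikes <- function(neuron, image, n_trials = 1, seed = 1L,
                            image_id = "img", block_id = 1L) {
  stopifnot(n_trials >= 1)
  prof <- simulate_response(neuron, image)
  p_bin <- prof$rate / 1000 # expected count per 1 ms bin
  with_seed(seed, {
    lapply(seq_len(n_trials), function(tr) {
      counts <- stats::rpois(length(p_bin), p_bin)
      times <- rep(prof$time, counts) + stats::runif(sum(counts))
      list(image_id = image_id, block_id = block_id, trial_id = tr,
           spike_times = sort(times))
    })
  })
}

#' Flatten spike records to a data frame
#'
#' @param records list of spike records as returned by [simulate_spikes()].
#' @return `data.frame` with columns `image_id`, `block_id`, `trial_id`,
#'   `spike_time_ms` (one row per spike; trials with no spikes are absent).
#' @export
spikes_to_df <- function(records) {
  rows <- lapply(records, function(r) {
    if (length(r$spike_times) == 0) return(NULL)
    data.frame(image_id = r$image_id, block_id = r$block_id,
               trial_id = r$trial_id, spike_time_ms = r$spike_times)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(image_id = character(), block_id = integer(),
                      trial_id = integer(), spike_time_ms = numeric())
  }
  out
}
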