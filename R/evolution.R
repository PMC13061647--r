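#' @title Paired closed-loop evolution
#'
#' @description One *evolution session* targets a single synthetic driver
#' neuron with two parallel optimization threads, one per generator latent
#' space, mirroring a paired in-vivo design: in every block both threads'
#' candidate images plus a fixed set of interleaved reference images are
#' presented, each image's spike response is scored by the mean firing rate
#' in a post-onset window, and the scores are fed back to each thread's
#' CMA-ES optimizer.
#'
#' @name evolution
NULL

#' Score an image from its spike records
#'
#' Mean over trials of the spike count inside `window`, divided by the
#' window length, in spikes/s.
#'
#' @param records list of spike records for one image (>= 1 trial).
#' @param window numeric `c(lo, hi)` ms, half-open (default `c(50, 200)`).
#' @return Firing rate in spikes/s.
#' @export
score_image <- function(records, window = c(50, 200)) {
  if (length(records) == 0) stop("no spike records supplied")
  counts <- vapply(records, function(r) {
    sum(r$spike_times >= window[1] & r$spike_times < window[2])
  }, numeric(1))
  mean(counts) / ((window[2] - window[1]) / 1000)
}

#' Default paired-evolution configuration
#'
#' @param blocks number of generations/blocks (default 40; typical sessions
#'   run 10-60, the success test needs at least 4).
#' @param popsize images proposed per thread per block (default 30).
#' @param trials_per_image presentations per image (default 1, as in rapid
#'   serial presentation where each image is shown once).
#' @param n_ref fixed reference images interleaved each block (default 10;
#'   drawn 5 + 5 from the two generators' priors once per session).
#' @param window scoring window in ms (default `c(50, 200)`).
#' @param sigma_texture,sigma_object initial CMA-ES step sizes; applied by
#'   partition presence (a partitioned latent space gets the object step).
#' @param stim_ms,isi_ms presentation timing metadata (100 ms on / 150 ms
#'   off); recorded on the session, trials are simulated independently.
#' @return Named list of settings.
#' @export
evolution_config <- function(blocks = 40, popsize = 30, trials_per_image = 1,
                             n_ref = 10, window = c(50, 200),
                             sigma_texture = 3.0, sigma_object = 0.09,
                             stim_ms = 100, isi_ms = 150) {
  stopifnot(blocks >= 4, blocks <= 60, popsize >= 4)
  as.list(environment())
}

default_sigma <- function(gen, config) {
  if (is.null(gen$partition)) config$sigma_texture else config$sigma_object
}

#' Run a paired closed-loop evolution session
#'
#' @param neuron a `neuron_model` (the driver).
#' @param gen_a,gen_b `generator` objects for the two threads (conventionally
#'   texture and object).
#' @param config list from [evolution_config()].
#' @param seed master integer seed; all per-component streams are derived
#'   from it, so equal seeds give identical sessions.
#' @return Object of class `evolution_session` with threads (per-block
#'   latents, scores, image ids, optimizer traces), reference responses, all
#'   spike records, the config snapshot and the master seed.
#' @export
run_paired_evolution <- function(neuron, gen_a, gen_b,
                                 config = evolution_config(), seed = 1L) {
  for (g in list(gen_a, gen_b)) {
    if (!all(c(g$height, g$width) == neuron$image_size)) {
      stop(sprintf("generator '%s' renders %dx%d but neuron expects %dx%d",
                   g$name, g$height, g$width,
                   neuron$image_size[1], neuron$image_size[2]))
    }
  }
  gens <- list(a = gen_a, b = gen_b)
  states <- list(
    a = cma_init(gen_a$latent_dim, sigma0 = default_sigma(gen_a, config),
                 popsize = config$popsize, seed = derive_seed(seed, "cma_a")),
    b = cma_init(gen_b$latent_dim, sigma0 = default_sigma(gen_b, config),
                 popsize = config$popsize, seed = derive_seed(seed, "cma_b")))
  # fixed reference stimuli: half from each generator's prior
  n_half <- config$n_ref - config$n_ref %/% 2
  ref_lat <- list(
    a = gen_a$sample_prior(n_half, derive_seed(seed, "ref_a"), scale = 0.5),
    b = gen_b$sample_prior(config$n_ref %/% 2, derive_seed(seed, "ref_b"),
                           scale = 0.5))
  ref_imgs <- c(lapply(seq_len(nrow(ref_lat$a)), function(i)
    render_image(gen_a, ref_lat$a[i, ])),
    lapply(seq_len(nrow(ref_lat$b)), function(i)
      render_image(gen_b, ref_lat$b[i, ])))
  ref_ids <- sprintf("ref_%02d", seq_along(ref_imgs))

  threads <- lapply(c("a", "b"), function(th) {
    list(generator = gens[[th]]$name, latents = list(), scores = list(),
         image_ids = list(), trace = list(means = NULL, sigma = numeric()))
  })
  names(threads) <- c("a", "b")
  ref_scores <- matrix(NA_real_, nrow = config$blocks, ncol = length(ref_imgs),
                       dimnames = list(NULL, ref_ids))
  spikes <- list()
  presentation <- list()
  log_lines <- character()

  batch <- list(a = cma_ask(states$a), b = cma_ask(states$b))
  states$a <- batch$a$state
  states$b <- batch$b$state

  for (blk in seq_len(config$blocks)) {
    Xa <- batch$a$X
    Xb <- batch$b$X
    ids_a <- sprintf("a_b%02d_i%02d", blk, seq_len(config$popsize))
    ids_b <- sprintf("b_b%02d_i%02d", blk, seq_len(config$popsize))
    stim <- c(
      lapply(seq_len(config$popsize), function(i) list(id = ids_a[i], th = "a", i = i)),
      lapply(seq_len(config$popsize), function(i) list(id = ids_b[i], th = "b", i = i)),
      lapply(seq_along(ref_ids), function(i) list(id = ref_ids[i], th = "ref", i = i)))
    ord <- with_seed(derive_seed(seed, paste0("interleave_", blk)),
                     sample.int(length(stim)))
    presentation[[blk]] <- vapply(stim[ord], `[[`, character(1), "id")
    sc <- list(a = rep(NA_real_, config$popsize),
               b = rep(NA_real_, config$popsize))
    for (s in stim[ord]) {
      img <- tryCatch({
        if (s$th == "ref") ref_imgs[[s$i]]
        else render_image(gens[[s$th]], batch[[s$th]]$X[, s$i])
      }, error = function(e) e)
      if (inherits(img, "error")) {
        log_lines <- c(log_lines, sprintf(
          "block %d: render failed for %s (%s); score excluded", blk, s$id,
          conditionMessage(img)))
        next
      }
      rec <- simulate_spikes(neuron, img,
                             n_trials = config$trials_per_image,
                             seed = derive_seed(seed,
                                                sprintf("spk_%s_b%02d", s$id, blk)),
                             image_id = s$id, block_id = blk)
      # references recur every block; key their records per block
      key <- if (s$th == "ref") sprintf("%s_b%02d", s$id, blk) else s$id
      spikes[[key]] <- rec
      val <- score_image(rec, config$window)
      if (s$th == "ref") ref_scores[blk, s$i] <- val else sc[[s$th]][s$i] <- val
    }
    for (th in c("a", "b")) {
      threads[[th]]$latents[[blk]] <- t(batch[[th]]$X)
      threads[[th]]$scores[[blk]] <- sc[[th]]
      threads[[th]]$image_ids[[blk]] <- if (th == "a") ids_a else ids_b
      threads[[th]]$trace$means <- rbind(threads[[th]]$trace$means,
                                         states[[th]]$mean)
      threads[[th]]$trace$sigma <- c(threads[[th]]$trace$sigma,
                                     states[[th]]$sigma)
      states[[th]] <- cma_tell(states[[th]], sc[[th]])
      if (blk < config$blocks) {
        nxt <- cma_ask(states[[th]])
        states[[th]] <- nxt$state
        batch[[th]] <- nxt
      }
    }
  }
  for (th in c("a", "b")) class(threads[[th]]) <- "evolution_thread"
  structure(list(
    neuron = neuron, threads = threads,
    generators = list(a = gen_a$recipe, b = gen_b$recipe),
    final_mean = list(a = states$a$mean, b = states$b$mean),
    ref = list(ids = ref_ids, latents = ref_lat, scores = ref_scores),
    spikes = spikes, presentation = presentation,
    config = config, master_seed = as.integer(seed), log = log_lines),
    class = "evolution_session")
}

#' @export
print.evolution_session <- function(x, ...) {
  cat(sprintf(
    "<evolution_session> seed=%d blocks=%d popsize=%d threads: %s vs %s\n",
    x$master_seed, x$config$blocks, x$config$popsize,
    x$threads$a$generator, x$threads$b$generator))
  for (th in c("a", "b")) {
    sc <- block_means(x$threads[[th]])
    cat(sprintf("  thread %s (%s): block mean %.2f -> %.2f spk/s\n", th,
                x$threads[[th]]$generator, sc[1], sc[length(sc)]))
  }
  invisible(x)
}

#' Per-block mean scores of a thread
#'
#' @param thread an `evolution_thread`.
#' @return Numeric vector of block means (NA scores dropped).
#' @export
block_means <- function(thread) {
  vapply(thread$scores, function(s) mean(s, na.rm = TRUE), numeric(1))
}

#' Per-block standard errors of a thread
#'
#' @param thread an `evolution_thread`.
#' @return Numeric vector of block-wise s.e.m. values.
#' @export
block_sems <- function(thread) {
  vapply(thread$scores, function(s) {
    s <- s[is.finite(s)]
    stats::sd(s) / sqrt(length(s))
  }, numeric(1))
}
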