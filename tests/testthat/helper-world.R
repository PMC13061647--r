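# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

h_tex32 <- function() fixture("tex32", function()
  make_texture_generator(32, 32, 24, seed = 11))

h_obj32 <- function() fixture("obj32", function()
  make_object_generator(32, 32, 6, 6, seed = 11))

h_tex64 <- function() fixture("tex64", function()
  make_texture_generator(64, 64, 16, seed = 3))

h_obj64 <- function() fixture("obj64", function()
  make_object_generator(64, 64, 8, 8, seed = 3))

# a random linear generator G(z) = A z (unclipped), with A exposed
h_linear_gen <- function(d, npx, seed, sd = 0.05) {
  A <- with_seed(seed, matrix(stats::rnorm(npx * npx * 3 * d, sd = sd),
                              ncol = d))
  g <- structure(list(
    name = "linear", latent_dim = d, height = npx, width = npx,
    partition = NULL,
    render = function(z) array(A %*% z, dim = c(npx, npx, 3)),
    A = A,
    sample_prior = function(n, seed, scale = 1)
      with_seed(seed, matrix(stats::rnorm(n * d, sd = scale), nrow = n))),
    class = "generator")
  g
}

# neuron whose rate is flat (baseline only) regardless of the image
h_null_neuron <- function(image_size = c(32L, 32L), baseline = 20) {
  neuron_model(template = array(0.5, c(8, 8, 3)), locus = c(1L, 1L),
               tuning_width = 1, baseline_rate = baseline,
               peak_rate = baseline, image_size = image_size)
}

# quick paired session at reduced scale (32 px generators)
h_small_session <- function(neuron = NULL, seed = 1L, blocks = 10,
                            popsize = 6, trials = 1) {
  if (is.null(neuron)) neuron <- h_null_neuron()
  cfg <- evolution_config(blocks = blocks, popsize = popsize,
                          trials_per_image = trials, n_ref = 4)
  run_paired_evolution(neuron, h_tex32(), h_obj32(), cfg, seed = seed)
}

# minimal stand-in session for trajectory-level functions
h_fake_session <- function(bm_a, bm_b, n_per_block = 3) {
  mk <- function(bm) {
    structure(list(generator = "x",
                   scores = lapply(bm, function(m) rep(m, n_per_block))),
              class = "evolution_thread")
  }
  structure(list(threads = list(a = mk(bm_a), b = mk(bm_b)),
                 config = list(blocks = length(bm_a))),
            class = "evolution_session")
}

# synthetic PSTH object on the standard grid without spike simulation
h_psth <- function(rate, sigma = 2, n_trials = 1) {
  tt <- seq(-50, 399)
  if (length(rate) == 1) rate <- rep(rate, length(tt))
  structure(list(time = tt, rate = rate, sigma = sigma, bin = 1,
                 n_trials = n_trials), class = "psth")
}

# richer texture dictionary: attribution analyses need a stimulus ensemble
# whose local patches vary in enough dimensions to identify readouts
h_tex64r <- function() fixture("tex64r", function()
  make_texture_generator(64, 64, 128, seed = 3))
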