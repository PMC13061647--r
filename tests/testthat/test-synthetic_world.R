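test_that("texture generator: mid-gray origin, pre-clip linearity, argument errors", {
  tg <- h_tex32()
  expect_true(all(render_image(tg, rep(0, tg$latent_dim)) == 0.5))
  z1 <- with_seed(1, rnorm(tg$latent_dim))
  z2 <- with_seed(2, rnorm(tg$latent_dim))
  lhs <- tg$render_preclip(z1 + z2)
  rhs <- tg$render_preclip(z1) + tg$render_preclip(z2) -
    tg$render_preclip(rep(0, tg$latent_dim))
  expect_lt(max(abs(lhs - rhs)), 1e-12)
  expect_error(make_texture_generator(0, 32, 24), "positive")
  expect_error(make_texture_generator(32, 32, 8), "n_basis")
  expect_error(render_image(tg, rep(0, 5)), "latent length")
  expect_error(render_image(tg, c(NA, rep(0, tg$latent_dim - 1))), "finite")
})

test_that("texture generator: moving mass between coefficients relocates image energy", {
  tg <- h_tex32()
  # pick two elements with well separated centers
  el <- tg$elements
  dmat <- as.matrix(dist(el[, c("cx", "cy")]))
  pick <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  i <- pick[1]; j <- pick[2]
  patch_energy <- function(img, cx, cy, rad = 6) {
    rows <- pmax(1, round(cy - rad)):pmin(32, round(cy + rad))
    cols <- pmax(1, round(cx - rad)):pmin(32, round(cx + rad))
    sum((img[rows, cols, ] - 0.5)^2)
  }
  z <- rep(0, tg$latent_dim)
  z[i] <- 2
  img_i <- render_image(tg, z)
  z2 <- rep(0, tg$latent_dim)
  z2[j] <- 2
  img_j <- render_image(tg, z2)
  # energy near locus i drops and energy near locus j rises when mass moves
  expect_gt(patch_energy(img_i, el$cx[i], el$cy[i]),
            patch_energy(img_j, el$cx[i], el$cy[i]))
  expect_gt(patch_energy(img_j, el$cx[j], el$cy[j]),
            patch_energy(img_i, el$cx[j], el$cy[j]))
})

test_that("object generator: class/noise factorization and centering convention", {
  og <- h_obj32()
  expect_named(og$partition, c("class", "noise"))
  zc <- with_seed(5, rnorm(6))
  id_fields <- c("shape_exp", "aspect", "hue", "part_angle", "part_dist",
                 "part_size", "sat", "bg_phase", "part_hue")
  p1 <- og$param_map(c(zc, with_seed(6, rnorm(6))))
  p2 <- og$param_map(c(zc, with_seed(7, rnorm(6))))
  for (f in id_fields) expect_identical(p1[[f]], p2[[f]])
  expect_false(isTRUE(all.equal(p1$x_off, p2$x_off)) &&
                 isTRUE(all.equal(p1$y_off, p2$y_off)))
  p0 <- og$param_map(c(zc, rep(0, 6)))
  expect_identical(c(p0$x_off, p0$y_off), c(0, 0))
  expect_error(make_object_generator(32, 32, 1, 6), "class_dim")
})

test_that("object generator: class interpolation morphs shape parameters monotonically", {
  og <- h_obj32()
  za <- with_seed(21, rnorm(6))
  zb <- with_seed(22, rnorm(6))
  ts <- seq(0, 1, length.out = 9)
  vals <- sapply(ts, function(t) {
    p <- og$param_map(c((1 - t) * za + t * zb, rep(0, 6)))
    c(p$shape_exp, p$hue, p$part_dist)
  })
  # each identity parameter is a monotone squash of a linear functional of
  # the class vector, so it must be monotone along the interpolation path
  for (r in 1:3) {
    dif <- diff(vals[r, ])
    expect_true(all(dif >= -1e-12) || all(dif <= 1e-12))
  }
})

test_that("generator determinism and continuity probes pass for both bundled generators", {
  for (gen in list(h_tex32(), h_obj32())) {
    pr <- probe_generator(gen, n = 100, eps = 1e-3, seed = 42)
    expect_identical(pr$max_determinism_gap, 0)
    expect_lt(pr$max_lipschitz, 100) # finite empirical Lipschitz constant
  }
})

test_that("simulate_response: peak at template, baseline far away, Gaussian scaling", {
  tg <- h_tex32()
  z <- with_seed(3, rnorm(24))
  img <- render_image(tg, z)
  tmpl <- img[9:24, 9:24, , drop = FALSE]
  nm <- neuron_model(tmpl, locus = c(9, 9), tuning_width = 0.05,
                     baseline_rate = 4, peak_rate = 120,
                     image_size = c(32, 32))
  pr <- simulate_response(nm, img)
  expect_equal(max(pr$rate), 120)
  expect_true(all(pr$rate >= 0))
  expect_true(all(pr$rate[pr$time < 0] == 4))
  # an image far from the preference in patch space stays near baseline
  far <- array(0, dim = dim(img)) # all-black: patch RMS distance ~0.5 >> width
  prf <- simulate_response(nm, far)
  expect_lt(max(prf$rate) - 4, 1e-6)
  # evoked component scales by the analytic Gaussian tuning factor
  delta <- 0.04
  pert <- img
  pert[9:24, 9:24, ] <- pmin(pmax(tmpl + delta, 0), 1)
  achieved <- sqrt(mean((pert[9:24, 9:24, , drop = FALSE] - tmpl)^2))
  prp <- simulate_response(nm, pert)
  expect_equal((prp$rate - 4)[prp$time >= 0],
               (pr$rate - 4)[pr$time >= 0] * exp(-achieved^2 / (2 * 0.05^2)),
               tolerance = 1e-10)
  expect_error(simulate_response(nm, array(0.5, c(16, 16, 3))), "size")
})

test_that("simulate_spikes: zero-rate silence, determinism, Poisson count statistics", {
  nm0 <- h_null_neuron(baseline = 0)
  img <- array(0.5, c(32, 32, 3))
  recs <- simulate_spikes(nm0, img, n_trials = 20, seed = 1)
  expect_true(all(vapply(recs, function(r) length(r$spike_times), 0L) == 0))
  nm <- h_null_neuron(baseline = 40)
  r1 <- simulate_spikes(nm, img, n_trials = 5, seed = 9)
  r2 <- simulate_spikes(nm, img, n_trials = 5, seed = 9)
  expect_identical(r1, r2)
  # constant rate r over the 450 ms window: mean count ~ r * T / 1000
  big <- simulate_spikes(nm, img, n_trials = 10000, seed = 10)
  counts <- vapply(big, function(r) length(r$spike_times), 0L)
  expected <- 40 * 450 / 1000
  se <- sqrt(expected / 10000)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # within-window ordering and bounds invariants
  expect_true(all(vapply(big, function(r) {
    !is.unsorted(r$spike_times) && all(r$spike_times >= -50) &&
      all(r$spike_times < 400)
  }, logical(1))))
})

test_that("spike simulation is measure-preserving against the rate integral", {
  tg <- h_tex32()
  z <- with_seed(8, rnorm(24))
  img <- render_image(tg, z)
  tmpl <- img[5:20, 5:20, , drop = FALSE]
  nm <- neuron_model(tmpl, locus = c(5, 5), tuning_width = 0.1,
                     baseline_rate = 6, peak_rate = 90, image_size = c(32, 32))
  for (probe in list(img, render_image(tg, -z))) {
    lam <- simulate_response(nm, probe)
    expected <- sum(lam$rate) / 1000
    recs <- simulate_spikes(nm, probe, n_trials = 4000, seed = 77)
    mc <- mean(vapply(recs, function(r) length(r$spike_times), 0L))
    expect_lt(abs(mc - expected), 3 * sqrt(expected / 4000))
  }
})

test_that("attainable rates respect each generator's prior (grid search)", {
  tg <- h_tex32()
  og <- h_obj32()
  # texture-matched neuron: preference realizable by the dictionary
  zt <- with_seed(12, rnorm(24)) * 1.2
  tex_img <- render_image(tg, zt)
  n_tex <- neuron_model(tex_img[9:24, 9:24, , drop = FALSE], locus = c(9, 9),
                        tuning_width = 0.08, baseline_rate = 0,
                        peak_rate = 100, image_size = c(32, 32))
  # object-part neuron: preference taken from an object-scene patch
  zo <- og$sample_prior(1, 13)[1, ]
  obj_img <- render_image(og, zo)
  n_obj <- neuron_model(obj_img[9:24, 9:24, , drop = FALSE], locus = c(9, 9),
                        tuning_width = 0.08, baseline_rate = 0,
                        peak_rate = 100, image_size = c(32, 32))
  max_rate <- function(neuron, gen, Z) {
    best <- 0
    for (i in seq_len(nrow(Z))) {
      best <- max(best, max(simulate_response(neuron,
                                              render_image(gen, Z[i, ]))$rate))
    }
    best
  }
  Zt <- tg$sample_prior(10000, 14, scale = 1.2)
  Zo <- og$sample_prior(4000, 15)
  tex_under_tex <- max_rate(n_tex, tg, Zt)
  tex_under_obj <- max_rate(n_tex, og, Zo)
  obj_under_obj <- max_rate(n_obj, og, Zo)
  obj_under_tex <- max_rate(n_obj, tg, Zt)
  expect_gt(tex_under_tex, tex_under_obj)
  expect_gt(obj_under_obj, obj_under_tex)
})

test_that("spike records flatten to the CSV schema", {
  nm <- h_null_neuron(baseline = 30)
  recs <- simulate_spikes(nm, array(0.5, c(32, 32, 3)), n_trials = 3,
                          seed = 2, image_id = "x1", block_id = 4L)
  df <- spikes_to_df(recs)
  expect_named(df, c("image_id", "block_id", "trial_id", "spike_time_ms"))
  expect_true(all(df$image_id == "x1"))
  expect_true(all(df$block_id == 4L))
  expect_identical(spikes_to_df(list())$spike_time_ms, numeric(0))
})
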