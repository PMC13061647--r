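ex16 <- function() fixture("bank16", function() feature_bank(seed = 4))

test_that("feature extraction: contract shape, constancy, translation equivariance", {
  ex <- ex16()
  imgs <- list(array(0.5, c(64, 64, 3)), array(0.31, c(64, 64, 3)))
  fe <- extract_local_features(imgs, ex)
  expect_identical(dim(fe), c(2L, 13L, 13L, 16L))
  # constant images give spatially constant feature maps
  for (n in 1:2) {
    for (ch in 1:16) {
      expect_lt(diff(range(fe[n, , , ch])), 1e-12)
    }
  }
  # translating a pattern by one grid stride moves its response one cell
  patt <- with_seed(7, array(runif(16 * 16 * 3), c(16, 16, 3)))
  base <- array(0.5, c(64, 64, 3))
  imA <- base
  imA[17:32, 17:32, ] <- patt
  imB <- base
  imB[17:32, 21:36, ] <- patt # shifted one stride (4 px) in x
  fA <- extract_local_features(list(imA), ex)
  fB <- extract_local_features(list(imB), ex)
  expect_equal(fA[1, 5, 5, ], fB[1, 5, 6, ], tolerance = 1e-12)
  expect_error(extract_local_features(list(base, array(0.5, c(32, 32, 3))), ex),
               "share one size")
})

test_that("spatial attribution mask: perfect fit, noise floor, invariances", {
  ex <- ex16()
  tg <- h_tex64r()
  Z <- tg$sample_prior(200, 31)
  imgs <- lapply(seq_len(nrow(Z)), function(i) render_image(tg, Z[i, ]))
  fe <- extract_local_features(imgs, ex)
  w_true <- with_seed(32, rnorm(16))
  target <- as.numeric(matrix(fe[, 7, 7, ], nrow = 200) %*% w_true)
  # noiseless linear readout of cell (7,7): adjusted R2 = 1 there
  mask <- spatial_attribution_mask(fe, target)
  expect_equal(mask$r2[7, 7], 1, tolerance = 1e-9)
  expect_identical(which(mask$r2 == max(mask$r2), arr.ind = TRUE)[1, ],
                   c(row = 7L, col = 7L))
  # responses independent of the images: mean adjusted R2 ~ 0
  noise_resp <- with_seed(33, rnorm(200))
  mask0 <- spatial_attribution_mask(fe, noise_resp)
  expect_lt(abs(mean(mask0$r2)), 0.05)
  # duplicated data leave the mask unchanged
  fe2 <- array(NA_real_, dim = c(400, 13, 13, 16))
  fe2[1:200, , , ] <- fe
  fe2[201:400, , , ] <- fe
  mask_dup <- spatial_attribution_mask(fe2, c(target, target))
  expect_equal(which.max(mask_dup$r2), which.max(mask$r2))
  expect_equal(mask_dup$weights[7, 7, ] / mask$weights[7, 7, ],
               rep(1, 16), tolerance = 1e-6)
  # constant responses: flagged, R2 = 0
  maskc <- spatial_attribution_mask(fe, rep(3, 200))
  expect_true(all(maskc$r2 == 0))
  expect_match(maskc$flagged[1], "constant")
  # under-determined fit: ridge fallback flag
  masku <- spatial_attribution_mask(fe[1:10, , , , drop = FALSE], target[1:10])
  expect_match(masku$flagged[1], "ridge")
})

test_that("mask weight vector: threshold, largest region, row-major tie-break", {
  mk_mask <- function(r2, W) {
    structure(list(r2 = r2, weights = W, n = 100, flagged = character()),
              class = "attribution_mask")
  }
  W <- array(0, c(5, 5, 3))
  for (i in 1:5) for (j in 1:5) W[i, j, ] <- c(i, j, i + j)
  # single cell above threshold
  r2 <- matrix(0, 5, 5)
  r2[2, 3] <- 0.9
  expect_equal(mask_weight_vector(mk_mask(r2, W)), W[2, 3, ])
  # two regions of sizes 5 and 3: average over the 5-cell region
  # (threshold percentile 0.5 puts both regions above threshold)
  r2b <- matrix(0, 5, 5)
  big <- rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(3, 1))
  small <- rbind(c(5, 4), c(5, 5), c(4, 5))
  for (k in 1:5) r2b[big[k, 1], big[k, 2]] <- 0.8
  for (k in 1:3) r2b[small[k, 1], small[k, 2]] <- 0.85
  expected <- colMeans(t(vapply(1:5, function(k) W[big[k, 1], big[k, 2], ],
                                numeric(3))))
  expect_equal(mask_weight_vector(mk_mask(r2b, W), percentile = 0.5), expected)
  # size tie: region containing the first cell in row-major order wins
  r2c <- matrix(0, 5, 5)
  r2c[1, 4] <- r2c[1, 5] <- 0.9 # region A, first row-major cell (1,4)
  r2c[4, 1] <- r2c[5, 1] <- 0.9 # region B
  expect_equal(mask_weight_vector(mk_mask(r2c, W), percentile = 0.5),
               (W[1, 4, ] + W[1, 5, ]) / 2)
  # everything at or below the threshold is an error
  expect_error(mask_weight_vector(mk_mask(matrix(0.3, 5, 5), W)), "threshold")
})

test_that("mask correlations behave and separate shared-locus drivers", {
  expect_equal(mask_correlation(1:8, 1:8), 1)
  expect_equal(mask_correlation(1:8, -(1:8)), -1)
  expect_equal(mask_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_warning(r <- mask_correlation(rep(2, 5), 1:5), "zero variance")
  expect_true(is.na(r))
  # drivers sharing a locus yield higher same-pair than cross-pair r
  ex <- ex16()
  tg <- h_tex64r()
  Z <- tg$sample_prior(120, 41)
  imgs <- lapply(seq_len(nrow(Z)), function(i) render_image(tg, Z[i, ]))
  fe <- extract_local_features(imgs, ex)
  wvec <- function(w_true, cell, noise_sd, seed) {
    resp <- as.numeric(matrix(fe[, cell[1], cell[2], ], nrow = 120) %*%
                         w_true) +
      with_seed(seed, rnorm(120, sd = noise_sd))
    mask_weight_vector(spatial_attribution_mask(fe, resp))
  }
  set.seed(42)
  same <- cross <- numeric(0)
  for (drv in 1:12) {
    w_true <- rnorm(16)
    cell <- c(sample(3:11, 1), sample(3:11, 1))
    wa <- wvec(w_true, cell, 0.3, 1000 + drv)
    wb <- wvec(w_true, cell, 0.3, 2000 + drv)
    w_other <- wvec(rnorm(16), c(sample(3:11, 1), sample(3:11, 1)), 0.3,
                    3000 + drv)
    same <- c(same, mask_correlation(wa, wb))
    cross <- c(cross, mask_correlation(wa, w_other))
  }
  expect_lt(mask_correlation_test(same, cross)$p, 0.05)
})

test_that("total variation closed forms", {
  expect_equal(total_variation(matrix(5, 7, 9)), 0)
  # unit step across one column boundary in an n-row map
  stepm <- cbind(matrix(0, 6, 3), matrix(1, 6, 4))
  expect_equal(total_variation(stepm), 6)
  rnd <- with_seed(5, matrix(rnorm(48), 6))
  expect_equal(total_variation(3.5 * rnd), 3.5 * total_variation(rnd),
               tolerance = 1e-12)
})

test_that("perceptual similarity maps: identity, symmetry, localization", {
  ex <- ex16()
  tg <- h_tex64()
  imgs <- lapply(1:2, function(i)
    render_image(tg, tg$sample_prior(2, 51)[i, ]))
  self <- perceptual_similarity_map(imgs[[1]], imgs[[1]], ex)
  expect_true(all(abs(self$map - 1) < 1e-12))
  ab <- perceptual_similarity_map(imgs[[1]], imgs[[2]], ex)
  ba <- perceptual_similarity_map(imgs[[2]], imgs[[1]], ex)
  expect_equal(ab$map, ba$map, tolerance = 1e-12)
  expect_lte(max(ab$map), 1)
  # images sharing one quadrant over independent noise: top-decile
  # similarity concentrates there
  hits <- 0
  for (s in 1:5) {
    set.seed(60 + s)
    a <- array(runif(64 * 64 * 3), c(64, 64, 3))
    b <- array(runif(64 * 64 * 3), c(64, 64, 3))
    b[1:32, 1:32, ] <- a[1:32, 1:32, ] # shared quadrant
    m <- perceptual_similarity_map(a, b, ex)$map
    thr <- quantile(m, 0.9)
    top <- which(m >= thr, arr.ind = TRUE)
    # quadrant rows/cols in grid units: patches fully inside rows 1:5
    frac <- mean(top[, 1] <= 5 & top[, 2] <= 5)
    if (frac >= 0.7) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("concentration score: closed forms, translation invariance, errors", {
  expect_equal(concentration_score(matrix(0.42, 13, 13)), 0.42)
  m0 <- matrix(0, 13, 13)
  m0[5, 5] <- 1
  expect_equal(concentration_score(m0, c(1, 2)), mean(c(1, 1 / 4)))
  for (k in c(1, 2, 3, 5, 8)) {
    expect_equal(concentration_score(m0, k), 1 / k^2)
  }
  m1 <- matrix(0, 13, 13)
  m1[9, 9] <- 1 # translated delta away from borders
  expect_equal(concentration_score(m1), concentration_score(m0))
  expect_error(concentration_score(m0, 14), "exceeds")
})

test_that("feature exemplar recovers a planted readout from a diverse ensemble", {
  # white-noise stimuli keep the feature design well conditioned; a
  # generator-prior ensemble only identifies the readout up to its
  # stimulus subspace (see the methods vignette)
  ex <- feature_bank(patch = 8, stride = 8, channels = 16, seed = 4,
                     rectify = "none")
  set.seed(70)
  imgs <- lapply(1:500, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  fe <- extract_local_features(imgs, ex)
  gh <- dim(fe)[2]
  s_true <- matrix(0, gh, gh)
  s_true[4:5, 4:5] <- c(1, 2, 2, 4)
  w_true <- with_seed(72, rnorm(16))
  signal <- vapply(seq_len(500), function(i)
    sum((matrix(fe[i, , , ], nrow = gh * gh) %*% w_true) *
          as.numeric(s_true)), numeric(1))
  resp <- signal + with_seed(73, rnorm(500, sd = 0.1 * sd(signal)))
  fx <- feature_exemplar(imgs, resp, ex, h_tex64(), seed = 3,
                         generations = 8)
  planted <- as.numeric(s_true) %o% w_true
  fitted <- as.numeric(fx$model$spatial) %o% fx$model$channel
  expect_gte(abs(cor(as.numeric(planted), as.numeric(fitted))), 0.9)
  # degenerate screen: responses unrelated to any feature
  expect_error(feature_exemplar(imgs[1:60], rep(0, 60) + 1e-8 * (1:60), ex,
                                h_tex64(), screen_min = 0.9),
               "degenerate")
})

test_that("feature exemplar maximizes its own encoding model deterministically", {
  ex <- ex16()
  tg <- h_tex64()
  Z <- tg$sample_prior(120, 71)
  imgs <- lapply(seq_len(nrow(Z)), function(i) render_image(tg, Z[i, ]))
  fe <- extract_local_features(imgs, ex)
  w_true <- with_seed(72, rnorm(16))
  resp <- as.numeric(matrix(fe[, 7, 7, ], nrow = 120) %*% w_true) +
    with_seed(73, rnorm(120, sd = 0.5))
  fx <- feature_exemplar(imgs, resp, ex, tg, seed = 3, init_latents = Z,
                         generations = 15)
  expect_gte(fx$predicted, fx$train_max)
  fx2 <- feature_exemplar(imgs, resp, ex, tg, seed = 3, init_latents = Z,
                          generations = 15)
  expect_identical(fx$image, fx2$image)
})
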