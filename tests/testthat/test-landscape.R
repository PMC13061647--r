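test_that("pullback Hessian matches the analytic linear-generator form", {
  for (s in 1:5) {
    lg <- h_linear_gen(d = 5, npx = 6, seed = s)
    pm <- pullback_hessian(lg, pixel_sq_distance, rep(0, 5), h = 1e-3,
                           check = FALSE)
    H_true <- 2 * crossprod(lg$A)
    expect_lt(max(abs(pm$H - H_true)) / max(abs(H_true)), 1e-6)
    expect_identical(pm$H, (pm$H + t(pm$H)) / 2)
    # eigenvalues equal 2 * singular values squared (independent SVD oracle)
    ev <- eigen(pm$H, symmetric = TRUE, only.values = TRUE)$values
    sv <- svd(lg$A, nu = 0, nv = 0)$d
    expect_equal(sort(ev), sort(2 * sv^2), tolerance = 1e-5)
  }
})

test_that("pullback Hessian reports the offending coordinate pair on failure", {
  bad_metric <- function(a, b) {
    v <- sum((a - b)^2)
    if (v > 0) NaN else 0
  }
  lg <- h_linear_gen(d = 3, npx = 4, seed = 1)
  expect_error(pullback_hessian(lg, bad_metric, rep(0, 3), h = 1e-3,
                                check = FALSE),
               "coordinate pair \\(1, 1\\)")
})

test_that("subspace eigendecomposition: block structure, orthonormality, optimality", {
  set.seed(6)
  Q1 <- qr.Q(qr(matrix(rnorm(16), 4)))
  Q2 <- qr.Q(qr(matrix(rnorm(36), 6)))
  H <- matrix(0, 10, 10)
  H[1:4, 1:4] <- Q1 %*% diag(c(5, 3, 2, 1)) %*% t(Q1)
  H[5:10, 5:10] <- Q2 %*% diag(6:1) %*% t(Q2)
  part <- list(class = 1:4, noise = 5:10)
  axes <- subspace_eigendecomposition(H, part)
  expect_length(axes, 10)
  # block-diagonal H: subspace eigenvalues equal full-matrix eigenvalues
  full_ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  sub_ev <- sort(vapply(axes, `[[`, numeric(1), "lambda"))
  expect_equal(sub_ev, full_ev, tolerance = 1e-10)
  for (nm in names(part)) {
    V <- vapply(Filter(function(a) a$subspace == nm, axes), `[[`,
                numeric(10), "v")
    expect_lt(max(abs(crossprod(V) - diag(length(part[[nm]])))), 1e-10)
    # zeros outside the block
    expect_equal(sum(abs(V[-part[[nm]], ])), 0)
  }
  # top class axis maximizes v' H v over random unit vectors in its subspace
  top <- axes[[1]]
  rand_q <- with_seed(8, {
    U <- matrix(rnorm(4 * 1000), nrow = 4)
    U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
    max(colSums(U * (H[1:4, 1:4] %*% U)))
  })
  expect_gte(top$lambda + 1e-12, rand_q)
})

test_that("line search achieves targets; closed form holds for linear generators", {
  lg <- h_linear_gen(d = 5, npx = 6, seed = 3)
  v <- with_seed(4, rnorm(5))
  v <- v / sqrt(sum(v^2))
  al <- line_search_alpha(lg, pixel_l2_distance, rep(0, 5), v, 0.3,
                          direction = 1, tol = 1e-6)
  expect_equal(al, 0.3 / sqrt(sum((lg$A %*% v)^2)), tolerance = 1e-4)
  al_neg <- line_search_alpha(lg, pixel_l2_distance, rep(0, 5), v, 0.3,
                              direction = -1, tol = 1e-6)
  expect_lt(al_neg, 0)
  expect_equal(abs(al_neg), al, tolerance = 1e-4)
  # unreachable target errors; non-monotone metric errors with diagnostic
  bounded <- function(a, b) min(sum((a - b)^2), 0.01)
  expect_error(line_search_alpha(lg, bounded, rep(0, 5), v, 5, max_alpha = 10),
               "unreachable")
  wiggly <- function(a, b) {
    d2 <- sum((a - b)^2)
    d2 * (1 + 0.9 * sin(40 * sqrt(d2)))
  }
  expect_error(
    suppressWarnings(line_search_alpha(lg, wiggly, rep(0, 5), v, 0.5)),
    "monotone")
})

test_that("build_axis_stimuli: nine matched stimuli per axis, exact center", {
  og <- h_obj64()
  z0 <- og$sample_prior(1, 5)[1, ]
  pm <- pullback_hessian(og, pixel_sq_distance, z0, h = 1e-3, check = FALSE)
  axes <- subspace_eigendecomposition(pm, og$partition)
  stim <- build_axis_stimuli(og, z0, axes[c(1, 9)])
  expect_length(stim, 2)
  center <- render_image(og, z0)
  for (st in stim) {
    expect_length(st$images, 9)
    expect_identical(st$images[[5]], center)
    expect_true(all(abs(abs(st$achieved) - abs(st$distances)) <= 1e-3))
    expect_identical(sign(st$achieved[-5]), sign(st$distances[-5]))
  }
})

test_that("measure_and_analyze recovers bell and ramp shapes and degenerate cases", {
  og <- h_obj64()
  z0 <- og$sample_prior(1, 5)[1, ]
  pm <- pullback_hessian(og, pixel_sq_distance, z0, h = 1e-3, check = FALSE)
  axes <- subspace_eigendecomposition(pm, og$partition)
  st <- build_axis_stimuli(og, z0, axes[1])[[1]]
  rms04 <- 0.40 / sqrt(64 * 64 * 3)
  bell_neuron <- neuron_model(render_image(og, z0), locus = c(1, 1),
                              tuning_width = rms04 / 2.2, baseline_rate = 2,
                              peak_rate = 200, image_size = c(64, 64))
  tb <- measure_and_analyze(bell_neuron, st, reps = 6, seed = 2)
  expect_identical(tb$label, "bell")
  expect_identical(tb$d_max, 0)
  expect_lt(tb$p, 0.01)
  ramp_neuron <- neuron_model(st$images[[1]], locus = c(1, 1),
                              tuning_width = rms04 / 1.2, baseline_rate = 2,
                              peak_rate = 200, image_size = c(64, 64))
  tr <- measure_and_analyze(ramp_neuron, st, reps = 6, seed = 2)
  expect_identical(tr$label, "ramp")
  # zero-variance responses: nonsignificant, fits skipped
  silent <- h_null_neuron(image_size = c(64L, 64L), baseline = 0)
  ts <- measure_and_analyze(silent, st, reps = 5, seed = 3)
  expect_identical(ts$label, "nonsignificant")
  expect_null(ts$fits)
})

test_that("larger-eigenvalue axes produce larger image change at matched step", {
  og <- h_obj64()
  z0 <- og$sample_prior(1, 9)[1, ]
  pm <- pullback_hessian(og, pixel_sq_distance, z0, h = 1e-3, check = FALSE)
  axes <- subspace_eigendecomposition(pm, og$partition)
  class_axes <- Filter(function(a) a$subspace == "class", axes)[1:5]
  base <- render_image(og, z0)
  changes <- vapply(class_axes, function(a) {
    pixel_l2_distance(base, render_image(og, z0 + 0.005 * a$v))
  }, numeric(1))
  lambdas <- vapply(class_axes, `[[`, numeric(1), "lambda")
  expect_gt(cor(rank(lambdas), rank(changes)), 0.8)
})

test_that("two-proportion z matches the pooled formula and reproduces printed statistics", {
  # printed count tables: bell 178/342 vs 26/103, ramp 41/342 vs 37/103
  expect_equal(round(two_proportion_z(178, 342, 26, 103)$z, 2), 4.79)
  expect_equal(round(two_proportion_z(41, 342, 37, 103)$z, 2), -5.60)
  set.seed(10)
  for (i in 1:100) {
    n1 <- sample(20:400, 1)
    n2 <- sample(20:400, 1)
    x1 <- rbinom(1, n1, runif(1, 0.05, 0.95))
    x2 <- rbinom(1, n2, runif(1, 0.05, 0.95))
    # hand-coded pooled-variance formula
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    z_hand <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(two_proportion_z(x1, n1, x2, n2)$z, z_hand,
                 tolerance = 1e-12)
  }
})

test_that("summarize_population aggregates fractions, intervals and contrasts", {
  mk_curve <- function(label, d_max = 0) {
    structure(list(label = label, d_max = d_max,
                   distances = c(0.40, 0.32, 0.24, 0.16, 0, -0.16, -0.24,
                                 -0.36, -0.40)),
              class = "tuning_curve")
  }
  curves <- c(lapply(1:8, function(i) mk_curve("bell")),
              lapply(1:2, function(i) mk_curve("ramp", 0.4)),
              lapply(1:3, function(i) mk_curve("ramp", -0.4)),
              lapply(1:3, function(i) mk_curve("other", 0.16)),
              lapply(1:2, function(i) mk_curve("nonsignificant")))
  success <- c(rep(TRUE, 10), rep(FALSE, 8))
  ps <- summarize_population(curves, success)
  expect_equal(ps$groups$successful$n, 10)
  expect_equal(ps$groups$unsuccessful$n, 6)
  expect_equal(unname(ps$groups$successful$bell_frac["estimate"]), 0.8)
  expect_true(ps$groups$successful$bell_frac["lower"] <= 0.8,
              ps$groups$successful$bell_frac["upper"] >= 0.8)
  expect_equal(sum(ps$groups$successful$peak_hist$count), 10)
  # all-bell group edge case
  all_bell <- lapply(1:4, function(i) mk_curve("bell"))
  ps2 <- summarize_population(c(all_bell, list(mk_curve("bell"))),
                              c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(ps2$groups$successful$bell_frac["estimate"]), 1)
  expect_equal(unname(ps2$groups$successful$ramp_frac["estimate"]), 0)
  expect_error(summarize_population(all_bell, rep(TRUE, 4)), "group")
})

test_that("wilson and beta intervals behave like proportion intervals", {
  w <- wilson_ci(8, 10)
  b <- beta_ci(8, 10)
  for (ci in list(w, b)) {
    expect_true(ci["lower"] < ci["estimate"], ci["upper"] > ci["estimate"])
    expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
  }
  # degenerate extremes stay in [0, 1]
  expect_gte(wilson_ci(0, 20)["lower"], 0)
  expect_lte(wilson_ci(20, 20)["upper"], 1)
})
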