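#' @title Generator contracts
#'
#' @description A generator is a deterministic, continuous map from a latent
#' vector to an RGB image in `[0, 1]`. The package bundles two generators
#' with deliberately contrasting priors:
#'
#' * a *texture* generator — a linear map over a seeded dictionary of
#'   localized, oriented band-pass (Gabor-like) elements plus a mid-gray
#'   offset. Flexible and analytically invertible on its span; its images
#'   are texture-like patterns with no object prior.
#' * an *object* generator — a low-dimensional smooth parametric scene
#'   (background gradient plus one coherent superellipse blob with internal
#'   parts). Its latent space is partitioned into a "class" sub-block
#'   controlling identity features (shape exponents, part layout, hue) and a
#'   "noise" sub-block controlling pose, scale, and position.
#'
#' Both are plain R objects of class `"generator"` with fields `name`,
#' `latent_dim`, `partition` (named list of index vectors or `NULL`),
#' `height`, `width`, and a `render` closure. Any object honouring this
#' contract can be plugged into the evolution engine and the tuning-landscape
#' machinery.
#'
#' @name generators
NULL

new_generator <- function(name, latent_dim, height, width, render,
                          partition = NULL, extra = list()) {
  g <- c(list(name = name, latent_dim = as.integer(latent_dim),
              height = as.integer(height), width = as.integer(width),
              partition = partition, render = render), extra)
  class(g) <- "generator"
  g
}

#' @export
print.generator <- function(x, ...) {
  cat(sprintf("<generator '%s'>  latent_dim=%d  image=%dx%dx3\n",
              x$name, x$latent_dim, x$height, x$width))
  if (!is.null(x$partition)) {
    for (nm in names(x$partition)) {
      cat(sprintf("  partition$%s: %d dims\n", nm, length(x$partition[[nm]])))
    }
  }
  invisible(x)
}

#' Render a latent vector to an image
#'
#' @param gen a `generator`.
#' @param z numeric latent vector of length `gen$latent_dim`; all finite.
#' @return `height x width x 3` numeric array with values in `[0, 1]`.
#' @export
render_image <- function(gen, z) {
  stopifnot(inherits(gen, "generator"))
  if (length(z) != gen$latent_dim) {
    stop(sprintf("latent length %d != latent_dim %d", length(z), gen$latent_dim))
  }
  if (!all(is.finite(z))) stop("latent vector contains non-finite values")
  gen$render(as.numeric(z))
}

#' Construct the texture-prior generator
#'
#' Builds a linear dictionary of `n_basis` localized oriented band-pass
#' elements (Gabor patches with random center, orientation, spatial frequency
#' and RGB color direction), each normalized to unit L2 norm. Rendering is
#' `0.5 + B %*% z`, clipped to `[0, 1]`. The pre-clipping map is exposed as
#' `gen$render_preclip` (the dictionary is exactly linear there), and the
#' dictionary matrix as `gen$basis`.
#'
#' Element centers are stratified over the image so that arbitrary local
#' patterns can be placed anywhere; element metadata (centers, orientations,
#' wavelengths) is stored in `gen$elements`.
#'
#' @param height,width image size in pixels (default 64).
#' @param n_basis dictionary size (>= 16; default 256).
#' @param seed integer seed fixing the dictionary.
#' @return A `generator` with `latent_dim = n_basis`.
#' @export
make_texture_generator <- function(height = 64, width = 64, n_basis = 256,
                                   seed = 1L) {
  if (height <= 0 || width <= 0) stop("image dimensions must be positive")
  if (n_basis < 16) stop("n_basis must be >= 16")
  npix <- height * width
  # stratified centers: lay elements on a jittered grid covering the image
  ngrid <- ceiling(sqrt(n_basis))
  basis <- matrix(0, nrow = npix * 3, ncol = n_basis)
  elements <- data.frame(cx = numeric(n_basis), cy = numeric(n_basis),
                         theta = numeric(n_basis), lambda = numeric(n_basis),
                         sigma = numeric(n_basis))
  xs <- matrix(rep(seq_len(width), each = height), nrow = height)
  ys <- matrix(rep(seq_len(height), times = width), nrow = height)
  with_seed(seed, {
    ord <- sample.int(ngrid * ngrid)[seq_len(n_basis)]
    for (k in seq_len(n_basis)) {
      gi <- (ord[k] - 1) %% ngrid
      gj <- (ord[k] - 1) %/% ngrid
      cx <- (gj + stats::runif(1)) / ngrid * width
      cy <- (gi + stats::runif(1)) / ngrid * height
      theta <- stats::runif(1, 0, pi)
      lambda <- stats::runif(1, 4, max(8, height / 3))
      sigma <- lambda * stats::runif(1, 0.35, 0.6)
      xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
      env <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
      carrier <- cos(2 * pi * xr / lambda + stats::runif(1, 0, 2 * pi))
      patch <- env * carrier
      col <- stats::rnorm(3)
      col <- col / sqrt(sum(col^2))
      el <- c(patch * col[1], patch * col[2], patch * col[3])
      basis[, k] <- el / sqrt(sum(el^2))
      elements[k, ] <- list(cx, cy, theta, lambda, sigma)
    }
  })
  render_preclip <- function(z) {
    v <- 0.5 + as.numeric(basis %*% z)
    array(v, dim = c(height, width, 3))
  }
  render <- function(z) {
    img <- render_preclip(z)
    img[] <- clip01(img)
    img
  }
  new_generator(
    name = "texture", latent_dim = n_basis, height = height, width = width,
    render = render,
    extra = list(basis = basis, elements = elements,
                 render_preclip = render_preclip,
                 recipe = list(fun = "make_texture_generator",
                               args = list(height = height, width = width,
                                           n_basis = n_basis, seed = seed)),
                 sample_prior = function(n, seed, scale = 1) {
                   with_seed(seed, matrix(stats::rnorm(n * n_basis, sd = scale),
                                          nrow = n))
                 })
  )
}

# Smooth HSV-ish hue -> RGB helper used by the object scene (period-1 hue).
hue_rgb <- function(hue) {
  0.5 + 0.5 * cos(2 * pi * (hue + c(0, 1 / 3, 2 / 3)))
}

#' Construct the object-prior generator
#'
#' A smooth parametric scene with a constrained prior: a vertical background
#' gradient plus a single coherent blob object (superellipse body with two
#' internal parts). The latent space is partitioned into a `class` sub-block,
#' mapped through a fixed seeded linear map and smooth squashing functions to
#' identity parameters (shape exponent, aspect, hue, part layout), and a
#' `noise` sub-block mapped to pose parameters (position, scale, rotation).
#' Zero noise places the object at the image midpoint.
#'
#' The analytic latent-to-parameter map is exposed as `gen$param_map(z)`,
#' returning the named parameter list actually used by the renderer, so that
#' tests can verify identity/pose factorization and morphing directly.
#'
#' @param height,width image size in pixels (default 64).
#' @param class_dim,noise_dim sub-block sizes (>= 2; defaults 16 and 16).
#' @param seed integer seed fixing the parameter maps.
#' @return A `generator` with `latent_dim = class_dim + noise_dim` and a
#'   recorded `partition`.
#' @export
make_object_generator <- function(height = 64, width = 64, class_dim = 16,
                                  noise_dim = 16, seed = 1L) {
  if (height <= 0 || width <= 0) stop("image dimensions must be positive")
  if (class_dim < 2 || noise_dim < 2) stop("class_dim and noise_dim must be >= 2")
  d <- class_dim + noise_dim
  maps <- with_seed(seed, list(
    Wc = matrix(stats::rnorm(9 * class_dim, sd = 1 / sqrt(class_dim)),
                nrow = 9),
    Wn = matrix(stats::rnorm(4 * noise_dim, sd = 1 / sqrt(noise_dim)),
                nrow = 4)
  ))
  partition <- list(class = seq_len(class_dim),
                    noise = class_dim + seq_len(noise_dim))
  param_map <- function(z) {
    u <- as.numeric(maps$Wc %*% z[partition$class])
    v <- as.numeric(maps$Wn %*% z[partition$noise])
    list(
      # identity (class-controlled)
      shape_exp = 2 + 1.4 * tanh(u[1]),      # superellipse exponent
      aspect = exp(0.45 * tanh(u[2])),       # body aspect ratio
      hue = 0.5 + 0.5 * tanh(u[3]),          # body hue in [0, 1]
      part_angle = pi * tanh(u[4]),          # internal part layout angle
      part_dist = 0.45 + 0.25 * tanh(u[5]),  # part offset (body radii)
      part_size = 0.22 + 0.10 * tanh(u[6]),  # part radius (body radii)
      sat = 0.55 + 0.35 * tanh(u[7]),        # body color saturation
      bg_phase = tanh(u[8]),                 # background gradient phase
      part_hue = 0.5 + 0.5 * tanh(u[9]),     # part hue
      # pose (noise-controlled)
      x_off = 0.22 * tanh(v[1]),             # horizontal offset (image units)
      y_off = 0.22 * tanh(v[2]),
      scale = 0.24 * exp(0.45 * tanh(v[3])), # body radius (image units)
      rot = (pi / 2) * tanh(v[4])
    )
  }
  # coordinate grids in [-0.5, 0.5], x rightwards, y downwards
  xg <- matrix(rep((seq_len(width) - 0.5) / width - 0.5, each = height),
               nrow = height)
  yg <- matrix(rep((seq_len(height) - 0.5) / height - 0.5, times = width),
               nrow = height)
  render <- function(z) {
    p <- param_map(z)
    xr <- (xg - p$x_off) * cos(p$rot) + (yg - p$y_off) * sin(p$rot)
    yr <- -(xg - p$x_off) * sin(p$rot) + (yg - p$y_off) * cos(p$rot)
    a <- p$scale * p$aspect
    b <- p$scale / p$aspect
    s <- (abs(xr / a)^p$shape_exp + abs(yr / b)^p$shape_exp)^(1 / p$shape_exp)
    inside <- 1 / (1 + exp(-(1 - s) / 0.06)) # soft superellipse edge
    body_col <- p$sat * hue_rgb(p$hue) + (1 - p$sat) * 0.5
    part_col <- p$sat * hue_rgb(p$part_hue) + (1 - p$sat) * 0.5
    # two internal parts, symmetric about the body center, riding the body
    pw <- 0
    for (sgn in c(-1, 1)) {
      px <- sgn * p$part_dist * a * cos(p$part_angle)
      py <- sgn * p$part_dist * b * sin(p$part_angle)
      pw <- pw + exp(-((xr - px)^2 + (yr - py)^2) /
                       (2 * (p$part_size * p$scale)^2))
    }
    pw <- pmin(pw, 1) * inside
    # vertical background gradient between two muted colors
    t_bg <- yg + 0.5
    c_top <- 0.35 + 0.25 * hue_rgb(0.55 + 0.2 * p$bg_phase)
    c_bot <- 0.35 + 0.25 * hue_rgb(0.05 + 0.2 * p$bg_phase)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      bg <- c_top[ch] * (1 - t_bg) + c_bot[ch] * t_bg
      layer <- bg * (1 - inside) +
        inside * (body_col[ch] * (1 - pw) + part_col[ch] * pw)
      img[, , ch] <- layer
    }
    img[] <- clip01(img)
    img
  }
  new_generator(
    name = "object", latent_dim = d, height = height, width = width,
    render = render, partition = partition,
    extra = list(param_map = param_map,
                 recipe = list(fun = "make_object_generator",
                               args = list(height = height, width = width,
                                           class_dim = class_dim,
                                           noise_dim = noise_dim, seed = seed)),
                 sample_prior = function(n, seed, scale = 1) {
                   with_seed(seed, {
                     zc <- matrix(stats::rnorm(n * class_dim, sd = scale), nrow = n)
                     zn <- matrix(stats::rnorm(n * noise_dim, sd = 0.5 * scale),
                                  nrow = n)
                     cbind(zc, zn)
                   })
                 })
  )
}

#' Probe a generator's determinism and continuity
#'
#' Renders `n` random latent pairs `(z, z + delta)` with `||delta|| <= eps`
#' and reports the worst determinism discrepancy (same latent rendered twice)
#' and the empirical Lipschitz ratio `||image change|| / ||delta||`, both
#' pre-clip (if the generator exposes `render_preclip`) and post-clip.
#'
#' @param gen a `generator`.
#' @param n number of probe pairs (default 100).
#' @param eps perturbation norm (default 1e-3).
#' @param scale latent sampling scale.
#' @param seed integer seed.
#' @return List with `max_determinism_gap` and `max_lipschitz`.
#' @export
probe_generator <- function(gen, n = 100, eps = 1e-3, scale = 1, seed = 1L) {
  Z <- with_seed(seed, matrix(stats::rnorm(n * gen$latent_dim, sd = scale),
                              nrow = n))
  U <- with_seed(seed + 1L, matrix(stats::rnorm(n * gen$latent_dim), nrow = n))
  det_gap <- 0
  lip <- 0
  for (i in seq_len(n)) {
    z <- Z[i, ]
    dz <- U[i, ] / sqrt(sum(U[i, ]^2)) * eps
    a1 <- render_image(gen, z)
    a2 <- render_image(gen, z)
    b <- render_image(gen, z + dz)
    det_gap <- max(det_gap, max(abs(a1 - a2)))
    lip <- max(lip, sqrt(sum((b - a1)^2)) / eps)
  }
  list(max_determinism_gap = det_gap, max_lipschitz = lip)
}
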