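#' @title Spatial attribution and perceptual similarity
#'
#' @description Where in an image does a neuron's response come from?
#' Images are decomposed into a spatial grid of local patches, each patch is
#' embedded by a fixed seeded filter bank (a generic stand-in for a
#' pretrained convolutional layer; any extractor obeying the same contract
#' can be plugged in), and at every grid location a linear regression
#' predicts the neuron's responses from that location's feature channels.
#' The per-location adjusted R-squared forms the attribution mask; masks
#' are compared via weight-vector correlations, smoothness (total
#' variation), patchwise perceptual-similarity heatmaps and a concentration
#' score.
#'
#' @name attribution
NULL

#' Construct the default local feature extractor
#'
#' A fixed seeded bank of oriented band-pass filters with random RGB color
#' directions, applied to mean-centered local patches with absolute-value
#' rectification. With the defaults (16 px patches, stride 4) a 64 x 64
#' image yields a 13 x 13 feature grid.
#'
#' @param patch patch side length in pixels.
#' @param stride grid stride in pixels.
#' @param channels number of filters.
#' @param seed integer seed fixing the bank.
#' @param rectify nonlinearity applied to filter responses: `"abs"`
#'   (default; energy-like, phase-invariant) or `"none"` (signed linear
#'   responses; keeps channels identifiable for encoding models).
#' @return Object of class `feature_extractor` with fields `patch`,
#'   `stride`, `channels`, `filters` (a `patch*patch*3 x channels` matrix
#'   of unit-norm filters) and `name`.
#' @export
feature_bank <- function(patch = 16, stride = 4, channels = 16, seed = 1L,
                         rectify = c("abs", "none")) {
  rectify <- match.arg(rectify)
  stopifnot(patch >= 2, stride >= 1, channels >= 1)
  xs <- matrix(rep(seq_len(patch), each = patch), nrow = patch)
  ys <- matrix(rep(seq_len(patch), times = patch), nrow = patch)
  cx <- (patch + 1) / 2
  filters <- with_seed(seed, {
    vapply(seq_len(channels), function(k) {
      theta <- stats::runif(1, 0, pi)
      lambda <- stats::runif(1, 3, patch)
      phase <- stats::runif(1, 0, 2 * pi)
      xr <- (xs - cx) * cos(theta) + (ys - cx) * sin(theta)
      env <- exp(-((xs - cx)^2 + (ys - cx)^2) / (2 * (patch / 3)^2))
      g <- env * cos(2 * pi * xr / lambda + phase)
      g <- g - mean(g)
      col <- stats::rnorm(3)
      col <- col / sqrt(sum(col^2))
      v <- c(g * col[1], g * col[2], g * col[3])
      v / sqrt(sum(v^2))
    }, numeric(patch * patch * 3))
  })
  structure(list(patch = as.integer(patch), stride = as.integer(stride),
                 channels = as.integer(channels), filters = filters,
                 rectify = rectify,
                 name = sprintf("bank%d_p%d_s%d_%s", channels, patch, stride,
                                rectify)),
            class = "feature_extractor")
}

extractor_grid <- function(extractor, height, width) {
  list(rows = seq(1, height - extractor$patch + 1, by = extractor$stride),
       cols = seq(1, width - extractor$patch + 1, by = extractor$stride))
}

#' Extract a spatial grid of local features
#'
#' @param images list of image arrays (uniform size) or a single image.
#' @param extractor a `feature_extractor` (default [feature_bank()]
#'   defaults).
#' @return Array `(n_images, grid_h, grid_w, channels)` with receptive-field
#'   geometry attached as attributes `grid_rows`/`grid_cols` (patch top-left
#'   pixel coordinates).
#' @export
extract_local_features <- function(images, extractor = feature_bank()) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  dims <- dim(images[[1]])
  for (im in images) {
    if (!all(dim(im) == dims)) stop("images must share one size")
  }
  g <- extractor_grid(extractor, dims[1], dims[2])
  gh <- length(g$rows)
  gw <- length(g$cols)
  p <- extractor$patch
  ncell <- gh * gw
  out <- array(NA_real_, dim = c(length(images), gh, gw, extractor$channels))
  P <- matrix(0, nrow = ncell, ncol = p * p * 3)
  for (n in seq_along(images)) {
    im <- images[[n]]
    cell <- 0L
    for (j in seq_len(gw)) {
      for (i in seq_len(gh)) {
        cell <- cell + 1L
        pv <- as.numeric(im[g$rows[i]:(g$rows[i] + p - 1),
                            g$cols[j]:(g$cols[j] + p - 1), ])
        P[cell, ] <- pv - mean(pv)
      }
    }
    Fm <- P %*% extractor$filters
    if (identical(extractor$rectify %||% "abs", "abs")) Fm <- abs(Fm)
    # cells were filled rows-fastest within column; map back to (i, j)
    out[n, , , ] <- array(Fm, dim = c(gh, gw, extractor$channels))
  }
  attr(out, "grid_rows") <- g$rows
  attr(out, "grid_cols") <- g$cols
  attr(out, "extractor") <- extractor$name
  out
}

#' Spatial attribution mask from per-location regressions
#'
#' At every grid location, ordinary least squares predicts `responses` from
#' that location's feature channels (with intercept); the map of adjusted
#' R-squared values is the attribution mask. With `n <= channels + 1`
#' observations the fit falls back to ridge regression (penalty
#' `1e-3 * mean(diag(X'X))`) and the mask is flagged.
#'
#' @param features array from [extract_local_features()].
#' @param responses numeric vector, one response per image.
#' @return Object of class `attribution_mask`: `r2` (grid matrix of
#'   adjusted R-squared), `weights` (grid x channels array), `n`, and
#'   `flagged` (constant responses or ridge fallback).
#' @export
spatial_attribution_mask <- function(features, responses) {
  n <- dim(features)[1]
  stopifnot(length(responses) == n)
  gh <- dim(features)[2]
  gw <- dim(features)[3]
  C <- dim(features)[4]
  flagged <- character()
  if (stats::sd(responses) == 0) {
    flagged <- c(flagged, "constant responses; R2 defined as 0")
    return(structure(list(r2 = matrix(0, gh, gw),
                          weights = array(0, c(gh, gw, C)),
                          n = n, flagged = flagged),
                     class = "attribution_mask"))
  }
  ridge <- n <= C + 1
  if (ridge) flagged <- c(flagged, "n <= channels + 1; ridge fallback")
  r2 <- matrix(NA_real_, gh, gw)
  W <- array(NA_real_, c(gh, gw, C))
  sst <- sum((responses - mean(responses))^2)
  for (i in seq_len(gh)) {
    for (j in seq_len(gw)) {
      X <- cbind(1, matrix(features[, i, j, ], nrow = n))
      if (!ridge) {
        fit <- stats::lm.fit(X, responses)
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        res <- responses - X %*% cf
        p_eff <- fit$rank - 1
      } else {
        XtX <- crossprod(X)
        lam <- 1e-3 * mean(diag(XtX))
        cf <- solve(XtX + diag(lam, ncol(X)), crossprod(X, responses))
        res <- responses - X %*% cf
        p_eff <- C
      }
      rsq <- 1 - sum(res^2) / sst
      denom <- n - p_eff - 1
      r2[i, j] <- if (denom > 0) 1 - (1 - rsq) * (n - 1) / denom else rsq
      W[i, j, ] <- cf[-1]
    }
  }
  structure(list(r2 = r2, weights = W, n = n, flagged = flagged),
            class = "attribution_mask")
}

#' @export
print.attribution_mask <- function(x, ...) {
  cat(sprintf("<attribution_mask> %dx%d grid, n=%d, max adj R2=%.3f%s\n",
              nrow(x$r2), ncol(x$r2), x$n, max(x$r2),
              if (length(x$flagged)) paste0(" [", x$flagged[1], "]") else ""))
  invisible(x)
}

# Connected components of a logical matrix under 8-connectivity.
# Returns an integer label matrix; labels follow row-major discovery order.
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        queue <- list(c(i, j))
        lab[i, j] <- cur
        while (length(queue)) {
          p <- queue[[1]]
          queue <- queue[-1]
          for (di in -1:1) for (dj in -1:1) {
            ni <- p[1] + di
            nj <- p[2] + dj
            if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
                mask[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- cur
              queue[[length(queue) + 1L]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  lab
}

#' Representative weight vector of an attribution mask
#'
#' Thresholds the adjusted R-squared map at its 80th percentile, finds the
#' largest connected above-threshold region (8-connectivity; size ties go
#' to the region containing the first cell in row-major order), and
#' averages the per-location weight vectors over that region.
#'
#' @param mask an `attribution_mask`.
#' @param percentile threshold quantile (default 0.8).
#' @return Numeric weight vector of length `channels`.
#' @export
mask_weight_vector <- function(mask, percentile = 0.8) {
  thr <- stats::quantile(mask$r2, percentile, names = FALSE)
  above <- mask$r2 > thr
  if (!any(above)) stop("no cells above the threshold")
  lab <- connected_components(above)
  sizes <- tabulate(lab[lab > 0])
  # row-major discovery order means the first label wins size ties
  best <- which(sizes == max(sizes))[1]
  sel <- which(lab == best, arr.ind = TRUE)
  colMeans(t(vapply(seq_len(nrow(sel)), function(k) {
    mask$weights[sel[k, 1], sel[k, 2], ]
  }, numeric(dim(mask$weights)[3]))))
}

#' Pearson correlation between two mask weight vectors
#'
#' @param wa,wb numeric vectors of equal length.
#' @return Pearson r, or `NA` (with a warning) if either vector has zero
#'   variance.
#' @export
mask_correlation <- function(wa, wb) {
  stopifnot(length(wa) == length(wb))
  if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
    warning("zero variance weight vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(wa, wb)
}

#' Rank test comparing same-driver and cross-driver mask correlations
#'
#' @param same numeric vector of same-driver correlations.
#' @param cross numeric vector of cross-driver correlations.
#' @return List with the Wilcoxon rank-sum statistic and p value, and the
#'   two medians.
#' @export
mask_correlation_test <- function(same, cross) {
  wt <- stats::wilcox.test(same, cross, alternative = "greater")
  list(w = unname(wt$statistic), p = wt$p.value,
       median_same = stats::median(same), median_cross = stats::median(cross))
}

#' Total variation of a 2-D map
#'
#' Sum over grid points of the Euclidean norm of the forward-difference
#' gradient (differences beyond the last row/column taken as zero).
#'
#' @param map numeric matrix.
#' @return Non-negative scalar; 0 for constant maps, homogeneous of degree
#'   1 in the map values.
#' @export
total_variation <- function(map) {
  map <- as.matrix(map)
  dx <- cbind(map[, -1, drop = FALSE] - map[, -ncol(map), drop = FALSE], 0)
  dy <- rbind(map[-1, , drop = FALSE] - map[-nrow(map), , drop = FALSE], 0)
  sum(sqrt(dx^2 + dy^2))
}

#' Patchwise perceptual similarity heatmap
#'
#' Embeds both images with the extractor, takes at every grid cell the
#' normalized feature distance `d = ||fa/||fa|| - fb/||fb|||| / 2` (range
#' `[0, 1]`), and returns `similarity = 1 - d`. A lightweight stand-in for
#' learned perceptual patch similarity; symmetric in its arguments and
#' bounded above by 1.
#'
#' @param img_a,img_b image arrays of identical size.
#' @param extractor a `feature_extractor`.
#' @return Object of class `similarity_heatmap`: `map` (grid matrix) and
#'   `metric` name.
#' @export
perceptual_similarity_map <- function(img_a, img_b,
                                      extractor = feature_bank()) {
  if (!all(dim(img_a) == dim(img_b))) stop("images must share one size")
  fa <- extract_local_features(list(img_a), extractor)
  fb <- extract_local_features(list(img_b), extractor)
  gh <- dim(fa)[2]
  gw <- dim(fa)[3]
  map <- matrix(NA_real_, gh, gw)
  for (i in seq_len(gh)) {
    for (j in seq_len(gw)) {
      va <- fa[1, i, j, ]
      vb <- fb[1, i, j, ]
      na <- sqrt(sum(va^2))
      nb <- sqrt(sum(vb^2))
      if (na > 0) va <- va / na
      if (nb > 0) vb <- vb / nb
      map[i, j] <- 1 - sqrt(sum((va - vb)^2)) / 2
    }
  }
  structure(list(map = map, metric = paste0("1-", extractor$name)),
            class = "similarity_heatmap")
}

#' Concentration score of a similarity heatmap
#'
#' For each filter side length `k`, convolves the map (valid mode) with a
#' `k x k` uniform filter normalized to sum 1 and records the maximum local
#' average; the score is the mean of these maxima across sizes. High scores
#' indicate similarity concentrated in compact regions.
#'
#' @param heatmap a `similarity_heatmap` or numeric matrix.
#' @param sizes filter side lengths (each between 1 and the smaller map
#'   dimension).
#' @return Scalar score.
#' @export
concentration_score <- function(heatmap, sizes = c(1, 2, 3, 5, 8)) {
  map <- if (inherits(heatmap, "similarity_heatmap")) heatmap$map else heatmap
  map <- as.matrix(map)
  stopifnot(all(sizes >= 1))
  if (any(sizes > min(dim(map)))) {
    stop("filter size exceeds the heatmap dimensions")
  }
  # summed-area table for O(1) window sums
  S <- apply(apply(map, 2, cumsum), 1, cumsum)
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  win_max <- vapply(sizes, function(k) {
    nr <- nrow(map) - k + 1
    nc <- ncol(map) - k + 1
    i <- seq_len(nr)
    j <- seq_len(nc)
    sums <- S[i + k, j + k, drop = FALSE] - S[i, j + k, drop = FALSE] -
      S[i + k, j, drop = FALSE] + S[i, j, drop = FALSE]
    max(sums) / k^2
  }, numeric(1))
  mean(win_max)
}

#' Fit an encoding model and re-optimize a feature exemplar
#'
#' Builds a factorized (spatial x channel) linear readout of the extractor
#' features: channels are screened by correlation with the responses, the
#' screened correlation structure is factorized (rank-1 SVD) to initialize
#' the spatial map and channel weights, and both factors are refined by
#' alternating least squares. The fitted model's predicted response is then
#' maximized over the generator's latent space with CMA-ES; the maximizing
#' image is the feature exemplar.
#'
#' @param images list of >= 50 images.
#' @param responses numeric responses, one per image.
#' @param extractor a `feature_extractor`.
#' @param generator a `generator` used for the re-optimization.
#' @param seed integer seed.
#' @param init_latents optional matrix (`length(images) x latent_dim`) of
#'   the latents that produced `images`; when given, optimization starts at
#'   the best-predicted training latent and the returned exemplar is
#'   guaranteed to predict at least as high as every training image.
#' @param generations CMA-ES generations for the re-optimization.
#' @param screen_min minimum absolute correlation any feature must reach;
#'   below it the model is declared degenerate and an error is raised.
#' @return List with `image`, `z`, `predicted`, the fitted `model`
#'   (`spatial`, `channel`, `bias`, `predict`), and the training-set
#'   maximum `train_max`.
#' @export
feature_exemplar <- function(images, responses, extractor = feature_bank(),
                             generator, seed = 1L, init_latents = NULL,
                             generations = 40, screen_min = 0.1) {
  stopifnot(length(images) >= 50, length(responses) == length(images))
  feats <- extract_local_features(images, extractor)
  n <- dim(feats)[1]
  gh <- dim(feats)[2]
  gw <- dim(feats)[3]
  C <- dim(feats)[4]
  Fm <- matrix(feats, nrow = n) # n x (gh*gw*C), cell-major then channel
  cors <- suppressWarnings(stats::cor(Fm, responses))
  cors[is.na(cors)] <- 0
  if (max(abs(cors)) < screen_min) {
    stop("degenerate encoding model: no feature channel passes the correlation screen")
  }
  cor_mat <- matrix(array(cors, dim = c(gh, gw, C)), nrow = gh * gw, ncol = C)
  # spatial screen: the readout support is restricted to the cells whose
  # feature channels correlate most with the responses (overlapping patches
  # make an unrestricted spatial factor unidentifiable)
  cell_strength <- apply(abs(cor_mat), 1, max)
  keep <- which(cell_strength >= 0.5 * max(cell_strength))
  sv <- svd(cor_mat[keep, , drop = FALSE], nu = 1, nv = 1)
  s_keep <- sv$u[, 1] * sv$d[1]
  w_vec <- sv$v[, 1]
  if (sum((s_keep %o% w_vec) * cor_mat[keep, , drop = FALSE]) < 0) {
    s_keep <- -s_keep
  }
  Fcell <- array(Fm, dim = c(n, gh * gw, C))
  bias <- mean(responses)
  for (it in 1:5) {
    U <- vapply(keep, function(cell) Fcell[, cell, ] %*% w_vec, numeric(n))
    Xs <- cbind(1, U)
    lam <- 1e-6 * mean(colSums(U^2))
    cf <- solve(crossprod(Xs) + diag(c(0, rep(lam, length(keep)))),
                crossprod(Xs, responses))
    bias <- cf[1]
    s_keep <- cf[-1]
    s_full <- rep(0, gh * gw)
    s_full[keep] <- s_keep
    V <- vapply(seq_len(C), function(ch) Fcell[, , ch] %*% s_full, numeric(n))
    Xc <- cbind(1, V)
    cf2 <- tryCatch(qr.coef(qr(Xc), responses), error = function(e) NULL)
    if (is.null(cf2) || anyNA(cf2)) break
    bias <- cf2[1]
    w_vec <- cf2[-1]
  }
  s_vec <- rep(0, gh * gw)
  s_vec[keep] <- s_keep
  predict_features <- function(f1) {
    sum((matrix(f1, nrow = gh * gw) %*% w_vec) * s_vec) + bias
  }
  predict_image <- function(img) {
    predict_features(extract_local_features(list(img), extractor)[1, , , ])
  }
  pred_train <- vapply(seq_len(n), function(i) predict_features(feats[i, , , ]),
                       numeric(1))
  train_max <- max(pred_train)
  mean0 <- rep(0, generator$latent_dim)
  if (!is.null(init_latents)) {
    stopifnot(nrow(init_latents) == n)
    mean0 <- init_latents[which.max(pred_train), ]
  }
  st <- cma_init(generator$latent_dim, mean0 = mean0,
                 sigma0 = if (is.null(generator$partition)) 0.5 else 0.09,
                 popsize = 20, seed = derive_seed(seed, "exemplar"))
  opt <- cma_optimize(function(z) predict_image(render_image(generator, z)),
                      st, generations)
  cands <- list(list(z = opt$best_x, p = opt$best_score))
  if (!is.null(init_latents)) {
    z0 <- init_latents[which.max(pred_train), ]
    cands[[2]] <- list(z = z0, p = predict_image(render_image(generator, z0)))
  }
  best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "p"))]]
  list(image = render_image(generator, best$z), z = best$z,
       predicted = best$p, train_max = train_max,
       model = list(spatial = matrix(s_vec, gh, gw), channel = w_vec,
                    bias = bias, predict = predict_image))
}
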