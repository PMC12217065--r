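#' Texture class parameters for the synthetic histology generator
#'
#' A cartoon of nuclear density and pleomorphism: benign-like tissue is
#' sparse, round and smooth; malignant-like tissue is dense, irregular and
#' rich in high-frequency noise. The gap between the two classes scales with
#' `separability` (0 = identical parameters, 1 = maximally distinct).
#'
#' @param class 0 (benign-like) or 1 (malignant-like).
#' @param separability Class-contrast control in `[0, 1]`.
#' @return List with `density` (blobs per 1e4 px^2), `radius` (range, px),
#'   `irregularity` in `[0, 1]`, `noise` (high-frequency amplitude),
#'   `background` and `blob` RGB tints.
#' @export
texture_class_params <- function(class, separability = 1) {
  if (separability < 0 || separability > 1) {
    abort("separability must lie in [0, 1]")
  }
  s <- separability
  if (class == 0) {
    list(density = 6, radius = c(3, 6), irregularity = 0.15, noise = 0.02,
         background = c(0.85, 0.75, 0.85), blob = c(0.45, 0.30, 0.55))
  } else {
    list(density = 6 + 10 * s, radius = c(3 - s, 6 - s),
         irregularity = 0.15 + 0.6 * s, noise = 0.02 + 0.08 * s,
         background = c(0.85, 0.75, 0.85),
         blob = c(0.45 - 0.1 * s, 0.30, 0.55))
  }
}

#' Render one synthetic histology-texture image
#'
#' Poisson-placed elliptical blobs with irregular boundaries (radial
#' perturbation proportional to the irregularity parameter) on a tinted
#' background, plus additive high-frequency pixel noise; values clipped to
#' `[0, 1]`. Uses the current RNG state — seed outside for determinism.
#'
#' @param params Class parameters from [texture_class_params()].
#' @param side Image side length in pixels.
#' @return `side x side x 3` RGB array.
#' @export
generate_class_image <- function(params, side = 64L) {
  if (any(params$radius <= 0) || params$density < 0) {
    abort("invalid texture parameters")
  }
  img <- array(rep(params$background, each = side * side),
               c(side, side, 3))
  n_blobs <- rpois(1, params$density * side^2 / 1e4)
  xs <- matrix(rep(seq_len(side), side), side, side)
  ys <- t(xs)
  for (bl in seq_len(n_blobs)) {
    cx <- runif(1, 1, side)
    cy <- runif(1, 1, side)
    r0 <- runif(1, params$radius[1], params$radius[2])
    aspect <- 1 + params$irregularity * runif(1, 0, 1.5)
    rot <- runif(1, 0, pi)
    # low-order radial harmonics perturb the boundary
    k_h <- sample(2:5, 2)
    amp <- params$irregularity * runif(2, 0.1, 0.45)
    phs <- runif(2, 0, 2 * pi)
    dx <- xs - cx
    dy <- ys - cy
    u <- dx * cos(rot) + dy * sin(rot)
    v <- (-dx * sin(rot) + dy * cos(rot)) * aspect
    theta <- atan2(v, u)
    rad <- sqrt(u^2 + v^2)
    boundary <- r0 * (1 + amp[1] * sin(k_h[1] * theta + phs[1]) +
                        amp[2] * sin(k_h[2] * theta + phs[2]))
    inside <- rad <= pmax(boundary, 0.5)
    shade <- runif(1, 0.85, 1.15)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- params$blob[ch] * shade
      img[, , ch] <- plane
    }
  }
  if (params$noise > 0) {
    img <- img + array(rnorm(side * side * 3, sd = params$noise),
                       dim(img))
  }
  array(pmin(pmax(img, 0), 1), dim(img))
}

#' Generate a balanced two-class synthetic image set
#'
#' Class 0 is benign-like (sparse, round, smooth), class 1 malignant-like
#' (dense, irregular, high-frequency), with the parameter gap scaled by
#' `separability`. Deterministic given `seed`; exactly `n_per_class` samples
#' per class. When `dir` is given, images are written as PNGs with a
#' `manifest.csv` alongside.
#'
#' @param n_per_class Samples per class.
#' @param side Image side length (>= 32).
#' @param separability Class contrast in `[0, 1]`.
#' @param seed Integer seed.
#' @param dir Optional output directory for PNGs + manifest.
#' @return Tibble with `id`, `label`, `image` (list of RGB arrays).
#' @export
generate_dataset <- function(n_per_class = 50L, side = 64L, separability = 1,
                             seed = 1L, dir = NULL) {
  if (n_per_class < 1) abort("n_per_class must be >= 1")
  if (side < 32) abort("side must be >= 32")
  set.seed(seed)
  rows <- lapply(c(0L, 1L), function(cl) {
    params <- texture_class_params(cl, separability)
    tibble(
      id = sprintf("class%d_%03d", cl, seq_len(n_per_class)),
      label = cl,
      image = lapply(seq_len(n_per_class), function(i) {
        generate_class_image(params, side)
      })
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(out))) {
      png::writePNG(out$image[[i]], file.path(dir, paste0(out$id[i], ".png")))
    }
    readr::write_csv(
      tibble(path = paste0(out$id, ".png"),
             label = ifelse(out$label == 1, "malignant", "benign")),
      file.path(dir, "manifest.csv")
    )
  }
  out
}

#' Generate a tabular fixture with planted informative features
#'
#' Informative features are class-shifted Gaussians (shift = `effect_size`),
#' noise features are standard Gaussians, and redundant features are noisy
#' copies of named source columns. Balanced labels by construction;
#' deterministic given `seed`.
#'
#' @param n Total number of samples (split evenly between classes).
#' @param d Number of base features before redundant copies.
#' @param informative Indices of informative features (default `1:5`).
#' @param effect_size Class mean shift of informative features.
#' @param redundant Named list mapping new-column names to
#'   `list(source = j, sd = s)` noisy-copy specs (appended after the `d`
#'   base columns), or `NULL`.
#' @param noise_sd Standard deviation of all feature noise.
#' @param seed Integer seed.
#' @return List with `features` (matrix, named columns), `labels` (0/1
#'   vector) and `truth_mask` (logical, marks informative columns).
#' @export
generate_feature_table <- function(n = 500L, d = 50L, informative = 1:5,
                                   effect_size = 3, redundant = NULL,
                                   noise_sd = 1, seed = 1L) {
  if (any(informative < 1 | informative > d)) {
    abort("informative indices must lie in [1, d]")
  }
  set.seed(seed)
  half <- n %/% 2
  labels <- rep(c(0L, 1L), c(n - half, half))
  x <- matrix(rnorm(n * d, sd = noise_sd), n, d)
  for (j in informative) {
    x[, j] <- x[, j] + effect_size * labels
  }
  colnames(x) <- sprintf("f%02d", seq_len(d))
  truth <- seq_len(d) %in% informative
  if (!is.null(redundant)) {
    extra <- vapply(redundant, function(spec) {
      x[, spec$source] + rnorm(n, sd = spec$sd)
    }, numeric(n))
    colnames(extra) <- names(redundant)
    x <- cbind(x, extra)
    truth <- c(truth, rep(FALSE, length(redundant)))
  }
  list(features = x, labels = labels, truth_mask = truth)
}
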