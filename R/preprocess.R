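# Colour-transfer matrices for the lαβ perceptual space (RGB -> LMS -> log ->
# decorrelated lαβ and back). Values are the standard Reinhard transfer
# constants.
.rgb2lms <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444
), nrow = 3, byrow = TRUE)

# exact inverse of the forward matrix (the commonly printed 4-decimal
# inverse leaves ~1e-3 round-trip error)
.lms2rgb <- solve(.rgb2lms)

.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), nrow = 3, byrow = TRUE)

.lab2lms <- solve(.lms2lab)

# log10 floor: avoids -Inf for pure-black pixels
.lab_eps <- 1e-6

#' Convert an RGB image to the lab perceptual colour space
#'
#' Pixels are mapped RGB -> LMS cone response -> log10 -> decorrelated lab
#' axes (luminance, yellow-blue, red-green). This is the space in which
#' Reinhard colour transfer matches channel statistics.
#'
#' @param image H x W x 3 array with values in `[0, 1]`.
#' @return H x W x 3 array of lab values.
#' @export
rgb_to_lab <- function(image) {
  check_rgb(image)
  dims <- dim(image)
  px <- matrix(image, ncol = 3)
  lms <- pmax(px %*% t(.rgb2lms), .lab_eps)
  lab <- log10(lms) %*% t(.lms2lab)
  array(lab, dims)
}

#' Convert a lab image back to RGB
#'
#' Inverse of [rgb_to_lab()]; output is clipped to `[0, 1]`.
#'
#' @param lab H x W x 3 array of lab values.
#' @return H x W x 3 RGB array in `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  check_rgb(lab)
  dims <- dim(lab)
  px <- matrix(lab, ncol = 3)
  lms <- 10^(px %*% t(.lab2lms))
  rgb <- lms %*% t(.lms2rgb)
  array(pmin(pmax(rgb, 0), 1), dims)
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("image must be an H x W x 3 array")
  }
  if (dim(image)[1] < 1 || dim(image)[2] < 1) abort("image must be nonempty")
  invisible(TRUE)
}

#' Reference colour statistics for Reinhard transfer
#'
#' Pools the pixels of one or more RGB images in lab space and records the
#' per-channel mean and standard deviation. By default the reference is
#' computed from the training split's pooled pixels, since no canonical
#' reference slide exists for synthetic data.
#'
#' @param images A single H x W x 3 array or a list of them.
#' @return A tibble with columns `channel` (`l`, `alpha`, `beta`), `mean`,
#'   `sd`; standard deviations are floored at `1e-8` so they stay strictly
#'   positive.
#' @export
reference_color_stats <- function(images) {
  if (is.array(images)) images <- list(images)
  labs <- lapply(images, function(im) matrix(rgb_to_lab(im), ncol = 3))
  px <- do.call(rbind, labs)
  tibble(
    channel = c("l", "alpha", "beta"),
    mean = colMeans(px),
    sd = pmax(apply(px, 2, sd), 1e-8)
  )
}

#' Reinhard colour normalization
#'
#' Shifts and scales each lab channel of `image` so its mean and standard
#' deviation match the reference statistics, then converts back to RGB and
#' clips to `[0, 1]`. A source channel with zero spread cannot be rescaled;
#' it is passed through unchanged with a warning (documented fallback).
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param ref Reference statistics from [reference_color_stats()].
#' @return Colour-normalized RGB array, same dimensions as the input.
#' @export
reinhard_normalize <- function(image, ref) {
  check_rgb(image)
  stopifnot(all(c("mean", "sd") %in% names(ref)), nrow(ref) == 3)
  if (any(ref$sd <= 0)) abort("reference standard deviations must be positive")
  lab <- rgb_to_lab(image)
  dims <- dim(lab)
  px <- matrix(lab, ncol = 3)
  for (ch in 1:3) {
    s <- sd(px[, ch])
    if (s < 1e-12) {
      warn(sprintf("channel %d has zero spread; passed through unscaled", ch))
      next
    }
    px[, ch] <- (px[, ch] - mean(px[, ch])) * (ref$sd[ch] / s) + ref$mean[ch]
  }
  lab_to_rgb(array(px, dims))
}

#' Resize, colour-normalize and z-score one image
#'
#' The standardization contract of the pipeline: optional Reinhard colour
#' normalization, bilinear resize to `side x side` (anti-aliased), then a
#' joint z-score over all pixels and channels so the image has mean 0 and
#' variance 1. The z-score step is idempotent.
#'
#' @param image H x W x 3 RGB array in `[0, 1]`.
#' @param ref Optional reference colour statistics; when `NULL` the Reinhard
#'   step is skipped.
#' @param side Output side length in pixels (default 224).
#' @return `side x side x 3` array with mean ~0 and variance ~1.
#' @export
standardize_image <- function(image, ref = NULL, side = 224L) {
  check_rgb(image)
  if (!is.null(ref)) image <- reinhard_normalize(image, ref)
  if (dim(image)[1] != side || dim(image)[2] != side) {
    image <- EBImage::resize(image, w = side, h = side, filter = "bilinear",
                             antialias = TRUE)
    image <- array(pmin(pmax(image, 0), 1), c(side, side, 3L))
  }
  zscore_image(image)
}

#' Joint per-image z-score
#'
#' Centers and scales all pixels/channels jointly to zero mean, unit
#' variance. A constant image has no scale and is rejected.
#'
#' @param image Numeric array.
#' @return Array of the same shape with mean 0, variance 1.
#' @export
zscore_image <- function(image) {
  s <- sd(as.vector(image))
  if (!is.finite(s) || s < 1e-12) abort("degenerate image: zero variance, cannot z-score")
  (image - mean(image)) / s
}

.allowed_labels <- c("0", "1", "benign", "malignant")

normalize_labels <- function(labels) {
  lab <- tolower(trimws(as.character(labels)))
  bad <- setdiff(unique(lab), .allowed_labels)
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown label(s) %s; allowed labels: %s",
      paste(sQuote(bad), collapse = ", "),
      paste(sQuote(.allowed_labels), collapse = ", ")
    ))
  }
  as.integer(lab %in% c("1", "malignant"))
}

read_rgb_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = abort(sprintf("JPEG input is not supported in this build: %s", path)),
    abort(sprintf("unsupported image format '%s': %s", ext, path))
  )
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  array(pmin(pmax(img, 0), 1), dim(img))
}

#' Load a labelled image set from a manifest
#'
#' Reads a CSV manifest with header `path,label` (paths relative to the
#' manifest's directory unless absolute), decodes each image to an RGB array
#' in `[0, 1]`, and maps labels to the binary convention 0 = benign,
#' 1 = malignant.
#'
#' @param manifest Path to the manifest CSV.
#' @return A tibble with columns `id` (derived from the path, extension
#'   stripped), `label` (integer 0/1) and `image` (list of H x W x 3 arrays).
#' @export
load_labeled_images <- function(manifest) {
  if (!file.exists(manifest)) abort(sprintf("manifest not found: %s", manifest))
  rows <- readr::read_csv(manifest, col_types = readr::cols(.default = "c"))
  if (!all(c("path", "label") %in% names(rows))) {
    abort("manifest must have columns 'path' and 'label'")
  }
  if (nrow(rows) == 0) abort("no samples: manifest is empty")
  base <- dirname(normalizePath(manifest))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", rows$path), rows$path,
                  file.path(base, rows$path))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("missing image file(s): %s", paste(missing, collapse = ", ")))
  }
  labels <- normalize_labels(rows$label)
  ids <- tools::file_path_sans_ext(basename(rows$path))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
  }
  tibble(
    id = ids,
    label = labels,
    image = lapply(paths, read_rgb_file)
  )
}

#' Standardize every image of a labelled set
#'
#' Applies [standardize_image()] sample-wise; the Reinhard reference defaults
#' to the pooled colour statistics of the set itself (pass the training
#' split's stats to normalize held-out data consistently).
#'
#' @param image_set Tibble with `id`, `label`, `image` columns.
#' @param ref Reference colour statistics, or `NULL` to compute them from
#'   `image_set`, or `FALSE` to skip colour normalization.
#' @param side Output side length.
#' @return The tibble with its `image` column standardized.
#' @export
standardize_images <- function(image_set, ref = NULL, side = 224L) {
  stopifnot(is_tibble(image_set), "image" %in% names(image_set))
  if (is.null(ref)) ref <- reference_color_stats(image_set$image)
  if (isFALSE(ref)) ref <- NULL
  image_set$image <- lapply(image_set$image, standardize_image, ref = ref,
                            side = side)
  image_set
}
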