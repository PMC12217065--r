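# Orthonormal scaling (father/lowpass) filter taps. The wavelet (mother/
# highpass) filter is the quadrature-mirror pair g[n] = (-1)^n h[L-1-n].
# Daubechies taps are stored to full double precision.
.wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079,
          0.2241438680420134, -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157,
          0.6308807679298589, -0.027983769416859854,
          -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032)
)

#' Construct a wavelet specification
#'
#' Returns the analysis filter pair of an orthonormal wavelet: the lowpass
#' (father/scaling) taps, which sum to `sqrt(2)`, and the highpass
#' (mother/wavelet) taps, which sum to 0 — the discrete analogue of the
#' admissibility condition that the mother wavelet integrate to zero.
#'
#' @param name One of `"haar"`, `"db2"`, `"db4"`.
#' @return An object of class `wavelet_spec` with fields `name`, `lowpass`,
#'   `highpass`.
#' @examples
#' make_wavelet("haar")
#' @export
make_wavelet <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.wavelet_filters)) {
    abort(sprintf(
      "unknown wavelet %s; supported wavelets: %s",
      sQuote(as.character(name)[1]),
      paste(names(.wavelet_filters), collapse = ", ")
    ))
  }
  h <- .wavelet_filters[[name]]
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  structure(list(name = name, lowpass = h, highpass = g),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("<wavelet_spec> %s (%d taps)\n", x$name, length(x$lowpass)))
  invisible(x)
}

as_wavelet <- function(wavelet) {
  if (inherits(wavelet, "wavelet_spec")) wavelet else make_wavelet(wavelet)
}

#' One periodized analysis step of the 1-D fast wavelet transform
#'
#' Correlate-and-decimate with wrap-around (periodic) boundary handling:
#' `a[k] = sum_n h[n] x[(2k + n) mod N]` and likewise for the detail band
#' with the highpass taps. `N` must be even.
#'
#' @param x Numeric vector of even length.
#' @param wavelet A `wavelet_spec` or wavelet name.
#' @return List with `approx` and `detail`, each of length `N/2`.
#' @examples
#' dwt_step(c(1, 2, 3, 4), "haar")
#' @export
dwt_step <- function(x, wavelet) {
  w <- as_wavelet(wavelet)
  N <- length(x)
  if (N %% 2 != 0) abort("signal length must be even for a periodized step")
  m <- dwt_rows(matrix(x, nrow = 1), w)
  list(approx = as.vector(m$lo), detail = as.vector(m$hi))
}

# Periodized analysis along the rows of a matrix, vectorized over taps.
dwt_rows <- function(X, w) {
  N <- ncol(X)
  K <- N / 2
  h <- w$lowpass
  g <- w$highpass
  lo <- matrix(0, nrow(X), K)
  hi <- matrix(0, nrow(X), K)
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_along(h)) {
    cols <- ((base + n - 1) %% N) + 1
    lo <- lo + h[n] * X[, cols, drop = FALSE]
    hi <- hi + g[n] * X[, cols, drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

# Periodized synthesis along the rows: inverse of dwt_rows.
idwt_rows <- function(lo, hi, w) {
  K <- ncol(lo)
  N <- 2 * K
  h <- w$lowpass
  g <- w$highpass
  X <- matrix(0, nrow(lo), N)
  base <- 2 * (seq_len(K) - 1)
  for (n in seq_along(h)) {
    cols <- ((base + n - 1) %% N) + 1
    X[, cols] <- X[, cols] + h[n] * lo + g[n] * hi
  }
  X
}

#' Multilevel 2-D fast discrete wavelet transform
#'
#' Separable analysis filter bank applied recursively to the approximation
#' (smooth) band with periodic boundary handling. Level-1 details are
#' computed from the input; the level-`levels` approximation is retained.
#' Orientation convention: `horizontal` = lowpass along rows / highpass along
#' columns, `vertical` the transpose, `diagonal` = highpass in both.
#'
#' @param image Numeric matrix (grayscale) with finite entries; both sides
#'   must be divisible by `2^levels`.
#' @param wavelet A `wavelet_spec` or name (default `"haar"`).
#' @param levels Number of decomposition levels `J >= 1`.
#' @return An object of class `wavelet_decomposition`: a list with `levels`,
#'   `approximation` (the level-J smooth band), `details` (per level, a list
#'   of `horizontal`, `vertical`, `diagonal` matrices), `boundary`
#'   (`"periodic"`) and the `wavelet` used.
#' @export
fdwt2 <- function(image, wavelet = "haar", levels = 1L) {
  w <- as_wavelet(wavelet)
  if (!is.matrix(image)) image <- as.matrix(image)
  if (!all(is.finite(image))) abort("image must be finite")
  jmax <- floor(log2(min(dim(image))))
  if (levels < 1 || levels > jmax) {
    abort(sprintf("levels must lie in [1, %d] for a %dx%d image",
                  jmax, nrow(image), ncol(image)))
  }
  if (any(dim(image) %% 2^levels != 0)) {
    abort("image sides must be divisible by 2^levels for periodized analysis")
  }
  details <- vector("list", levels)
  a <- image
  for (j in seq_len(levels)) {
    rowband <- dwt_rows(a, w)                  # along rows (x direction)
    ll_lh <- dwt_rows(t(rowband$lo), w)        # then along columns
    hl_hh <- dwt_rows(t(rowband$hi), w)
    a <- t(ll_lh$lo)
    details[[j]] <- list(
      horizontal = t(ll_lh$hi),
      vertical = t(hl_hh$lo),
      diagonal = t(hl_hh$hi)
    )
  }
  structure(
    list(levels = levels, approximation = a, details = details,
         boundary = "periodic", wavelet = w),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, J = %d, approximation %dx%d\n",
              x$wavelet$name, x$levels,
              nrow(x$approximation), ncol(x$approximation)))
  invisible(x)
}

#' Inverse multilevel 2-D wavelet transform
#'
#' Synthesis bank reconstructing the original image from a
#' [fdwt2()] decomposition; exact inverse up to floating point.
#'
#' @param decomp A `wavelet_decomposition`.
#' @return The reconstructed grayscale matrix.
#' @export
ifdwt2 <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  w <- decomp$wavelet
  a <- decomp$approximation
  for (j in rev(seq_len(decomp$levels))) {
    d <- decomp$details[[j]]
    if (!all(dim(d$horizontal) == dim(a)) || !all(dim(d$vertical) == dim(a)) ||
        !all(dim(d$diagonal) == dim(a))) {
      abort(sprintf("mismatched subband shapes at level %d", j))
    }
    lo <- t(idwt_rows(t(a), t(d$horizontal), w))
    hi <- t(idwt_rows(t(d$vertical), t(d$diagonal), w))
    a <- idwt_rows(lo, hi, w)
  }
  a
}

subband_stats_one <- function(coef, prefix) {
  v <- as.vector(coef)
  absv <- abs(v)
  energy <- mean(v^2)
  if (max(absv) < .Machine$double.eps) {
    entropy <- 0
  } else {
    counts <- tabulate(
      pmin(64L, floor(absv / max(absv) * 64) + 1L), nbins = 64L
    )
    p <- counts / sum(counts)
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  }
  stats <- c(mean(absv), sd(v), energy, entropy)
  names(stats) <- paste0(prefix, "_", c("mean", "sd", "energy", "entropy"))
  stats
}

#' Per-subband texture statistics of a wavelet decomposition
#'
#' For each subband (all detail bands plus the level-J approximation) four
#' statistics are computed: mean absolute coefficient, standard deviation,
#' energy (mean squared coefficient), and the Shannon entropy (base 2) of a
#' 64-bin histogram of the normalized absolute coefficients, with
#' `0 * log(0) := 0`. Degenerate (all-zero) subbands yield entropy 0.
#'
#' @param decomp A `wavelet_decomposition`.
#' @return One-row tibble with `(3J + 1) * 4` columns named like
#'   `L2_horizontal_energy`; name order is deterministic.
#' @export
subband_statistics <- function(decomp) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  out <- c()
  for (j in seq_len(decomp$levels)) {
    for (band in c("horizontal", "vertical", "diagonal")) {
      out <- c(out, subband_stats_one(decomp$details[[j]][[band]],
                                      sprintf("L%d_%s", j, band)))
    }
  }
  out <- c(out, subband_stats_one(decomp$approximation,
                                  sprintf("L%d_approximation", decomp$levels)))
  as_tibble(as.list(out))
}

#' Luminance of an RGB image
#'
#' ITU-R 601 weights: `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image H x W x 3 array.
#' @return H x W matrix.
#' @export
luminance <- function(image) {
  check_rgb(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Wavelet texture features for a labelled image set
#'
#' Reduces each image to luminance, decomposes it with [fdwt2()], and
#' collects the per-subband statistics into a feature table. Row order
#' matches sample order and column names are stable across runs.
#'
#' @param image_set Tibble with `id`, `label`, `image` columns (standardized
#'   images).
#' @param wavelet Wavelet name or spec (default `"haar"`).
#' @param levels Decomposition depth (default 3).
#' @return Tibble with `id`, `label` and `(3 * levels + 1) * 4` feature
#'   columns.
#' @export
extract_features <- function(image_set, wavelet = "haar", levels = 3L) {
  stopifnot(is_tibble(image_set), all(c("id", "label", "image") %in% names(image_set)))
  w <- as_wavelet(wavelet)
  feats <- lapply(seq_len(nrow(image_set)), function(i) {
    tryCatch(
      subband_statistics(fdwt2(luminance(image_set$image[[i]]), w, levels)),
      error = function(e) {
        abort(sprintf("feature extraction failed for sample '%s': %s",
                      image_set$id[i], conditionMessage(e)))
      }
    )
  })
  dplyr::bind_cols(
    tibble(id = image_set$id, label = image_set$label),
    dplyr::bind_rows(feats)
  )
}
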