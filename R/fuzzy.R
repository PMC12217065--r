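#' Class probabilities from per-class energies
#'
#' `P_i` is proportional to `exp(-E_i)` — a normalized exponential over
#' negated energies (a softmax over logits `-E`), numerically stabilized by
#' subtracting the minimum energy. The output is shift-invariant in `E` and
#' sums to 1.
#'
#' @param energies Finite numeric vector of per-class energies `E_i`.
#' @return Probability vector of the same length.
#' @examples
#' class_distribution(c(0, log(3))) # 0.75, 0.25
#' @export
class_distribution <- function(energies) {
  if (!all(is.finite(energies))) abort("energies must be finite")
  e <- exp(-(energies - min(energies)))
  e / sum(e)
}

window_idx <- function(i, a, b, m) {
  if (i < 1 || i > m) abort("class index out of range")
  if (a < 0 || b < 0) abort("window extents must be nonnegative")
  max(1, i - a):min(m, i + b)
}

#' Probability-weighted window centroid
#'
#' The centroid `V0` of the class-index window `[i - a, i + b]` (clipped to
#' `[1, m]`), weighted by the class probabilities:
#' `V0 = sum(j * P_j) / sum(P_j)` over the window. Its distance from `i`
#' measures how much probability mass leaks to neighbouring classes.
#'
#' @param P Probability vector over `m` classes.
#' @param i True/reference class index (1-based).
#' @param a Window extent toward lower class indices (benign-ward).
#' @param b Window extent toward higher class indices (malignant-ward).
#' @return The centroid `V0`, inside the clipped window.
#' @examples
#' window_centroid(c(0.2, 0.5, 0.3), i = 2, a = 1, b = 1) # 2.1
#' @export
window_centroid <- function(P, i, a, b) {
  idx <- window_idx(i, a, b, length(P))
  mass <- sum(P[idx])
  if (mass <= 0) abort("window probability mass is zero")
  v0 <- sum(idx * P[idx]) / mass
  # the exact centroid lies inside the window; clamp away rounding noise
  min(max(v0, min(idx)), max(idx))
}

#' Fuzzy redistributed probability
#'
#' `P~_i = (|i - V0| / (a + b)) * sum(P_j over the window)`. The window
#' width `a + b` normalizes the centroid distance, so
#' `0 <= P~_i < sum(window P)` always holds.
#'
#' @inheritParams window_centroid
#' @return The redistributed probability `P~_i`.
#' @examples
#' fuzzy_redistribute(c(0.2, 0.5, 0.3), i = 2, a = 1, b = 1) # 0.05
#' @export
fuzzy_redistribute <- function(P, i, a, b) {
  if (a + b < 1) abort("window width a + b must be >= 1")
  idx <- window_idx(i, a, b, length(P))
  v0 <- window_centroid(P, i, a, b)
  (abs(i - v0) / (a + b)) * sum(P[idx])
}

#' Plain and fuzzy backpropagation errors and their difference
#'
#' `epsilon_i = y_i - P_i`, `epsilon~_i = y_i - P~_i`, and the impact term
#' `phi = (|i - V0| / (a + b)) * sum(window P) - P_i` (i.e. `P~_i - P_i`).
#' When class `i` holds the window maximum, `phi <= 0`, so substituting the
#' fuzzy error shrinks the output-layer update for confidently-windowed
#' samples; in the equal-probability window case
#' `phi = (|i - V0| / (a + b) - 1) * P_i` exactly.
#'
#' @param y One-hot target vector.
#' @param P Probability vector.
#' @inheritParams window_centroid
#' @return List with scalars `epsilon`, `epsilon_tilde`, `phi` (for class
#'   `i`) plus the redistributed `p_tilde` and centroid `v0`.
#' @export
fuzzy_errors <- function(y, P, i, a, b) {
  if (length(y) != length(P)) abort("y and P must have equal length")
  pt <- fuzzy_redistribute(P, i, a, b)
  list(
    epsilon = y[i] - P[i],
    epsilon_tilde = y[i] - pt,
    phi = pt - P[i],
    p_tilde = pt,
    v0 = window_centroid(P, i, a, b)
  )
}

# Redistributed probability for every class index at once (each class uses
# its own window); the vector form used by the output-layer gradient.
fuzzy_redistribute_all <- function(P, a, b) {
  vapply(seq_along(P), function(j) fuzzy_redistribute(P, j, a, b), numeric(1))
}

#' Fuzzy scoring configuration
#'
#' Parameters of the fuzzy output stage: class count `m`, window extents
#' `a` (negative/benign-ward growth tendency) and `b` (positive/
#' malignant-ward), class score anchors, the Gaussian membership spread
#' scaling, and per-class decision thresholds.
#'
#' @param m Number of classes (>= 2).
#' @param a,b Nonnegative integer window extents with `a + b >= 1`.
#' @param anchors Class score anchors `S` (default `1:m`).
#' @param spread_scale Multiplier on fitted Gaussian spreads (default 1).
#' @param threshold Decision threshold in (0, 1) on the malignant score
#'   (default 0.5).
#' @return List of class `fuzzy_config`.
#' @export
fuzzy_config <- function(m = 2L, a = 1L, b = 1L, anchors = seq_len(m),
                         spread_scale = 1, threshold = 0.5) {
  if (m < 2) abort("m must be >= 2")
  if (a < 0 || b < 0 || a + b < 1) abort("need a, b >= 0 and a + b >= 1")
  if (threshold <= 0 || threshold >= 1) abort("threshold must lie in (0, 1)")
  structure(list(m = m, a = a, b = b, anchors = anchors,
                 spread_scale = spread_scale, threshold = threshold),
            class = "fuzzy_config")
}
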