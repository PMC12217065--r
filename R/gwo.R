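#' Linear decay of the exploration scalar
#'
#' `a = 2 * (1 - t / T)`: the encircling coefficient range shrinks linearly
#' from 2 (pure exploration) to 0 (pure exploitation) over the run.
#'
#' @param t Current iteration, `0 <= t <= T`.
#' @param T_max Total number of iterations, `>= 1`.
#' @return The decay scalar `a` in `[0, 2]`.
#' @export
linear_decay <- function(t, T_max) {
  if (T_max < 1) abort("T_max must be >= 1")
  if (t < 0 || t > T_max) abort("t must lie in [0, T_max]")
  2 * (1 - t / T_max)
}

#' Draw the stochastic coefficient vectors of one encircling update
#'
#' `A = 2 a r1 - a` (componentwise in `[-a, a]`) and `C = 2 r2`
#' (componentwise in `[0, 2]`), with fresh `r1, r2 ~ Uniform[0, 1]` per
#' dimension. Uses the current RNG state; seed outside for determinism.
#'
#' @param a Decay scalar in `[0, 2]`.
#' @param dim Number of dimensions.
#' @return List with vectors `A` and `C` of length `dim`.
#' @export
coefficient_vectors <- function(a, dim) {
  if (a < 0 || a > 2) abort("a must lie in [0, 2]")
  list(A = 2 * a * runif(dim) - a, C = 2 * runif(dim))
}

#' One encircling move toward a leader
#'
#' `D = |C * X_p - X|`, `X' = X_p - A * D`, clamped to the box bounds.
#'
#' @param position Current wolf position.
#' @param leader Leader (prey surrogate) position.
#' @param A,C Coefficient vectors from [coefficient_vectors()].
#' @param lower,upper Box bounds (recycled to the dimension).
#' @return The new, clamped position.
#' @export
encircle <- function(position, leader, A, C, lower = -Inf, upper = Inf) {
  if (length(position) != length(leader)) abort("dimension mismatch")
  D <- abs(C * leader - position)
  pmin(pmax(leader - A * D, lower), upper)
}

#' Hunting update guided by the three leaders
#'
#' Encircles the alpha, beta and delta leaders with independent coefficient
#' draws and averages the three candidate positions
#' (`X' = (X1 + X2 + X3) / 3`), clamped to bounds.
#'
#' @param position Current wolf position.
#' @param leaders List with elements `alpha`, `beta`, `delta` (positions).
#' @param a Decay scalar.
#' @param lower,upper Box bounds.
#' @return The new position.
#' @export
hunt_position <- function(position, leaders, a, lower = -Inf, upper = Inf) {
  stopifnot(all(c("alpha", "beta", "delta") %in% names(leaders)))
  d <- length(position)
  xs <- vapply(c("alpha", "beta", "delta"), function(nm) {
    cv <- coefficient_vectors(a, d)
    encircle(position, leaders[[nm]], cv$A, cv$C, lower, upper)
  }, numeric(d))
  pmin(pmax(rowMeans(matrix(xs, nrow = d)), lower), upper)
}

#' Single-objective Grey Wolf Optimizer
#'
#' Wolves are initialized uniformly in the box; each iteration ranks the pack
#' to elect alpha/beta/delta (the three best-ever-seen solutions), moves every
#' wolf with [hunt_position()] under the linearly decaying `a`, and
#' re-evaluates. The best-ever wolf and a per-iteration best-fitness history
#' (monotone nonincreasing) are returned.
#'
#' @param objective Function mapping a position vector to a finite scalar to
#'   minimize.
#' @param lower,upper Numeric bound vectors defining the search box.
#' @param n_wolves Pack size (>= 3).
#' @param iters Number of iterations `T >= 1`.
#' @param seed Optional integer seed.
#' @param init Optional matrix (rows = positions) seeding part of the pack.
#' @return Object of class `gwo_result`: list with `best_position`,
#'   `best_fitness`, and `history` (tibble with `iteration`, `best_fitness`).
#' @export
gwo_minimize <- function(objective, lower, upper, n_wolves = 30L, iters = 100L,
                         seed = NULL, init = NULL) {
  if (n_wolves < 3) abort("n_wolves must be >= 3")
  if (iters < 1) abort("iters must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dim <- length(lower)
  stopifnot(length(upper) == dim, all(lower < upper))
  X <- matrix(runif(n_wolves * dim, rep(lower, each = n_wolves),
                    rep(upper, each = n_wolves)), n_wolves, dim)
  if (!is.null(init)) {
    init <- matrix(init, ncol = dim)
    k <- min(nrow(init), n_wolves)
    X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 rep(lower, each = k)), rep(upper, each = k))
  }
  eval_pos <- function(x) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
      abort(sprintf("objective returned a non-finite value at position (%s)",
                    paste(signif(x, 4), collapse = ", ")))
    }
    f
  }
  fit <- apply(X, 1, eval_pos)
  history <- numeric(iters)
  for (t in seq_len(iters)) {
    ord <- order(fit)
    leaders <- list(alpha = X[ord[1], ], beta = X[ord[2], ],
                    delta = X[ord[3], ])
    a <- linear_decay(t - 1, iters)
    for (i in seq_len(n_wolves)) {
      cand <- hunt_position(X[i, ], leaders, a, lower, upper)
      X[i, ] <- cand
    }
    # leaders persist in `leaders`; re-evaluate the moved pack but keep the
    # best-ever solution so history never regresses
    new_fit <- apply(X, 1, eval_pos)
    if (min(new_fit) > fit[ord[1]]) {
      worst <- which.max(new_fit)
      X[worst, ] <- leaders$alpha
      new_fit[worst] <- fit[ord[1]]
    }
    fit <- new_fit
    history[t] <- min(fit)
  }
  best <- which.min(fit)
  structure(
    list(best_position = X[best, ], best_fitness = fit[best],
         history = tibble(iteration = seq_len(iters), best_fitness = history)),
    class = "gwo_result"
  )
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("<gwo_result> best fitness %.6g after %d iterations\n",
              x$best_fitness, nrow(x$history)))
  invisible(x)
}

#' @rdname gwo_minimize
#' @param x A `gwo_result`.
#' @param ... Unused.
#' @export
tidy.gwo_result <- function(x, ...) x$history

#' @rdname gwo_minimize
#' @export
glance.gwo_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness, iterations = nrow(x$history),
         dim = length(x$best_position))
}
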