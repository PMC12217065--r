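#' Pareto dominance (minimization)
#'
#' `f` dominates `g` iff `f <= g` in every objective and `f < g` in at least
#' one.
#'
#' @param f,g Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(f, g) {
  if (length(f) != length(g)) abort("objective vectors must have equal length")
  all(f <= g) && any(f < g)
}

#' Brute-force Pareto front of a set of objective vectors
#'
#' Quadratic scan retained as the transparent reference for archive tests.
#'
#' @param objectives Matrix, one row per candidate.
#' @return Logical vector marking non-dominated rows.
#' @export
pareto_mask <- function(objectives) {
  n <- nrow(objectives)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(objectives[j, ], objectives[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

new_archive <- function(n_obj, dim, capacity = Inf) {
  structure(
    list(positions = matrix(numeric(0), 0, dim),
         objectives = matrix(numeric(0), 0, n_obj),
         capacity = capacity),
    class = "pareto_archive"
  )
}

#' @export
print.pareto_archive <- function(x, ...) {
  cat(sprintf("<pareto_archive> %d member(s), %d objective(s)\n",
              nrow(x$objectives), ncol(x$objectives)))
  invisible(x)
}

#' Tidy a Pareto archive into a tibble
#'
#' @param x A `pareto_archive`.
#' @param ... Unused.
#' @return Tibble with `position_*` and `objective_*` columns, one row per
#'   archive member.
#' @export
tidy.pareto_archive <- function(x, ...) {
  pos <- as_tibble(x$positions, .name_repair = ~ paste0("position_", seq_along(.)))
  obj <- as_tibble(x$objectives, .name_repair = ~ paste0("objective_", seq_along(.)))
  dplyr::bind_cols(pos, obj)
}

#' Build a hypercube grid over the archive's objective space
#'
#' Cell boundaries span the observed objective ranges, inflated by `margin`
#' on each side, with `divisions` equal cells per objective.
#'
#' @param objectives Matrix of archive objective vectors (rows).
#' @param divisions Cells per objective (default 10).
#' @param margin Fractional inflation beyond the observed ranges (default
#'   0.1).
#' @return Object of class `hypercube_grid` with `lower`, `upper`,
#'   `divisions`.
#' @export
build_grid <- function(objectives, divisions = 10L, margin = 0.1) {
  lo <- apply(objectives, 2, min)
  hi <- apply(objectives, 2, max)
  span <- pmax(hi - lo, 1e-12)
  structure(
    list(lower = lo - margin * span, upper = hi + margin * span,
         divisions = divisions),
    class = "hypercube_grid"
  )
}

#' Map objective vectors to grid cell ids
#'
#' Every member maps to exactly one cell; values on the upper boundary fall
#' in the last cell.
#'
#' @param grid A `hypercube_grid`.
#' @param objectives Matrix of objective vectors (rows).
#' @return Integer vector of combined cell ids.
#' @export
grid_cells <- function(grid, objectives) {
  objectives <- matrix(objectives, ncol = length(grid$lower))
  k <- grid$divisions
  ids <- rep(0L, nrow(objectives))
  for (m in seq_along(grid$lower)) {
    width <- (grid$upper[m] - grid$lower[m]) / k
    bin <- floor((objectives[, m] - grid$lower[m]) / width)
    bin <- pmin(pmax(bin, 0), k - 1)
    ids <- ids * k + as.integer(bin)
  }
  ids + 1L
}

in_grid <- function(grid, f) {
  all(f >= grid$lower & f <= grid$upper)
}

#' Roulette-wheel cell selection probabilities
#'
#' Each occupied cell is weighted `c / N_i` where `N_i` is its occupancy, so
#' sparser cells are favoured; probabilities are the normalized weights.
#'
#' @param occupancy Positive integer vector of per-cell member counts.
#' @param c Constant larger than 1 (default 2).
#' @return Numeric vector of selection probabilities summing to 1.
#' @examples
#' cell_probabilities(c(1, 2, 4), c = 2) # 4/7, 2/7, 1/7
#' @export
cell_probabilities <- function(occupancy, c = 2) {
  if (any(occupancy <= 0)) abort("occupancies must be positive")
  if (c <= 1) abort("c must be larger than 1")
  w <- c / occupancy
  w / sum(w)
}

#' Draw one cell by the roulette-wheel rule
#'
#' Samples a cell index with probability proportional to `c / N_i`. Uses the
#' current RNG state.
#'
#' @inheritParams cell_probabilities
#' @return Integer cell index.
#' @export
roulette_cell <- function(occupancy, c = 2) {
  p <- cell_probabilities(occupancy, c)
  sample.int(length(occupancy), 1L, prob = p)
}

#' Elect alpha, beta and delta leaders from the archive
#'
#' A cell is drawn by [roulette_cell()] over the occupancies of the occupied
#' grid cells, and the alpha leader is drawn uniformly from it. Beta and
#' delta repeat the procedure over the remaining members, moving to other
#' cells as cells empty. With fewer than 3 archive members leaders repeat.
#'
#' @param archive A `pareto_archive` (nonempty).
#' @param grid A `hypercube_grid` covering the archive.
#' @param c Roulette constant (> 1, default 2).
#' @return List with positions `alpha`, `beta`, `delta` and the chosen
#'   member indices `idx`.
#' @export
select_leaders <- function(archive, grid, c = 2) {
  n <- nrow(archive$objectives)
  if (n == 0) abort("cannot elect leaders from an empty archive")
  cells <- grid_cells(grid, archive$objectives)
  draw_one <- function(avail) {
    occ <- table(cells[avail])
    cell_ids <- as.integer(names(occ))
    chosen_cell <- cell_ids[roulette_cell(as.vector(occ), c)]
    members <- avail[cells[avail] == chosen_cell]
    if (length(members) == 1) members else sample(members, 1L)
  }
  idx <- integer(3)
  avail <- seq_len(n)
  for (k in 1:3) {
    if (length(avail) == 0) avail <- seq_len(n)  # tiny archive: allow repeats
    idx[k] <- draw_one(avail)
    avail <- setdiff(avail, idx[k])
  }
  list(alpha = archive$positions[idx[1], ],
       beta = archive$positions[idx[2], ],
       delta = archive$positions[idx[3], ],
       idx = idx)
}

#' Insert a candidate into the non-dominated archive
#'
#' The candidate is rejected if any member dominates it; members it dominates
#' are removed. If insertion exceeds capacity, one member is evicted
#' uniformly at random from the most occupied grid cell. A candidate outside
#' the grid bounds triggers a grid rebuild covering it.
#'
#' @param archive A `pareto_archive`.
#' @param position Candidate position vector.
#' @param objectives Candidate objective vector.
#' @param grid A `hypercube_grid` or `NULL` to build one.
#' @param divisions,margin Grid parameters used on rebuilds.
#' @return List with the updated `archive` and `grid`.
#' @export
update_archive <- function(archive, position, objectives, grid = NULL,
                           divisions = 10L, margin = 0.1) {
  n <- nrow(archive$objectives)
  if (n > 0) {
    for (i in seq_len(n)) {
      if (dominates(archive$objectives[i, ], objectives) ||
          all(archive$objectives[i, ] == objectives)) {
        return(list(archive = archive, grid = grid))
      }
    }
    kill <- vapply(seq_len(n), function(i) {
      dominates(objectives, archive$objectives[i, ])
    }, logical(1))
    if (any(kill)) {
      archive$positions <- archive$positions[!kill, , drop = FALSE]
      archive$objectives <- archive$objectives[!kill, , drop = FALSE]
    }
  }
  archive$positions <- rbind(archive$positions, position)
  archive$objectives <- rbind(archive$objectives, objectives)
  if (is.null(grid) || !in_grid(grid, objectives)) {
    grid <- build_grid(archive$objectives, divisions, margin)
  }
  if (nrow(archive$objectives) > archive$capacity) {
    cells <- grid_cells(grid, archive$objectives)
    occ <- table(cells)
    crowded <- as.integer(names(occ)[occ == max(occ)])
    if (length(crowded) > 1) crowded <- sample(crowded, 1L)
    members <- which(cells == crowded)
    evict <- if (length(members) == 1) members else sample(members, 1L)
    archive$positions <- archive$positions[-evict, , drop = FALSE]
    archive$objectives <- archive$objectives[-evict, , drop = FALSE]
  }
  list(archive = archive, grid = grid)
}

#' Adaptive multi-objective Grey Wolf Optimizer
#'
#' The single-objective hunting mechanics of [gwo_minimize()] driven by a
#' non-dominated Pareto archive: each iteration evaluates the pack, inserts
#' every wolf into the archive, elects alpha/beta/delta by the
#' crowding-aware roulette rule, and moves all wolves under the decaying
#' exploration scalar.
#'
#' @param objectives Function mapping a position to a numeric vector of
#'   >= 2 objectives (minimized).
#' @param lower,upper Box bounds.
#' @param n_wolves Pack size (>= 3).
#' @param iters Iterations.
#' @param capacity Archive capacity (default 100).
#' @param divisions Grid divisions per objective (default 10).
#' @param c Roulette constant (default 2).
#' @param seed Optional integer seed.
#' @param init Optional matrix of initial positions.
#' @return Object of class `agwo_result`: list with the final
#'   `pareto_archive` (`archive`) and a `history` tibble (`iteration`,
#'   `archive_size`).
#' @export
agwo_minimize <- function(objectives, lower, upper, n_wolves = 30L,
                          iters = 100L, capacity = 100L, divisions = 10L,
                          c = 2, seed = NULL, init = NULL) {
  if (n_wolves < 3) abort("n_wolves must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  dim <- length(lower)
  stopifnot(length(upper) == dim, all(lower < upper))
  X <- matrix(runif(n_wolves * dim, rep(lower, each = n_wolves),
                    rep(upper, each = n_wolves)), n_wolves, dim)
  if (!is.null(init)) {
    init <- matrix(init, ncol = dim)
    k <- min(nrow(init), n_wolves)
    X[seq_len(k), ] <- init[seq_len(k), , drop = FALSE]
  }
  eval_pos <- function(x) {
    f <- objectives(x)
    if (!is.numeric(f) || length(f) < 2 || !all(is.finite(f))) {
      abort(sprintf("objectives returned a non-finite value at position (%s)",
                    paste(signif(x, 4), collapse = ", ")))
    }
    f
  }
  f0 <- eval_pos(X[1, ])
  archive <- new_archive(length(f0), dim, capacity)
  grid <- NULL
  insert_pack <- function(Fmat) {
    for (i in seq_len(nrow(Fmat))) {
      upd <- update_archive(archive, X[i, ], Fmat[i, ], grid, divisions)
      archive <<- upd$archive
      grid <<- upd$grid
    }
  }
  Fmat <- rbind(f0, t(apply(X[-1, , drop = FALSE], 1, eval_pos)))
  insert_pack(Fmat)
  history <- integer(iters)
  for (t in seq_len(iters)) {
    a <- linear_decay(t - 1, iters)
    leaders <- select_leaders(archive, grid, c)
    for (i in seq_len(n_wolves)) {
      X[i, ] <- hunt_position(X[i, ], leaders, a, lower, upper)
    }
    Fmat <- t(apply(X, 1, eval_pos))
    insert_pack(Fmat)
    history[t] <- nrow(archive$objectives)
  }
  structure(
    list(archive = archive,
         history = tibble(iteration = seq_len(iters), archive_size = history)),
    class = "agwo_result"
  )
}

#' @export
print.agwo_result <- function(x, ...) {
  cat(sprintf("<agwo_result> archive of %d member(s) after %d iterations\n",
              nrow(x$archive$objectives), nrow(x$history)))
  invisible(x)
}

#' @rdname agwo_minimize
#' @param x An `agwo_result`.
#' @param ... Unused.
#' @export
tidy.agwo_result <- function(x, ...) tidy(x$archive)

#' @rdname agwo_minimize
#' @export
glance.agwo_result <- function(x, ...) {
  tibble(archive_size = nrow(x$archive$objectives),
         iterations = nrow(x$history))
}

#' Pareto-front plot of an AGWO archive
#'
#' @param object An `agwo_result` with two objectives.
#' @param ... Unused.
#' @return A ggplot of the archived front in objective space.
#' @export
autoplot.agwo_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$objective_1, .data$objective_2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "objective 1", y = "objective 2") +
    ggplot2::theme_minimal()
}
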