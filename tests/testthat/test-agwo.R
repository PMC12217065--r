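test_that("Pareto dominance follows the strict definition", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("archive insertion respects dominance", {
  arch <- histowolf:::new_archive(2, 2)
  upd <- update_archive(arch, c(0, 0), c(1, 1))
  arch <- upd$archive
  # dominated candidate leaves the archive unchanged
  upd2 <- update_archive(arch, c(1, 1), c(2, 2), upd$grid)
  expect_equal(nrow(upd2$archive$objectives), 1)
  expect_equal(as.vector(upd2$archive$objectives[1, ]), c(1, 1))
  # a candidate dominating everything empties the rest
  upd3 <- update_archive(arch, c(2, 2), c(0.5, 0.5), upd$grid)
  expect_equal(nrow(upd3$archive$objectives), 1)
  expect_equal(as.vector(upd3$archive$objectives[1, ]), c(0.5, 0.5))
})

test_that("an unbounded archive equals the brute-force Pareto front", {
  set.seed(41)
  for (rep in 1:3) {
    F <- matrix(runif(200 * 2), 200, 2)
    arch <- histowolf:::new_archive(2, 2)
    grid <- NULL
    for (i in 1:200) {
      upd <- update_archive(arch, F[i, ], F[i, ], grid)
      arch <- upd$archive
      grid <- upd$grid
    }
    want <- F[pareto_mask(F), , drop = FALSE]
    got <- arch$objectives
    key <- function(m) sort(paste(signif(m[, 1], 12), signif(m[, 2], 12)))
    expect_identical(key(got), key(want))
  }
})

test_that("capacity overflow evicts from the most crowded cell", {
  set.seed(42)
  arch <- histowolf:::new_archive(2, 2, capacity = 5)
  grid <- NULL
  # a long nondominated front forces evictions
  for (i in 1:50) {
    t <- runif(1)
    f <- c(t, 1 - t)
    upd <- update_archive(arch, f, f, grid)
    arch <- upd$archive
    grid <- upd$grid
  }
  expect_lte(nrow(arch$objectives), 5)
  expect_true(all(pareto_mask(arch$objectives)))
})

test_that("roulette probabilities follow the crowding law", {
  expect_equal(cell_probabilities(c(1, 2, 4), c = 2), c(4, 2, 1) / 7)
  expect_equal(cell_probabilities(5, c = 3), 1)
  expect_error(cell_probabilities(c(0, 1), 2), "positive")
  expect_error(cell_probabilities(c(1, 2), 1), "larger than 1")

  set.seed(43)
  draws <- replicate(20000, roulette_cell(c(1, 2, 4), 2))
  freq <- tabulate(draws, 3) / 20000
  expect_lt(max(abs(freq - c(4, 2, 1) / 7)), 0.02)
})

test_that("leader election draws three distinct members when possible", {
  set.seed(44)
  pos <- matrix(runif(12), 6, 2)
  obj <- cbind(seq(0, 1, length.out = 6), seq(1, 0, length.out = 6))
  arch <- histowolf:::new_archive(2, 2)
  grid <- NULL
  for (i in 1:6) {
    upd <- update_archive(arch, pos[i, ], obj[i, ], grid)
    arch <- upd$archive
    grid <- upd$grid
  }
  for (r in 1:20) {
    lead <- select_leaders(arch, grid)
    expect_equal(length(unique(lead$idx)), 3)
  }
  single <- histowolf:::new_archive(2, 2)
  upd <- update_archive(single, c(0, 0), c(1, 2))
  lead <- select_leaders(upd$archive, upd$grid)
  expect_equal(lead$alpha, c(0, 0))
  expect_error(select_leaders(histowolf:::new_archive(2, 2),
                              upd$grid), "empty archive")
})

test_that("agwo solves a bi-objective convex problem with a clean archive", {
  biobj <- function(x) c(sum((x - c(1, 0))^2), sum((x + c(1, 0))^2))
  res <- agwo_minimize(biobj, c(-2, -2), c(2, 2), n_wolves = 20, iters = 60,
                       capacity = 100, seed = 45)
  expect_gte(nrow(res$archive$objectives), 20)
  expect_true(all(pareto_mask(res$archive$objectives)))
  expect_true(all(res$archive$positions >= -2 & res$archive$positions <= 2))

  res2 <- agwo_minimize(biobj, c(-2, -2), c(2, 2), n_wolves = 20, iters = 60,
                        capacity = 100, seed = 45)
  expect_identical(res$archive, res2$archive)
  expect_identical(res$history, res2$history)

  tiny <- agwo_minimize(biobj, c(-2, -2), c(2, 2), n_wolves = 3, iters = 1,
                        capacity = 1, seed = 46)
  expect_equal(nrow(tiny$archive$objectives), 1)
})

test_that("archive tidiers expose positions and objectives", {
  biobj <- function(x) c(x[1]^2, (x[1] - 1)^2)
  res <- agwo_minimize(biobj, -3, 3, n_wolves = 5, iters = 10, seed = 47)
  td <- tidy(res)
  expect_true(all(c("position_1", "objective_1", "objective_2") %in% names(td)))
  expect_equal(nrow(td), glance(res)$archive_size)
})
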