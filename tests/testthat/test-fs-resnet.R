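test_that("residual blocks honor the shortcut algebra", {
  set.seed(61)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))

  zero_block <- list(
    conv_a = list(W = matrix(0, 2, 9 * 2), b = numeric(2)),
    conv_b = list(W = matrix(0, 2, 9 * 2), b = numeric(2)),
    dense = FALSE
  )
  expect_equal(residual_forward(x, zero_block), pmax(x, 0))

  # a projection equal to the identity matches the identity shortcut
  rand_block <- list(
    conv_a = list(W = matrix(rnorm(2 * 18, sd = 0.2), 2, 18), b = rnorm(2)),
    conv_b = list(W = matrix(rnorm(2 * 18, sd = 0.2), 2, 18), b = rnorm(2)),
    dense = FALSE
  )
  ident <- residual_forward(x, rand_block)
  proj <- residual_forward(x, c(rand_block, list(projection = diag(2))))
  expect_equal(proj, ident, tolerance = 1e-12)
})

test_that("a single 1x1 residual conv matches the hand formula", {
  set.seed(62)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  W <- matrix(rnorm(4), 2, 2)  # 1x1 kernel, 2 channels in/out
  block <- list(conv_a = list(W = W, b = c(0, 0)), conv_b = NULL)
  got <- residual_forward(x, block)
  want <- array(0, dim(x))
  for (i in 1:4) for (j in 1:4) {
    want[i, j, ] <- pmax(W %*% x[i, j, ] + x[i, j, ], 0)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("mismatched shapes without a projection are rejected", {
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  grow <- list(conv_a = list(W = matrix(0, 3, 9 * 2), b = numeric(3)),
               conv_b = NULL)
  expect_error(residual_forward(x, grow), "projection")
})

test_that("model building is shape-correct and seed-reproducible", {
  cfg <- network_config(side = 64, m = 2, seed = 5)
  m1 <- build_fs_resnet(cfg)
  m2 <- build_fs_resnet(cfg)
  expect_identical(m1$params, m2$params)
  expect_gt(m1$n_parameters, 0)

  E <- network_energies(m1, array(0, c(64, 64, 3)))
  expect_length(E, 2)
  expect_true(all(is.finite(E)))
  expect_error(network_energies(m1, array(0, c(32, 32, 3))), "64x64x3")
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(side = 16, filters = 3, seed = 6)
  model <- build_fs_resnet(cfg)
  set.seed(63)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- c(0, 1)
  loss_of <- function(m) {
    P <- class_distribution(histowolf:::forward_pass(m, x)$energies)
    -log(P[2])
  }
  fwd <- histowolf:::forward_pass(model, x, keep_cache = TRUE)
  P <- class_distribution(fwd$energies)
  g <- histowolf:::backward_pass(model, x, fwd, P - y)
  eps <- 1e-5
  for (nm in names(model$params)) {
    set.seed(64)
    for (pick in 1:2) {
      i <- sample(length(model$params[[nm]]), 1)
      up <- model
      up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- model
      dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      expect_equal(g[[nm]][i], (loss_of(up) - loss_of(dn)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("Gaussian memberships are fitted per class with a floored spread", {
  set.seed(65)
  acts <- rbind(matrix(rnorm(20, mean = 0), 10, 2),
                matrix(rnorm(20, mean = 6), 10, 2))
  labels <- rep(0:1, each = 10)
  W <- diag(2)
  ms <- fit_gaussian_memberships(acts, labels, W)
  expect_gt(abs(ms$mu[2] - ms$mu[1]), mean(ms$sigma))

  flat <- matrix(1, 6, 2)
  ms2 <- fit_gaussian_memberships(flat, rep(0:1, each = 3), W)
  expect_equal(ms2$sigma, c(1e-3, 1e-3))

  # membership degree peaks at 1 at its own mean
  expect_equal(histowolf:::membership_degree(ms$mu[1], ms$mu[1], ms$sigma[1]), 1)
  expect_error(fit_gaussian_memberships(acts[1:11, ], labels[1:11], W),
               "at least 2")
})

test_that("training honors the epoch, determinism and history contracts", {
  tiny <- make_tiny_set(8, 32, 1, seed = 66)
  splits <- split_dataset(tiny, seed = 66)
  cfg <- network_config(side = 32, filters = 4, epochs = 0, seed = 66)
  model <- build_fs_resnet(cfg)
  un <- train_fs_resnet(model, splits$train, splits$validation, cfg)
  expect_identical(un$params, model$params)
  expect_equal(nrow(un$history), 0)

  cfg2 <- network_config(side = 32, filters = 4, epochs = 3, batch_size = 8,
                         seed = 66)
  f1 <- train_fs_resnet(build_fs_resnet(cfg2), splits$train,
                        splits$validation, cfg2)
  f2 <- train_fs_resnet(build_fs_resnet(cfg2), splits$train,
                        splits$validation, cfg2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(c("train_loss", "val_accuracy") %in% names(f1$history)))
  expect_true(f1$trained)
  expect_equal(nrow(tidy(f1)), 3)
  expect_false(glance(model)$trained)
})

test_that("prediction reports scores, centroids and the tie contract", {
  tiny <- make_tiny_set(6, 32, 1, seed = 67)
  cfg <- network_config(side = 32, filters = 4, epochs = 2, batch_size = 8,
                        seed = 67)
  model <- build_fs_resnet(cfg)
  expect_error(predict(model, tiny), "untrained")

  splits <- split_dataset(tiny, seed = 67)
  fit <- train_fs_resnet(model, splits$train, splits$validation, cfg)
  pred <- predict(fit, tiny)
  expect_equal(nrow(pred), nrow(tiny))
  expect_equal(pred$id, tiny$id)
  expect_true(all(pred$label %in% 0:1))
  expect_equal(pred$p_benign + pred$p_malignant, rep(1, nrow(pred)),
               tolerance = 1e-12)
  expect_true(all(pred$v0 >= 1 & pred$v0 <= 2))

  # force the exact tie: zero head weights give P = (0.5, 0.5)
  tied <- fit
  tied$params$Wfc <- matrix(0, 2, 4)
  tied$params$bfc <- c(0, 0)
  tied$memberships <- NULL
  pt <- predict(tied, tiny[1, ])
  expect_equal(pt$label, 0L)
  expect_true(pt$uncertain)
  expect_equal(pt$v0, 1.5)
})

test_that("a confident sample's score approaches its class index", {
  fc <- fuzzy_config()
  P <- c(1e-9, 1 - 1e-9)
  expect_equal(window_centroid(P, 2, fc$a, fc$b), 2, tolerance = 1e-6)
})

test_that("membership grid tuning is deterministic and monotone in quality", {
  tiny <- make_tiny_set(8, 32, 1, seed = 68)
  splits <- split_dataset(tiny, seed = 68)
  cfg <- network_config(side = 32, filters = 4, epochs = 4, batch_size = 8,
                        seed = 68)
  fit <- train_fs_resnet(build_fs_resnet(cfg), splits$train,
                         splits$validation, cfg)

  one <- tune_memberships_grid(fit, splits$validation, spread_grid = 2,
                               threshold_grid = 0.4)
  expect_equal(one$fuzzy$spread_scale, 2)
  expect_equal(one$fuzzy$threshold, 0.4)

  t1 <- tune_memberships_grid(fit, splits$validation)
  t2 <- tune_memberships_grid(fit, splits$validation)
  expect_identical(t1$fuzzy, t2$fuzzy)
  expect_identical(t1$tuning_grid, t2$tuning_grid)
  # the tuned point attains the grid's best balanced accuracy
  expect_equal(
    t1$tuning_grid$balanced_accuracy[
      t1$tuning_grid$spread == t1$fuzzy$spread_scale &
        t1$tuning_grid$threshold == t1$fuzzy$threshold][1],
    max(t1$tuning_grid$balanced_accuracy)
  )
  expect_error(tune_memberships_grid(fit, splits$validation,
                                     spread_grid = numeric(0)), "nonempty")
})

test_that("the fitted defaults beat corrupted membership variants", {
  tiny <- make_tiny_set(10, 32, 1, seed = 69)
  splits <- split_dataset(tiny, seed = 69)
  cfg <- network_config(side = 32, filters = 4, epochs = 6, batch_size = 8,
                        seed = 69)
  fit <- train_fs_resnet(build_fs_resnet(cfg), splits$train,
                         splits$validation, cfg)
  good <- tune_memberships_grid(fit, splits$validation, spread_grid = 1,
                                threshold_grid = NULL)
  corrupted <- fit
  corrupted$memberships$mu <- rev(corrupted$memberships$mu) + 100
  bad <- tune_memberships_grid(corrupted, splits$validation, spread_grid = 1,
                               threshold_grid = NULL)
  expect_gte(max(good$tuning_grid$balanced_accuracy),
             max(bad$tuning_grid$balanced_accuracy))
})
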