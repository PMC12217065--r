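test_that("degenerate parameters give a uniform background", {
  params <- texture_class_params(0, 1)
  params$density <- 0
  params$noise <- 0
  set.seed(81)
  img <- generate_class_image(params, 48)
  for (ch in 1:3) {
    expect_equal(max(img[, , ch]) - min(img[, , ch]), 0)
  }
})

test_that("image generation is deterministic under a fixed seed", {
  params <- texture_class_params(1, 0.8)
  set.seed(82)
  a <- generate_class_image(params, 64)
  set.seed(82)
  b <- generate_class_image(params, 64)
  expect_identical(a, b)
})

test_that("denser parameters produce more blobs (component-count oracle)", {
  lo <- texture_class_params(0, 1)
  lo$noise <- 0
  hi <- texture_class_params(1, 1)
  hi$noise <- 0
  count_blobs <- function(img, bg) {
    mask <- abs(img[, , 1] - bg[1]) > 0.05
    max(EBImage::bwlabel(mask))
  }
  set.seed(83)
  n_lo <- mean(replicate(5, count_blobs(generate_class_image(lo, 96),
                                        lo$background)))
  n_hi <- mean(replicate(5, count_blobs(generate_class_image(hi, 96),
                                        hi$background)))
  expect_gt(n_hi, n_lo)
})

test_that("datasets are balanced, reproducible and manifest-backed", {
  d1 <- generate_dataset(6, 32, 0.5, seed = 84)
  expect_equal(nrow(d1), 12)
  expect_equal(as.vector(table(d1$label)), c(6, 6))
  d2 <- generate_dataset(6, 32, 0.5, seed = 84)
  expect_identical(d1, d2)

  out <- file.path(tempdir(), "synth_out")
  generate_dataset(2, 32, 1, seed = 85, dir = out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  reloaded <- load_labeled_images(file.path(out, "manifest.csv"))
  expect_equal(nrow(reloaded), 4)
  expect_equal(sort(unique(reloaded$label)), c(0L, 1L))

  expect_error(generate_dataset(6, 16), "side")
  expect_error(texture_class_params(0, 2), "separability")
})

test_that("separability 1 supports a near-perfect linear read-out", {
  data <- generate_dataset(30, 64, 1, seed = 86)
  feats <- extract_features(standardize_images(data, ref = FALSE, side = 64),
                            "haar", 3)
  x <- as.matrix(feats[setdiff(names(feats), c("id", "label"))])
  set.seed(86)
  tr <- unlist(lapply(0:1, function(cl) sample(which(feats$label == cl), 20)))
  te <- setdiff(seq_len(60), tr)
  fit <- suppressWarnings(glm(feats$label[tr] ~ ., family = binomial,
                              data = as.data.frame(scale(x[tr, ]))))
  pred <- suppressWarnings(predict(fit, newdata = as.data.frame(
    scale(x[te, ], center = colMeans(x[tr, ]), scale = apply(x[tr, ], 2, sd))),
    type = "response")) > 0.5
  expect_gte(mean(pred == (feats$label[te] == 1)), 0.95)
})

test_that("separability 0 yields no significant band-energy contrast", {
  pvals <- vapply(1:5, function(seed) {
    data <- generate_dataset(15, 64, 0, seed = seed)
    feats <- extract_features(standardize_images(data, ref = FALSE, side = 64),
                              "haar", 2)
    cols <- grep("_energy$", names(feats), value = TRUE)
    ps <- vapply(cols, function(cl) {
      t.test(feats[[cl]][feats$label == 0],
             feats[[cl]][feats$label == 1])$p.value
    }, numeric(1))
    min(p.adjust(ps, "bonferroni"))
  }, numeric(1))
  expect_gt(median(pvals), 0.01)
})

test_that("planted feature tables realize their statistical contract", {
  # effect 0: no feature correlates with the label
  top_r <- vapply(1:5, function(seed) {
    tab <- generate_feature_table(n = 500, d = 20, informative = 1:5,
                                  effect_size = 0, seed = seed)
    max(abs(cor(tab$features, tab$labels)))
  }, numeric(1))
  expect_true(all(top_r < 0.3))

  # effect 3: every informative feature out-correlates every noise feature
  tab <- generate_feature_table(n = 500, d = 20, informative = 1:5,
                                effect_size = 3, seed = 87)
  r <- abs(cor(tab$features, tab$labels))
  expect_gt(min(r[1:5]), max(r[6:20]))
  expect_equal(tab$truth_mask, seq_len(20) %in% 1:5)
  expect_equal(sum(tab$labels), 250)

  # a noiseless redundant copy correlates perfectly with its source
  tab2 <- generate_feature_table(
    n = 100, d = 5, informative = 1:2, effect_size = 2,
    redundant = list(copy1 = list(source = 1, sd = 0)), seed = 88)
  expect_equal(ncol(tab2$features), 6)
  expect_equal(cor(tab2$features[, "copy1"], tab2$features[, 1]), 1)
  expect_false(tab2$truth_mask[6])
})
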