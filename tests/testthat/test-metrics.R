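test_that("stratified splits partition the data with exact proportions", {
  data <- tibble::tibble(id = sprintf("s%03d", 1:100),
                         label = rep(0:1, each = 50))
  sp <- split_dataset(data, seed = 1)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 60L, validation = 20L, test = 20L))
  for (part in sp) {
    expect_equal(as.vector(table(part$label)),
                 rep(nrow(part) / 2, 2))
  }
  ids <- unlist(lapply(sp, function(x) x$id))
  expect_setequal(ids, data$id)
  expect_equal(length(ids), 100)

  sp2 <- split_dataset(data, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(data, seed = 2)
  expect_false(identical(sp$train$id, sp3$train$id))

  expect_error(split_dataset(data[c(1, 2, 51:99), ], seed = 1), "3 samples")
  expect_error(split_dataset(data, fractions = c(a = 0.5, b = 0.6), seed = 1),
               "sum to 1")
})

test_that("stratification deviates by at most one sample per class", {
  data <- tibble::tibble(id = as.character(1:83),
                         label = rep(c(0L, 1L), c(37, 46)))
  sp <- split_dataset(data, seed = 3)
  for (nm in names(sp)) {
    frac <- c(train = 0.6, validation = 0.2, test = 0.2)[[nm]]
    for (cl in 0:1) {
      want <- frac * sum(data$label == cl)
      expect_lte(abs(sum(sp[[nm]]$label == cl) - want), 1)
    }
  }
})

test_that("confusion counts match a hand tally and swap symmetry", {
  expect_equal(as.list(confusion(rep(c(1, 0), each = 10),
                                 rep(c(1, 0), each = 10))),
               list(tp = 10L, fp = 0L, tn = 10L, fn = 0L))

  labels <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0)
  preds <- c(1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1, 1, 0, 0, 0, 1, 1, 0, 0)
  cm <- confusion(labels, preds)
  # hand tally of the 20-sample fixture
  expect_equal(as.list(cm), list(tp = 6L, fp = 4L, tn = 6L, fn = 4L))
  inv <- confusion(labels, 1 - preds)
  expect_equal(inv$tp, cm$fn)
  expect_equal(inv$fn, cm$tp)
  expect_equal(inv$fp, cm$tn)
  expect_equal(inv$tn, cm$fp)
  expect_error(confusion(c(0, 1), c(1)), "equal length")
})

test_that("metrics agree with hand formulas over the exhaustive sweep", {
  for (tp in 0:5) for (fp in 0:5) for (tn in 0:5) for (fn in 0:5) {
    if (tp + fp + tn + fn == 0) {
      expect_error(classification_metrics(
        list(tp = 0, fp = 0, tn = 0, fn = 0)), "all-zero")
      next
    }
    m <- classification_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fp > 0) {
      expect_equal(m$precision, tp / (tp + fp))
    } else {
      expect_true(is.na(m$precision))
      expect_true("precision" %in% m$undefined[[1]])
    }
    if (tp + fn > 0) {
      expect_equal(m$recall, tp / (tp + fn))
    } else {
      expect_true(is.na(m$recall))
      expect_true("recall" %in% m$undefined[[1]])
    }
    if (!is.na(m$precision) && !is.na(m$recall) &&
        m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
    } else {
      expect_true(is.na(m$f1))
    }
  }
})

test_that("the worked confusion case gives 0.9 on all four metrics", {
  m <- classification_metrics(list(tp = 9, fp = 1, tn = 9, fn = 1))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$undefined[[1]], character(0))
})

test_that("rank AUC equals the pairwise oracle, ties included", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  set.seed(91)
  scores <- round(runif(150), 1)  # heavy ties
  labels <- rbinom(150, 1, 0.4)
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  # invariance under monotone transforms
  expect_equal(roc_auc(exp(3 * scores), labels), roc_auc(scores, labels))
  expect_error(roc_auc(scores, rep(1, 150)), "both classes")
})

test_that("rank AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(92)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(93)
  auc <- roc_auc(runif(1000), rbinom(1000, 1, 0.5))
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("model comparison gates its test on Shapiro-Wilk normality", {
  a <- c(0.8, 0.82, 0.85, 0.79, 0.81, 0.83)
  same <- compare_models(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(same$mean_diff, 0)

  set.seed(94)
  base <- runif(10, 0.7, 0.9)
  shifted <- compare_models(base + 1 + rnorm(10, sd = 0.002),
                            base + rnorm(10, sd = 0.002))
  expect_lt(shifted$p_value, 0.01)
  expect_equal(shifted$mean_diff, 1, tolerance = 0.01)

  const <- compare_models(a + 0.5, a)
  expect_equal(const$test, "sign (exact)")
  expect_match(const$flag, "constant")
})

test_that("the chosen test is consistent with the gate on random fixtures", {
  set.seed(95)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    a <- if (i %% 2 == 0) rnorm(n) else rexp(n)^2
    b <- a + rnorm(n, sd = 0.5)
    rep <- compare_models(a, b)
    if (rep$test == "paired t") {
      expect_gt(rep$shapiro_p, 0.05)
    } else if (rep$test == "wilcoxon signed-rank") {
      expect_lte(rep$shapiro_p, 0.05)
    }
  }
})
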