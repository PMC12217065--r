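#' Stratified train/validation/test split
#'
#' Partitions a labelled set into disjoint, exhaustive splits with class
#' proportions preserved within rounding; deterministic by seed.
#'
#' @param image_set Tibble with a `label` column.
#' @param fractions Named fractions summing to 1 (default 60/20/20).
#' @param seed Integer seed.
#' @return Named list of tibbles (`train`, `validation`, `test`).
#' @export
split_dataset <- function(image_set,
                          fractions = c(train = 0.6, validation = 0.2,
                                        test = 0.2),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    abort("fractions must be positive and sum to 1")
  }
  counts <- table(image_set$label)
  if (any(counts < 3)) abort("every class needs at least 3 samples to split")
  set.seed(seed)
  assign <- character(nrow(image_set))
  for (cl in names(counts)) {
    members <- sample(which(image_set$label == as.integer(cl)))
    k <- length(members)
    sizes <- floor(fractions * k)
    rem <- k - sum(sizes)
    if (rem > 0) {
      top <- order(fractions * k - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[top] <- sizes[top] + 1
    }
    bounds <- cumsum(sizes)
    assign[members[seq_len(bounds[1])]] <- names(fractions)[1]
    for (s in 2:length(fractions)) {
      if (sizes[s] > 0) {
        assign[members[(bounds[s - 1] + 1):bounds[s]]] <- names(fractions)[s]
      }
    }
  }
  lapply(setNames(nm = names(fractions)), function(nm) {
    image_set[assign == nm, , drop = FALSE]
  })
}

#' Confusion counts for binary predictions
#'
#' The positive class is malignant (label 1).
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels, same length.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    abort("labels and predictions must have equal length")
  }
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1)) {
    abort("labels and predictions must be binary 0/1")
  }
  tibble(
    tp = sum(labels == 1 & predictions == 1),
    fp = sum(labels == 0 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fn = sum(labels == 1 & predictions == 0)
  )
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`, `accuracy = (TP+TN)/(TP+TN+FP+FN)`. Ratios with zero
#' denominators are reported as `NA` and listed in the `undefined` column.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble with `precision`, `recall`, `f1`, `accuracy` and
#'   an `undefined` list-column naming any undefined metrics.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) abort("all-zero confusion counts")
  undefined <- character(0)
  precision <- if (tp + fp == 0) {
    undefined <- c(undefined, "precision"); NA_real_
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    undefined <- c(undefined, "recall"); NA_real_
  } else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  tibble(
    precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / total,
    undefined = list(undefined)
  )
}

#' Area under the ROC curve by the rank statistic
#'
#' Tie-adjusted Mann-Whitney estimator: the probability that a random
#' malignant sample scores above a random benign one (ties count half).
#' Invariant to strictly monotone score transforms.
#'
#' @param scores Per-sample malignant scores/probabilities.
#' @param labels True 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Paired model comparison with a normality-gated test choice
#'
#' Shapiro-Wilk on the paired differences decides the test: paired t-test
#' when `p > 0.05` (normality not rejected), Wilcoxon signed-rank otherwise.
#' Constant differences make both degenerate; an exact sign test is reported
#' instead, flagged.
#'
#' @param a,b Paired per-fold metric vectors of equal length >= 5.
#' @return One-row tibble with `shapiro_p`, `test`, `statistic`, `p_value`,
#'   `mean_diff`, `conf_low`, `conf_high`, `flag`.
#' @export
compare_models <- function(a, b) {
  check_paired_numeric(a, b)
  if (length(a) < 5) abort("need at least 5 paired values")
  d <- a - b
  # near-zero spread (incl. floating-point residue of an exact shift) makes
  # both the Shapiro-Wilk gate and the t-test degenerate
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    if (all(d == 0)) {
      return(tibble(shapiro_p = NA_real_, test = "degenerate",
                    statistic = NA_real_, p_value = 1, mean_diff = 0,
                    conf_low = 0, conf_high = 0,
                    flag = "identical paired values"))
    }
    bt <- binom.test(sum(d > 0), length(d))
    return(tibble(shapiro_p = NA_real_, test = "sign (exact)",
                  statistic = as.numeric(bt$statistic),
                  p_value = bt$p.value, mean_diff = mean(d),
                  conf_low = NA_real_, conf_high = NA_real_,
                  flag = "constant differences; sign-test fallback"))
  }
  sw <- shapiro.test(d)
  tt <- t.test(a, b, paired = TRUE)
  if (sw$p.value > 0.05) {
    tibble(shapiro_p = sw$p.value, test = "paired t",
           statistic = as.numeric(tt$statistic), p_value = tt$p.value,
           mean_diff = mean(d),
           conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
           flag = NA_character_)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    tibble(shapiro_p = sw$p.value, test = "wilcoxon signed-rank",
           statistic = as.numeric(wt$statistic), p_value = wt$p.value,
           mean_diff = mean(d),
           conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
           flag = NA_character_)
  }
}

#' ROC curve plot
#'
#' Empirical ROC of malignant scores against binary labels.
#'
#' @param scores Per-sample malignant scores.
#' @param labels True 0/1 labels.
#' @return A ggplot of the ROC curve with the AUC in the subtitle.
#' @export
plot_roc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1) / sum(labels == 1)
  fpr <- cumsum(labels[ord] == 0) / sum(labels == 0)
  df <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc_auc(scores, labels))) +
    ggplot2::theme_minimal()
}
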