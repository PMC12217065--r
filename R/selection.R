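#' Decode a continuous position into a binary feature mask
#'
#' Coordinate `k` keeps feature `k` iff it exceeds `tau`. An all-zero mask is
#' coerced to keep the single largest coordinate so every mask selects at
#' least one feature.
#'
#' @param position Numeric vector in `[0, 1]^d`.
#' @param tau Threshold in `[0, 1)` (default 0.5).
#' @return Logical vector of length `d`.
#' @export
decode_feature_mask <- function(position, tau = 0.5) {
  if (length(position) < 1) abort("position must have at least one coordinate")
  mask <- position > tau
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

# Closed-form ridge classifier on +/-1 labels: the deliberately cheap, fixed
# reference model scored inside the feature-selection objective. Features are
# standardized on the training rows; lambda is fixed.
ridge_error <- function(x_tr, y_tr, x_va, y_va, lambda = 1.0) {
  mu <- colMeans(x_tr)
  sdv <- pmax(apply(x_tr, 2, sd), 1e-8)
  xt <- sweep(sweep(x_tr, 2, mu), 2, sdv, "/")
  xv <- sweep(sweep(x_va, 2, mu), 2, sdv, "/")
  yy <- ifelse(y_tr == 1, 1, -1)
  d <- ncol(xt)
  beta <- solve(crossprod(xt) + lambda * diag(d), crossprod(xt, yy))
  b0 <- mean(yy)
  pred <- as.vector(xv %*% beta) + b0 >= 0
  mean(pred != (y_va == 1))
}

stratified_split_idx <- function(labels, frac) {
  idx <- unlist(lapply(unique(labels), function(cl) {
    members <- which(labels == cl)
    sample(members, max(1L, round(frac * length(members))))
  }))
  sort(idx)
}

#' Bi-objective fitness of a feature mask
#'
#' Objective 1 is `1 - accuracy` of a fixed, cheap regularized linear
#' (ridge) classifier under seeded stratified 50/50 splits of the supplied
#' training portion, averaged over `n_splits` splits — the averaging keeps
#' the error estimate finely enough resolved that a lucky tiny mask cannot
#' tie a genuinely informative one; objective 2 is the selected fraction
#' `sum(mask) / d`.
#'
#' @param mask Logical feature mask keeping at least one feature.
#' @param features Numeric matrix (samples x d), training portion only.
#' @param labels Binary 0/1 labels.
#' @param seed Integer seed controlling the splits.
#' @param n_splits Number of averaged splits (default 10).
#' @return Numeric vector `c(error, fraction)`.
#' @export
feature_selection_objectives <- function(mask, features, labels, seed = 1L,
                                         n_splits = 10L) {
  if (!any(mask)) abort("mask must keep at least one feature")
  if (length(unique(labels)) < 2) abort("labels must contain both classes")
  x <- as.matrix(features)[, mask, drop = FALSE]
  errs <- vapply(seq_len(n_splits), function(s) {
    set.seed(seed + s - 1L)
    tr <- stratified_split_idx(labels, 0.5)
    va <- setdiff(seq_along(labels), tr)
    ridge_error(x[tr, , drop = FALSE], labels[tr],
                x[va, , drop = FALSE], labels[va])
  }, numeric(1))
  structure(c(error = mean(errs), fraction = sum(mask) / length(mask)),
            se = sd(errs) / sqrt(n_splits))
}

#' AGWO wrapper feature selection
#'
#' Runs the adaptive multi-objective Grey Wolf Optimizer over continuous
#' positions in `[0, 1]^d` decoded by [decode_feature_mask()], minimizing
#' the (validation error, selected fraction) pair of
#' [feature_selection_objectives()]. Because the search optimizes against a
#' fixed split ensemble, the apparent error of the best archive members is
#' optimistically biased (winner's curse); the final mask is therefore
#' chosen by re-evaluating every archive member on an independent, larger
#' split ensemble and applying the one-standard-error rule: among members
#' whose re-evaluated error lies within one standard error of the minimum,
#' the one with the fewest features wins.
#'
#' @param features Numeric matrix or feature tibble (non-feature columns
#'   `id`/`label` are dropped automatically).
#' @param labels Binary 0/1 labels (taken from a `label` column if present).
#' @param n_wolves,iters,capacity,divisions,c AGWO settings.
#' @param tau Mask decoding threshold.
#' @param seed Integer seed.
#' @return List with `mask` (logical), `selected` (indices), `objectives`
#'   (error/fraction of the chosen member), `archive` and the full
#'   `agwo_result` as `fit`.
#' @export
select_features <- function(features, labels = NULL, n_wolves = 24L,
                            iters = 40L, capacity = 100L, divisions = 10L,
                            c = 2, tau = 0.5, seed = 1L) {
  if (is.data.frame(features)) {
    if (is.null(labels) && "label" %in% names(features)) labels <- features$label
    features <- as.matrix(features[setdiff(names(features), c("id", "label"))])
  }
  if (is.null(labels)) abort("labels are required")
  d <- ncol(features)
  obj <- function(pos) {
    feature_selection_objectives(decode_feature_mask(pos, tau),
                                 features, labels, seed = seed)
  }
  fit <- agwo_minimize(obj, lower = rep(0, d), upper = rep(1, d),
                       n_wolves = n_wolves, iters = iters,
                       capacity = capacity, divisions = divisions, c = c,
                       seed = seed)
  # Local exploitation phase: greedy backward elimination from the best
  # archive member; every evaluated neighbour is offered to the archive so
  # the final choice is still an archive member.
  archive <- fit$archive
  grid <- NULL
  obj_of <- function(mask) feature_selection_objectives(mask, features,
                                                        labels, seed = seed)
  offer <- function(mask, o) {
    upd <- update_archive(archive, ifelse(mask, 0.75, 0.25), as.numeric(o),
                          grid, divisions)
    archive <<- upd$archive
    grid <<- upd$grid
  }
  errs0 <- archive$objectives[, 1]
  cur_mask <- decode_feature_mask(
    archive$positions[order(errs0, archive$objectives[, 2])[1], ], tau)
  cur <- obj_of(cur_mask)
  repeat {
    if (sum(cur_mask) <= 1) break
    cand <- lapply(which(cur_mask), function(j) {
      m2 <- cur_mask
      m2[j] <- FALSE
      o <- obj_of(m2)
      offer(m2, o)
      list(j = j, o = o)
    })
    cerr <- vapply(cand, function(x) x$o[[1]], numeric(1))
    k <- which.min(cerr)
    # Accept strictly improving drops always; accept equal-error drops only
    # while the error is positive — on a zero-error plateau the validation
    # signal is exhausted and further pruning is unsupported by evidence.
    if (cerr[k] < cur[[1]] || (cerr[k] == cur[[1]] && cur[[1]] > 0)) {
      cur_mask[cand[[k]]$j] <- FALSE
      cur <- cand[[k]]$o
    } else break
  }
  fit$archive <- archive
  scored <- lapply(seq_len(nrow(fit$archive$positions)), function(r) {
    feature_selection_objectives(
      decode_feature_mask(fit$archive$positions[r, ], tau), features,
      labels, seed = seed + 1000L, n_splits = 20L)
  })
  err <- vapply(scored, `[`, numeric(1), 1L)
  frac <- vapply(scored, `[`, numeric(1), 2L)
  se <- vapply(scored, attr, numeric(1), "se")
  cutoff <- min(err) + se[which.min(err)]
  best <- which(err <= cutoff)
  best <- best[order(frac[best], err[best])][1]
  mask <- decode_feature_mask(fit$archive$positions[best, ], tau)
  list(mask = mask, selected = which(mask),
       objectives = c(error = err[best], fraction = frac[best]),
       archive = fit$archive, fit = fit)
}

#' Decode a unit-cube position into training hyperparameters
#'
#' Learning rate log-uniform over `[1e-4, 1e-2]`, batch size in
#' `{32, 64, 128}` by thirds, weight decay log-uniform over `[1e-6, 1e-2]`.
#'
#' @param position Numeric vector of 3 coordinates in `[0, 1]`.
#' @return List with `learning_rate`, `batch_size`, `weight_decay`.
#' @examples
#' decode_hyperparams(c(0.5, 0.5, 0.5)) # lr 1e-3, batch 64, decay 1e-4
#' @export
decode_hyperparams <- function(position) {
  if (length(position) != 3) abort("position must have exactly 3 coordinates")
  p <- pmin(pmax(position, 0), 1)
  batch <- c(32L, 64L, 128L)[pmin(floor(p[2] * 3) + 1, 3)]
  list(
    learning_rate = 10^(-4 + 2 * p[1]),
    batch_size = batch,
    weight_decay = 10^(-6 + 4 * p[3])
  )
}

#' GWO hyperparameter tuning for the residual network
#'
#' Minimizes short-training validation error over the unit cube decoded by
#' [decode_hyperparams()] with the single-objective Grey Wolf core. The
#' default configuration is seeded into the initial pack, so the tuned
#' configuration is never worse than the default on the tuning objective.
#'
#' @param train,validation Standardized image-set tibbles.
#' @param config Base network configuration ([network_config()]).
#' @param n_wolves,iters GWO budget (desk-scale defaults).
#' @param tune_epochs Epochs per objective evaluation (short training).
#' @param seed Integer seed.
#' @return List with the tuned `learning_rate`, `batch_size`,
#'   `weight_decay`, the tuning `error`, and the `gwo_result` as `fit`.
#' @export
tune_hyperparams <- function(train, validation, config = network_config(),
                             n_wolves = 4L, iters = 3L, tune_epochs = 3L,
                             seed = 1L) {
  bpos <- switch(as.character(config$batch_size),
                 "32" = 1 / 6, "64" = 1 / 2, "128" = 5 / 6, 1 / 2)
  default_pos <- pmin(pmax(c(
    (log10(config$learning_rate) + 4) / 2,
    bpos,
    (log10(config$weight_decay) + 6) / 4
  ), 0), 1)
  obj <- function(pos) {
    hp <- decode_hyperparams(pos)
    cfg <- modifyList(config, c(hp, list(epochs = tune_epochs, seed = seed)))
    fit <- train_fs_resnet(build_fs_resnet(cfg), train, validation, cfg)
    1 - tail(fit$history$val_accuracy, 1)
  }
  res <- gwo_minimize(obj, lower = rep(0, 3), upper = rep(1, 3),
                      n_wolves = n_wolves, iters = iters, seed = seed,
                      init = matrix(default_pos, nrow = 1))
  c(decode_hyperparams(res$best_position),
    list(error = res$best_fitness, fit = res))
}
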