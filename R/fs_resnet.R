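#' Network configuration for the compact residual CNN
#'
#' The desk-scale architecture: one strided convolution (the stem), a
#' residual block of two further convolutions with optional dense cascaded
#' wiring (the second block convolution also receives the block input,
#' channel-concatenated), an identity shortcut with a post-addition
#' nonlinearity, global average pooling, and a fully connected fuzzy scoring
#' head emitting per-class energies. Adam is the optimizer throughout.
#'
#' @param side Input side length in pixels (default 224).
#' @param channels Input channels (default 3).
#' @param filters Convolution filters per layer (default 8).
#' @param kernel Kernel size (default 3).
#' @param stem_stride Stride of the stem convolution (default 2).
#' @param m Number of classes (default 2).
#' @param dense_wiring Dense cascaded wiring inside the residual block
#'   (default `TRUE`).
#' @param learning_rate,batch_size,weight_decay,epochs Adam training
#'   settings.
#' @param fuzzy_head Use the fuzzy error at the output layer (default
#'   `TRUE`); `FALSE` gives the plain softmax/cross-entropy baseline head.
#' @param seed Integer seed for initialization and batching.
#' @return A `network_config` list.
#' @export
network_config <- function(side = 224L, channels = 3L, filters = 8L,
                           kernel = 3L, stem_stride = 2L, m = 2L,
                           dense_wiring = TRUE, learning_rate = 1e-2,
                           batch_size = 32L, weight_decay = 1e-4,
                           epochs = 15L, fuzzy_head = TRUE, seed = 1L) {
  if (m < 2) abort("m must be >= 2")
  structure(
    list(side = as.integer(side), channels = as.integer(channels),
         filters = as.integer(filters), kernel = as.integer(kernel),
         stem_stride = as.integer(stem_stride), m = as.integer(m),
         dense_wiring = isTRUE(dense_wiring), learning_rate = learning_rate,
         batch_size = as.integer(batch_size), weight_decay = weight_decay,
         epochs = as.integer(epochs), fuzzy_head = isTRUE(fuzzy_head),
         seed = as.integer(seed)),
    class = "network_config"
  )
}

#' Build the fuzzy-scoring residual network
#'
#' Initializes all parameters (He-normal, seeded by `config$seed`) and
#' precomputes the convolution geometries for the configured input side.
#' Identical configuration and seed give identical initial parameters.
#'
#' @param config A [network_config()].
#' @param fuzzy A [fuzzy_config()]; defaults to a binary symmetric window
#'   `a = b = 1`.
#' @return Object of class `fs_resnet` with fields `config`, `fuzzy`,
#'   `params`, `geoms`, `n_parameters`, `trained`, `memberships`.
#' @export
build_fs_resnet <- function(config = network_config(),
                            fuzzy = fuzzy_config(m = config$m)) {
  stopifnot(inherits(config, "network_config"))
  if (fuzzy$m != config$m) abort("fuzzy config class count must match the network")
  k <- config$kernel
  Fch <- config$filters
  g1 <- conv_geom(config$side, config$side, config$channels, k,
                  stride = config$stem_stride, pad = 1L)
  ga <- conv_geom(g1$Ho, g1$Wo, Fch, k, stride = 1L, pad = 1L)
  cb_in <- if (config$dense_wiring) 2L * Fch else Fch
  gb <- conv_geom(g1$Ho, g1$Wo, cb_in, k, stride = 1L, pad = 1L)
  set.seed(config$seed)
  params <- list(
    W1 = he_init(Fch, k * k * config$channels), b1 = numeric(Fch),
    Wa = he_init(Fch, k * k * Fch), ba = numeric(Fch),
    Wb = he_init(Fch, k * k * cb_in), bb = numeric(Fch),
    Wfc = he_init(config$m, Fch), bfc = numeric(config$m)
  )
  structure(
    list(config = config, fuzzy = fuzzy, params = params,
         geoms = list(g1 = g1, ga = ga, gb = gb),
         n_parameters = sum(vapply(params, length, integer(1))),
         trained = FALSE, memberships = NULL),
    class = "fs_resnet"
  )
}

#' @export
print.fs_resnet <- function(x, ...) {
  cat(sprintf(
    "<fs_resnet> %dx%dx%d input, %d filters, %d classes, %d parameters (%s)\n",
    x$config$side, x$config$side, x$config$channels, x$config$filters,
    x$config$m, x$n_parameters, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Forward pass through a residual block
#'
#' Computes `y = sigma(F(x) + shortcut(x))`: the residual mapping `F` plus an
#' element-wise shortcut addition, with the second nonlinearity applied after
#' the addition. The shortcut is the identity when shapes match; otherwise a
#' linear (1x1) projection `W_s` must be supplied.
#'
#' @param x Activation array `H x W x C`.
#' @param block List with `conv_a = list(W, b)` (and optionally
#'   `conv_b = list(W, b)` for a two-layer residual mapping), logical
#'   `dense` (the second convolution also receives `x`,
#'   channel-concatenated), and optional `projection` (a `C_out x C` matrix
#'   applied pixel-wise as the shortcut).
#' @return Activation array after the post-addition nonlinearity.
#' @export
residual_forward <- function(x, block) {
  dims <- dim(x)
  C <- dims[3]
  infer_geom <- function(W, C_in) {
    k <- as.integer(round(sqrt(ncol(W) / C_in)))
    conv_geom(dims[1], dims[2], C_in, k, stride = 1L, pad = (k - 1L) %/% 2L)
  }
  fa <- conv_forward(x, block$conv_a$W, block$conv_a$b,
                     infer_geom(block$conv_a$W, C))
  if (is.null(block$conv_b)) {
    Fx <- fa$out
  } else {
    ra <- relu(fa$out)
    xb <- if (isTRUE(block$dense)) {
      array(c(x, ra), c(dims[1], dims[2], C + dim(ra)[3]))
    } else ra
    Fx <- conv_forward(xb, block$conv_b$W, block$conv_b$b,
                       infer_geom(block$conv_b$W, dim(xb)[3]))$out
  }
  if (is.null(block$projection)) {
    if (!all(dim(Fx) == dims)) {
      abort("residual output shape differs from the input; supply a projection shortcut (W_s)")
    }
    sc <- x
  } else {
    px <- matrix(x, ncol = C) %*% t(block$projection)
    sc <- array(px, dim(Fx))
  }
  relu(Fx + sc)
}

# Full forward pass; returns energies, pooled penultimate activations and
# (optionally) the caches the backward pass needs.
forward_pass <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  g <- model$geoms
  c1 <- conv_forward(x, p$W1, p$b1, g$g1)
  r1 <- relu(c1$out)
  ca <- conv_forward(r1, p$Wa, p$ba, g$ga)
  ra <- relu(ca$out)
  xb <- if (model$config$dense_wiring) {
    array(c(r1, ra), c(dim(r1)[1], dim(r1)[2], 2L * dim(r1)[3]))
  } else ra
  cb <- conv_forward(xb, p$Wb, p$bb, g$gb)
  s <- cb$out + r1
  y <- relu(s)
  z <- apply(y, 3, mean)
  logits <- as.vector(p$Wfc %*% z + p$bfc)
  out <- list(logits = logits, energies = -logits, z = z)
  if (keep_cache) {
    out$cache <- list(c1 = c1, r1 = r1, ca = ca, ra = ra, xb = xb, cb = cb,
                      s = s, y = y)
  }
  out
}

backward_pass <- function(model, x, fwd, dlogits) {
  p <- model$params
  g <- model$geoms
  cc <- fwd$cache
  Fch <- model$config$filters
  dWfc <- dlogits %*% t(fwd$z)
  dbfc <- dlogits
  dz <- as.vector(crossprod(p$Wfc, dlogits))
  spatial <- prod(dim(cc$y)[1:2])
  dy <- array(rep(dz / spatial, each = spatial), dim(cc$y))
  ds <- dy * (cc$s > 0)
  bb_ <- conv_backward(ds, p$Wb, cc$cb$cols, g$gb)
  dr1 <- ds  # identity shortcut path
  if (model$config$dense_wiring) {
    dr1 <- dr1 + bb_$dx[, , seq_len(Fch), drop = FALSE]
    dra <- bb_$dx[, , Fch + seq_len(Fch), drop = FALSE]
  } else {
    dra <- bb_$dx
  }
  dca <- dra * (cc$ca$out > 0)
  ba_ <- conv_backward(dca, p$Wa, cc$ca$cols, g$ga)
  dr1 <- dr1 + ba_$dx
  dc1 <- dr1 * (cc$c1$out > 0)
  b1_ <- conv_backward(dc1, p$W1, cc$c1$cols, g$g1)
  list(W1 = b1_$dW, b1 = b1_$db, Wa = ba_$dW, ba = ba_$db,
       Wb = bb_$dW, bb = bb_$db, Wfc = dWfc, bfc = dbfc)
}

#' Per-class energies of one image
#'
#' Runs a forward pass and returns the output-stage energies `E` (negated
#' logits); finite for any finite input.
#'
#' @param model An `fs_resnet`.
#' @param image `side x side x channels` array.
#' @return Numeric vector of `m` energies.
#' @export
network_energies <- function(model, image) {
  stopifnot(inherits(model, "fs_resnet"))
  if (!all(dim(image) == c(model$config$side, model$config$side,
                           model$config$channels))) {
    abort(sprintf("image must be %dx%dx%d", model$config$side,
                  model$config$side, model$config$channels))
  }
  forward_pass(model, image)$energies
}

#' Fit Gaussian membership parameters from penultimate activations
#'
#' For each class the pooled penultimate activation of every training sample
#' is projected onto that class's output weight vector; the class's Gaussian
#' membership is centred at the mean of its own samples' projections with
#' spread equal to their standard deviation, floored at `1e-3`.
#'
#' @param activations `n x F` matrix of pooled penultimate activations.
#' @param labels Integer class labels (0-based binary or 1-based indices).
#' @param weights `m x F` output-layer weight matrix.
#' @return Tibble with columns `class` (1-based index), `mu`, `sigma`.
#' @export
fit_gaussian_memberships <- function(activations, labels, weights) {
  m <- nrow(weights)
  cls <- if (min(labels) == 0) labels + 1L else as.integer(labels)
  counts <- table(factor(cls, levels = seq_len(m)))
  if (any(counts < 2)) {
    abort("each class needs at least 2 samples to fit a membership")
  }
  proj <- activations %*% t(weights)
  tibble(
    class = seq_len(m),
    mu = vapply(seq_len(m), function(c) mean(proj[cls == c, c]), numeric(1)),
    sigma = vapply(seq_len(m), function(c) {
      max(sd(proj[cls == c, c]), 1e-3)
    }, numeric(1))
  )
}

membership_degree <- function(t, mu, sigma, scale = 1) {
  exp(-((t - mu)^2) / (2 * (sigma * scale)^2))
}

#' Train the fuzzy-scoring residual network
#'
#' Mini-batch Adam training in which the output-layer gradient uses the
#' fuzzy error (`epsilon~`, via the per-class redistributed probabilities)
#' in place of the plain softmax error when `config$fuzzy_head` is `TRUE`;
#' hidden layers backpropagate the substituted signal unchanged.
#' Cross-entropy on `P` is reported for monitoring. After the final epoch
#' the Gaussian membership parameters are fitted on the training
#' activations. Fully deterministic under a fixed seed.
#'
#' @param model An `fs_resnet` from [build_fs_resnet()].
#' @param train,validation Image-set tibbles (`id`, `label`, `image`) of
#'   standardized images; binary labels.
#' @param config Training configuration; defaults to the model's.
#' @return The trained model, with a `history` tibble (`epoch`,
#'   `train_loss`, `train_accuracy`, `val_loss`, `val_accuracy`) attached.
#' @export
train_fs_resnet <- function(model, train, validation, config = model$config) {
  stopifnot(inherits(model, "fs_resnet"))
  model$config <- config
  a <- model$fuzzy$a
  b <- model$fuzzy$b
  if (config$epochs == 0) {
    model$history <- tibble(epoch = integer(0), train_loss = numeric(0),
                            train_accuracy = numeric(0), val_loss = numeric(0),
                            val_accuracy = numeric(0))
    return(model)
  }
  n <- nrow(train)
  cls <- train$label + 1L
  set.seed(config$seed)
  opt <- adam_new(model$params)
  step <- 0L
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    correct <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1L, n)]
      grads <- NULL
      bl <- 0
      for (i in batch) {
        fwd <- forward_pass(model, train$image[[i]], keep_cache = TRUE)
        P <- class_distribution(fwd$energies)
        yv <- numeric(config$m)
        yv[cls[i]] <- 1
        # Fuzzy head: the impact term phi = P~_i - P_i of the modified error
        # modulates the backpropagated output error as a per-sample grade
        # 1 + phi. With class i at the window maximum phi <= 0, so confident
        # samples contribute a reduced update; borderline samples (mass
        # leaking to window neighbours) are graded up. phi = 0 (P~ = P)
        # recovers the plain softmax error exactly, and the zero-sum
        # structure of the output error is preserved.
        dlogits <- P - yv
        if (config$fuzzy_head) {
          phi <- fuzzy_redistribute(P, cls[i], a, b) - P[cls[i]]
          dlogits <- (1 + phi) * dlogits
        }
        gi <- backward_pass(model, train$image[[i]], fwd, dlogits)
        grads <- if (is.null(grads)) gi else {
          Map(`+`, grads, gi)
        }
        bl <- bl - log(max(P[cls[i]], 1e-12))
        correct <- correct + as.integer(which.max(P) == cls[i])
      }
      grads <- lapply(grads, `/`, length(batch))
      if (!all(vapply(grads, function(g) all(is.finite(g)), logical(1)))) {
        abort("NaN/Inf gradient encountered; the learning rate is likely too high")
      }
      step <- step + 1L
      upd <- adam_step(model$params, grads, opt, config$learning_rate, step,
                       weight_decay = config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      losses <- c(losses, bl / length(batch))
      if (!is.finite(tail(losses, 1))) {
        abort("NaN loss encountered; the learning rate is likely too high")
      }
    }
    val <- evaluate_loss(model, validation)
    hist[[ep]] <- tibble(epoch = ep, train_loss = mean(losses),
                         train_accuracy = correct / n,
                         val_loss = val$loss, val_accuracy = val$accuracy)
  }
  model$history <- dplyr::bind_rows(hist)
  acts <- t(vapply(train$image, function(im) forward_pass(model, im)$z,
                   numeric(model$config$filters)))
  model$memberships <- fit_gaussian_memberships(acts, train$label,
                                                model$params$Wfc)
  model$trained <- TRUE
  model
}

evaluate_loss <- function(model, image_set) {
  cls <- image_set$label + 1L
  loss <- 0
  correct <- 0L
  for (i in seq_len(nrow(image_set))) {
    P <- class_distribution(forward_pass(model, image_set$image[[i]])$energies)
    loss <- loss - log(max(P[cls[i]], 1e-12))
    correct <- correct + as.integer(which.max(P) == cls[i])
  }
  list(loss = loss / nrow(image_set), accuracy = correct / nrow(image_set))
}

# One forward pass per sample: class distribution P and the per-class
# projections of the pooled activation onto the output weight rows.
forward_states <- function(model, image_set) {
  n <- nrow(image_set)
  m <- model$config$m
  P <- matrix(0, n, m)
  proj <- matrix(0, n, m)
  for (i in seq_len(n)) {
    fwd <- forward_pass(model, image_set$image[[i]])
    P[i, ] <- class_distribution(fwd$energies)
    proj[i, ] <- as.vector(model$params$Wfc %*% fwd$z)
  }
  list(P = P, proj = proj)
}

# Membership-adjusted scores and thresholded labels from cached states.
score_states <- function(states, memberships, spread_scale, threshold, m) {
  n <- nrow(states$P)
  Q <- states$P
  if (!is.null(memberships)) {
    for (c in seq_len(m)) {
      Q[, c] <- Q[, c] * membership_degree(states$proj[, c],
                                           memberships$mu[c],
                                           memberships$sigma[c],
                                           spread_scale)
    }
  }
  tot <- rowSums(Q)
  bad <- tot <= 0
  tot[bad] <- 1
  Q <- Q / tot
  if (any(bad)) Q[bad, ] <- states$P[bad, , drop = FALSE]
  if (m == 2) {
    label <- as.integer(Q[, 2] > threshold + 1e-9)
    uncertain <- abs(Q[, 2] - threshold) <= 1e-9
  } else {
    label <- max.col(Q, ties.method = "first") - 1L
    uncertain <- apply(Q, 1, max) < threshold
  }
  list(Q = Q, label = label, uncertain = uncertain)
}

#' Grid-tune the membership spread and decision threshold
#'
#' Evaluates every (spread scaling, threshold) pair on the validation set
#' and keeps the one maximizing balanced accuracy; ties break toward the
#' larger spread, then the lower threshold — fully deterministic for a fixed
#' grid ordering. Forward passes are computed once and reused across the
#' grid.
#'
#' @param model A trained `fs_resnet`.
#' @param validation Image-set tibble containing both classes.
#' @param spread_grid Candidate spread scalings (default
#'   `c(0.5, 1, 2, 4)`).
#' @param threshold_grid Candidate thresholds; the default `NULL` derives
#'   them per spread from the validation scores themselves (midpoints
#'   between adjacent sorted unique scores, plus 0.5), so the search can
#'   always place the cut between the two classes however the scores are
#'   calibrated.
#' @return The model with its fuzzy config updated; the full grid table is
#'   attached as `model$tuning_grid`.
#' @export
tune_memberships_grid <- function(model, validation,
                                  spread_grid = c(0.5, 1, 2, 4),
                                  threshold_grid = NULL) {
  if (length(spread_grid) == 0 ||
      (!is.null(threshold_grid) && length(threshold_grid) == 0)) {
    abort("grid must be nonempty")
  }
  if (length(unique(validation$label)) < 2) {
    abort("validation set must contain both classes")
  }
  states <- forward_states(model, validation)
  rows <- list()
  for (spread in spread_grid) {
    sc0 <- score_states(states, model$memberships, spread, 0.5,
                        model$config$m)
    thr <- threshold_grid
    if (is.null(thr)) {
      s <- sort(unique(sc0$Q[, 2]))
      thr <- unique(pmin(pmax(
        c(0.5, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2),
        1e-6), 1 - 1e-6))
    }
    for (t in thr) {
      sc <- score_states(states, model$memberships, spread, t,
                         model$config$m)
      rows[[length(rows) + 1]] <- tibble(
        spread = spread, threshold = t,
        balanced_accuracy = balanced_accuracy(validation$label, sc$label)
      )
    }
  }
  grid <- dplyr::bind_rows(rows)
  best <- order(-grid$balanced_accuracy, -grid$spread, grid$threshold)[1]
  model$fuzzy$spread_scale <- grid$spread[best]
  model$fuzzy$threshold <- grid$threshold[best]
  model$tuning_grid <- grid
  model
}

balanced_accuracy <- function(labels, predictions) {
  mean(vapply(unique(labels), function(cl) {
    mean(predictions[labels == cl] == cl)
  }, numeric(1)))
}

#' Predict labels and fuzzy scores
#'
#' For each sample: the class distribution `P`, the membership-adjusted
#' score, the redistributed probability of the predicted class, the window
#' centroid `V0` (the continuous, decimal-valued class score), the
#' thresholded label and an `uncertain` flag for scores on the decision
#' boundary.
#'
#' @param object A trained `fs_resnet`.
#' @param image_set Image-set tibble (`id`, `image`; `label` optional).
#' @param ... Unused.
#' @return Tibble with columns `id`, `p_benign`, `p_malignant`, `score`
#'   (membership-adjusted malignant probability), `p_tilde`, `v0`, `label`,
#'   `uncertain`, in input order.
#' @export
predict.fs_resnet <- function(object, image_set, ...) {
  if (!object$trained) abort("model is untrained; call train_fs_resnet() first")
  fz <- object$fuzzy
  states <- forward_states(object, image_set)
  sc <- score_states(states, object$memberships, fz$spread_scale,
                     fz$threshold, fz$m)
  pred_class <- sc$label + 1L
  tibble(
    id = image_set$id,
    p_benign = states$P[, 1],
    p_malignant = states$P[, 2],
    score = sc$Q[, 2],
    p_tilde = vapply(seq_len(nrow(states$P)), function(i) {
      fuzzy_redistribute(states$P[i, ], pred_class[i], fz$a, fz$b)
    }, numeric(1)),
    v0 = vapply(seq_len(nrow(states$P)), function(i) {
      window_centroid(states$P[i, ], pred_class[i], fz$a, fz$b)
    }, numeric(1)),
    label = sc$label,
    uncertain = sc$uncertain
  )
}

#' @rdname train_fs_resnet
#' @param x An `fs_resnet`.
#' @param ... Unused.
#' @export
tidy.fs_resnet <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history")
  x$history
}

#' @rdname train_fs_resnet
#' @export
glance.fs_resnet <- function(x, ...) {
  tibble(
    n_parameters = x$n_parameters,
    filters = x$config$filters,
    classes = x$config$m,
    fuzzy_head = x$config$fuzzy_head,
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    val_accuracy = if (is.null(x$history) || nrow(x$history) == 0) NA_real_
                   else tail(x$history$val_accuracy, 1)
  )
}

#' Training-history plot
#'
#' @param object An `fs_resnet` with a training history.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and accuracy curves.
#' @export
autoplot.fs_resnet <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, -"epoch", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
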