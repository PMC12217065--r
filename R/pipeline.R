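#' Default pipeline configuration
#'
#' Nested configuration driving [run_pipeline()] and [run_ablation()]:
#' data source (synthetic generator spec or a manifest path), wavelet
#' settings, the redundancy-filter threshold, optimizer budgets, network
#' training settings and the split fractions. Any part can be overridden
#' via `...` (named nested lists are merged).
#'
#' @param ... Named overrides merged into the defaults, e.g.
#'   `data = list(separability = 0.5)`.
#' @return A nested `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    data = list(manifest = NULL, n_per_class = 100L, side = 64L,
                separability = 1),
    split = c(train = 0.6, validation = 0.2, test = 0.2),
    preprocess = list(reinhard = TRUE),
    wavelet = list(name = "haar", levels = 3L),
    scc = list(threshold = 0.95),
    selection = list(enabled = TRUE, n_wolves = 12L, iters = 15L,
                     capacity = 100L, tau = 0.5),
    tuning = list(enabled = FALSE, n_wolves = 4L, iters = 3L,
                  tune_epochs = 3L),
    network = list(filters = 8L, kernel = 3L, epochs = 15L,
                   learning_rate = 1e-2, batch_size = 32L,
                   weight_decay = 1e-4, fuzzy_head = TRUE,
                   tune_memberships = TRUE)
  )
  structure(modifyList(cfg, list(...)), class = "pipeline_config")
}

acquire_data <- function(cfg) {
  if (!is.null(cfg$data$manifest)) {
    load_labeled_images(cfg$data$manifest)
  } else {
    generate_dataset(cfg$data$n_per_class, cfg$data$side,
                     cfg$data$separability, seed = cfg$seed)
  }
}

network_config_from <- function(cfg) {
  network_config(
    side = cfg$data$side, filters = cfg$network$filters,
    kernel = cfg$network$kernel, epochs = cfg$network$epochs,
    learning_rate = cfg$network$learning_rate,
    batch_size = cfg$network$batch_size,
    weight_decay = cfg$network$weight_decay,
    fuzzy_head = cfg$network$fuzzy_head, seed = cfg$seed
  )
}

#' Run the full classification pipeline
#'
#' Preprocess (Reinhard + z-score) -> wavelet texture features ->
#' correlation redundancy filter -> AGWO feature selection -> optional GWO
#' hyperparameter tuning -> residual-network training with the fuzzy
#' scoring head -> evaluation on the held-out test split. When `out_dir` is
#' given, a metrics JSON, a prediction CSV, the selection archive, the
#' training history and a reproducibility manifest are written.
#'
#' @param config A [pipeline_config()] (or path to a YAML file encoding
#'   one).
#' @param out_dir Optional artifact directory.
#' @return Object of class `histowolf_pipeline`: list with `metrics`
#'   (one-row tibble incl. `roc_auc`), `predictions`, `model`, `selection`,
#'   `kept_columns`, `tuning`, and the resolved `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- resolve_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  data <- stage("data", acquire_data(cfg))
  splits <- stage("split", split_dataset(data, cfg$split, seed = cfg$seed))
  ref <- if (isTRUE(cfg$preprocess$reinhard)) {
    stage("reference", reference_color_stats(splits$train$image))
  } else FALSE
  splits <- stage("standardize", lapply(splits, standardize_images, ref = ref,
                                        side = cfg$data$side))
  feats <- stage("features", lapply(splits, extract_features,
                                    wavelet = cfg$wavelet$name,
                                    levels = cfg$wavelet$levels))
  fcols <- setdiff(names(feats$train), c("id", "label"))
  kept <- stage("scc_filter", suppressWarnings(correlation_redundancy_filter(
    as.matrix(feats$train[fcols]), cfg$scc$threshold
  )))
  kept_names <- fcols[kept]
  selection <- NULL
  if (isTRUE(cfg$selection$enabled)) {
    selection <- stage("feature_selection", select_features(
      as.matrix(feats$train[kept_names]), feats$train$label,
      n_wolves = cfg$selection$n_wolves, iters = cfg$selection$iters,
      capacity = cfg$selection$capacity, tau = cfg$selection$tau,
      seed = cfg$seed
    ))
  }
  net_cfg <- network_config_from(cfg)
  tuning <- NULL
  if (isTRUE(cfg$tuning$enabled)) {
    tuning <- stage("tuning", tune_hyperparams(
      splits$train, splits$validation, net_cfg,
      n_wolves = cfg$tuning$n_wolves, iters = cfg$tuning$iters,
      tune_epochs = cfg$tuning$tune_epochs, seed = cfg$seed
    ))
    net_cfg$learning_rate <- tuning$learning_rate
    net_cfg$batch_size <- tuning$batch_size
    net_cfg$weight_decay <- tuning$weight_decay
  }
  model <- stage("train", train_fs_resnet(
    build_fs_resnet(net_cfg), splits$train, splits$validation, net_cfg
  ))
  if (isTRUE(cfg$network$tune_memberships) && cfg$network$fuzzy_head) {
    model <- stage("membership_grid", tune_memberships_grid(
      model, splits$validation
    ))
  }
  predictions <- stage("evaluate", predict(model, splits$test))
  counts <- confusion(splits$test$label, predictions$label)
  metrics <- classification_metrics(counts)
  metrics$roc_auc <- roc_auc(predictions$score, splits$test$label)
  result <- structure(
    list(metrics = dplyr::bind_cols(counts, metrics),
         predictions = dplyr::bind_cols(
           predictions, tibble(true_label = splits$test$label)),
         model = model, selection = selection, kept_columns = kept_names,
         tuning = tuning, config = cfg),
    class = "histowolf_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

resolve_config <- function(config) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, unclass(config))
  }
  config
}

# Small deterministic content hash (FNV-1a over the serialized config text)
# for the reproducibility manifest.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- result$metrics
  m$undefined <- vapply(m$undefined, paste, character(1), collapse = ",")
  jsonlite::write_json(as.list(m), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(result$predictions, file.path(out_dir, "predictions.csv"))
  if (!is.null(result$model$history)) {
    readr::write_csv(result$model$history, file.path(out_dir, "history.csv"))
  }
  if (!is.null(result$selection)) {
    readr::write_csv(tidy(result$selection$archive),
                     file.path(out_dir, "selection_archive.csv"))
    writeLines(jsonlite::toJSON(result$selection$selected),
               file.path(out_dir, "selected_features.json"))
  }
  manifest <- list(
    seed = result$config$seed,
    config = unclass(result$config),
    config_hash = config_hash(result$config),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}

#' @export
print.histowolf_pipeline <- function(x, ...) {
  cat("<histowolf_pipeline>\n")
  print(x$metrics)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `histowolf_pipeline`.
#' @param ... Unused.
#' @export
glance.histowolf_pipeline <- function(x, ...) x$metrics

ablation_arms <- list(
  baseline = list(network = list(fuzzy_head = FALSE, tune_memberships = FALSE),
                  tuning = list(enabled = FALSE),
                  selection = list(enabled = FALSE)),
  fuzzy = list(network = list(fuzzy_head = TRUE),
               tuning = list(enabled = FALSE),
               selection = list(enabled = FALSE)),
  agwo = list(network = list(fuzzy_head = FALSE, tune_memberships = FALSE),
              tuning = list(enabled = TRUE),
              selection = list(enabled = TRUE)),
  full = list(network = list(fuzzy_head = TRUE),
              tuning = list(enabled = TRUE),
              selection = list(enabled = TRUE))
)

#' Four-arm ablation of the fuzzy head and AGWO tuning
#'
#' Arms: `baseline` (plain softmax/cross-entropy head, default
#' hyperparameters), `fuzzy` (fuzzy scoring head only), `agwo`
#' (hyperparameter tuning only) and `full` (both). All arms share the data,
#' splits and seeds, so test sample ids align exactly across arms; each arm
#' differs from the baseline only in its documented switches. Pairwise
#' significance against the baseline uses the Shapiro-Wilk-gated paired
#' test of [compare_models()].
#'
#' @param config A [pipeline_config()]; its `data` block defines the shared
#'   study conditions.
#' @param seeds Integer vector of replicate seeds (default `1:5`).
#' @return Object of class `ablation_report`: list with `results` (tibble:
#'   arm, seed, metrics) and `significance` (tibble of arm-vs-baseline
#'   comparisons on accuracy; requires >= 5 seeds).
#' @export
run_ablation <- function(config = pipeline_config(), seeds = 1:5) {
  cfg <- resolve_config(config)
  rows <- list()
  for (s in seeds) {
    for (arm in names(ablation_arms)) {
      arm_cfg <- modifyList(cfg, ablation_arms[[arm]])
      arm_cfg$seed <- as.integer(s)
      res <- run_pipeline(arm_cfg)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(arm = arm, seed = s,
               test_ids = paste(sort(res$predictions$id), collapse = ";")),
        res$metrics[setdiff(names(res$metrics), "undefined")]
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  significance <- NULL
  if (length(seeds) >= 5) {
    base_acc <- results$accuracy[results$arm == "baseline"][order(
      results$seed[results$arm == "baseline"])]
    significance <- dplyr::bind_rows(lapply(
      setdiff(names(ablation_arms), "baseline"), function(arm) {
        acc <- results$accuracy[results$arm == arm][order(
          results$seed[results$arm == arm])]
        dplyr::bind_cols(tibble(arm = arm), compare_models(acc, base_acc))
      }
    ))
  }
  structure(list(results = results, significance = significance,
                 config = cfg, seeds = seeds),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n")
  print(dplyr::summarise(dplyr::group_by(x$results, .data$arm),
                         mean_accuracy = mean(.data$accuracy),
                         mean_f1 = mean(.data$f1), .groups = "drop"))
  invisible(x)
}

#' @rdname run_ablation
#' @param x An `ablation_report`.
#' @param ... Unused.
#' @export
tidy.ablation_report <- function(x, ...) x$results

#' Exhaustive hyperparameter grid search with stratified k-fold CV
#'
#' Every (batch size, learning rate) pair is scored by mean fold validation
#' accuracy; ties break toward the lower learning rate, then the smaller
#' batch. The full grid table is returned alongside the winner.
#'
#' @param image_set Labelled training set.
#' @param batch_grid Batch sizes (default `c(32, 64, 128)`).
#' @param lr_grid Learning rates (default 3 points log-spaced over
#'   `[1e-4, 1e-2]`).
#' @param folds Number of stratified folds (default 5).
#' @param seed Integer seed.
#' @param train_fn Function `(learning_rate, batch_size, train, validation)
#'   -> validation accuracy`; defaults to a short residual-network
#'   training run.
#' @param epochs Epochs for the default `train_fn`.
#' @return List with `best` (named list `learning_rate`, `batch_size`) and
#'   `table` (tibble of all grid points with mean fold accuracy).
#' @export
grid_search <- function(image_set, batch_grid = c(32L, 64L, 128L),
                        lr_grid = 10^seq(-4, -2, length.out = 3),
                        folds = 5L, seed = 1L, train_fn = NULL,
                        epochs = 3L) {
  set.seed(seed)
  labels <- image_set$label
  fold_id <- integer(length(labels))
  for (cl in unique(labels)) {
    members <- sample(which(labels == cl))
    fold_id[members] <- rep_len(seq_len(folds), length(members))
  }
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold_id == f])) < 2) {
      abort(sprintf("fold %d contains a single class", f))
    }
  }
  if (is.null(train_fn)) {
    side <- dim(image_set$image[[1]])[1]
    train_fn <- function(learning_rate, batch_size, train, validation) {
      cfg <- network_config(side = side, epochs = epochs,
                            learning_rate = learning_rate,
                            batch_size = batch_size, seed = seed)
      fit <- train_fs_resnet(build_fs_resnet(cfg), train, validation, cfg)
      tail(fit$history$val_accuracy, 1)
    }
  }
  grid <- expand.grid(batch_size = batch_grid, learning_rate = lr_grid)
  acc <- vapply(seq_len(nrow(grid)), function(r) {
    mean(vapply(seq_len(folds), function(f) {
      train_fn(grid$learning_rate[r], grid$batch_size[r],
               image_set[fold_id != f, ], image_set[fold_id == f, ])
    }, numeric(1)))
  }, numeric(1))
  best <- order(-acc, grid$learning_rate, grid$batch_size)[1]
  list(
    best = list(learning_rate = grid$learning_rate[best],
                batch_size = grid$batch_size[best]),
    table = as_tibble(cbind(grid, mean_accuracy = acc))
  )
}
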