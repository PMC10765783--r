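#' Scaffold-based train/valid/test split
#'
#' Groups molecules by Bemis-Murcko scaffold so structural analogues never
#' span folds. Groups are sorted by size (descending, ties by first
#' occurrence) and assigned greedily to fill test, then validation, then
#' train to their target counts. Acyclic molecules share the empty scaffold
#' and therefore one group. `mode = "random"` ignores scaffolds and permutes
#' molecules into the folds.
#'
#' @param x List of [rmat_molecule] objects carrying scaffolds, or a
#'   character vector of scaffold keys (one per molecule).
#' @param fractions Named or positional fractions for train/valid/test;
#'   must sum to 1.
#' @param seed Seed for `mode = "random"`.
#' @param mode `"scaffold"` or `"random"`.
#' @return Character vector of fold labels (`"train"`, `"valid"`, `"test"`)
#'   with attributes `mode`, `seed` and `fractions`.
#' @export
scaffold_split <- function(x, fractions = c(train = 0.8, valid = 0.1, test = 0.1),
                           seed = 1L, mode = c("scaffold", "random")) {
  mode <- match.arg(mode)
  scaff <- if (is.character(x)) x else vapply(x, function(m) m$scaffold, "")
  n <- length(scaff)
  stopifnot(n >= 3L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  n_test <- round(fractions[[3L]] * n)
  n_valid <- round(fractions[[2L]] * n)
  fold <- rep("train", n)
  if (mode == "random") {
    ord <- with_seed(seed, sample.int(n))
    fold[ord[seq_len(n_test)]] <- "test"
    fold[ord[n_test + seq_len(n_valid)]] <- "valid"
  } else {
    groups <- split(seq_len(n), scaff)
    if (length(groups) < 3L) {
      stop("only ", length(groups), " distinct scaffolds for 3 folds; ",
           "consider mode = \"random\"")
    }
    first <- vapply(groups, min, 0L)
    sizes <- lengths(groups)
    groups <- groups[order(-sizes, first)]
    filled_test <- 0L
    filled_valid <- 0L
    for (g in groups) {
      if (filled_test + length(g) <= n_test) {
        fold[g] <- "test"
        filled_test <- filled_test + length(g)
      } else if (filled_valid + length(g) <= n_valid) {
        fold[g] <- "valid"
        filled_valid <- filled_valid + length(g)
      }                                   # else stays train
    }
  }
  structure(fold, mode = mode, seed = seed, fractions = fractions,
            scaffold = scaff)
}

#' Evaluation metrics
#'
#' @param y_true Observed labels (0/1 for `roc_auc`).
#' @param y_pred Predictions (scores for `roc_auc`).
#' @param metric `"rmse"`, `"mae"` or `"roc_auc"`.
#' @return The scalar metric.
#' @export
eval_metric <- function(y_true, y_pred, metric = c("rmse", "mae", "roc_auc")) {
  metric <- match.arg(metric)
  stopifnot(length(y_true) == length(y_pred))
  ok <- !is.na(y_true) & !is.na(y_pred)
  y_true <- y_true[ok]
  y_pred <- y_pred[ok]
  switch(metric,
    rmse = sqrt(mean((y_true - y_pred)^2)),
    mae = mean(abs(y_true - y_pred)),
    roc_auc = {
      if (length(unique(y_true)) < 2L) {
        stop("ROC AUC undefined: labels contain a single class")
      }
      as.numeric(pROC::auc(response = y_true, predictor = y_pred,
                           direction = "<", quiet = TRUE))
    })
}

#' Default fine-tuning protocol settings
#'
#' The only model hyperparameter searched is the learning rate, over a
#' 7-value grid; the best rate is chosen on the validation fold and the test
#' metric is reported as mean (sd) across split seeds.
#'
#' @param task `"regression"` or `"classification"`.
#' @param metric Metric name for [eval_metric()] (default follows the task).
#' @param lr_grid Learning-rate grid.
#' @param epochs,batch_size Training length per grid point.
#' @param split_seeds Seeds of the independent splits.
#' @param fractions Train/valid/test fractions.
#' @param split_mode `"scaffold"` or `"random"`.
#' @param init_seed Seed for model initialization.
#' @param warmup_frac Fraction of steps under linear learning-rate warmup.
#' @return List of class `rmat_experiment`.
#' @export
rmat_experiment <- function(task = c("regression", "classification"),
                            metric = NULL,
                            lr_grid = c(1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
                            epochs = 50L, batch_size = 16L,
                            split_seeds = 1:3,
                            fractions = c(train = 0.8, valid = 0.1, test = 0.1),
                            split_mode = c("scaffold", "random"),
                            init_seed = 1L, warmup_frac = 0.1) {
  task <- match.arg(task)
  if (is.null(metric)) metric <- if (task == "regression") "rmse" else "roc_auc"
  stopifnot(length(lr_grid) >= 1L, abs(sum(fractions) - 1) < 1e-8)
  structure(list(task = task, metric = metric, lr_grid = lr_grid,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 split_seeds = as.integer(split_seeds), fractions = fractions,
                 split_mode = match.arg(split_mode),
                 init_seed = as.integer(init_seed),
                 warmup_frac = warmup_frac),
            class = "rmat_experiment")
}

#' Plain supervised training of one model
#'
#' Adam with linear warmup then a constant rate; minibatch gradients are
#' averaged over molecules. Training aborts with `diverged = TRUE` if a
#' non-finite loss or gradient appears.
#'
#' @param model An `rmat_model`.
#' @param items Featurized items.
#' @param y Numeric vector or matrix of labels (NA = missing, masked in the
#'   loss).
#' @param lr Learning rate.
#' @param epochs,batch_size Training schedule.
#' @param seed Seed for shuffling (and dropout, if enabled).
#' @param warmup_frac Fraction of steps under warmup.
#' @return List with `model`, `history` (per-epoch mean loss), `diverged`.
#' @export
train_rmat <- function(model, items, y, lr, epochs, batch_size = 16L,
                       seed = 1L, warmup_frac = 0.1) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == length(items), ncol(y) == model$n_outputs)
  targets <- lapply(seq_len(nrow(y)), function(i) y[i, ])
  sgd_train(model, items, targets, supervised_loss_fn(model$task), lr, epochs,
            batch_size, seed, warmup_frac)
}

#' Fine-tune with the learning-rate-only protocol
#'
#' For every split seed: split the data (scaffold or random), z-standardize
#' regression labels on the train fold, train one model per learning rate in
#' the grid, select the rate with the best validation metric, and evaluate
#' that model once on the test fold. The test fold is never touched during
#' selection (the returned `audit` records every metric evaluation).
#'
#' @param cfg An [rmat_config()] describing the model.
#' @param data List with `items` (from [featurize_molecules()]), `y`
#'   (labels) and `scaffolds` (for scaffold mode).
#' @param exp_cfg An [rmat_experiment()].
#' @return List of class `rmat_finetune`: `results` data frame (one row per
#'   split seed: chosen lr, validation and test metric), `mean_test`,
#'   `sd_test`, `grid` (validation metric of every (seed, lr)), `models`
#'   (best model per seed) and `audit`.
#' @export
finetune <- function(cfg, data, exp_cfg = rmat_experiment()) {
  stopifnot(inherits(cfg, "rmat_config"), inherits(exp_cfg, "rmat_experiment"))
  items <- data$items
  y <- as.matrix(data$y)
  n_out <- ncol(y)
  minimize <- exp_cfg$metric %in% c("rmse", "mae")
  audit <- list()
  grid_rows <- list()
  res_rows <- list()
  models <- list()
  for (s in exp_cfg$split_seeds) {
    fold <- if (exp_cfg$split_mode == "scaffold") {
      scaffold_split(data$scaffolds, exp_cfg$fractions, seed = s)
    } else {
      scaffold_split(rep("", length(items)), exp_cfg$fractions, seed = s,
                     mode = "random")
    }
    tr <- fold == "train"
    va <- fold == "valid"
    te <- fold == "test"
    # per-target label standardization, fit on the train fold only
    if (exp_cfg$task == "regression") {
      mu <- colMeans(y[tr, , drop = FALSE], na.rm = TRUE)
      sd_ <- apply(y[tr, , drop = FALSE], 2L, stats::sd, na.rm = TRUE)
      sd_[!is.finite(sd_) | sd_ == 0] <- 1
    } else {
      mu <- rep(0, n_out)
      sd_ <- rep(1, n_out)
    }
    y_std <- sweep(sweep(y, 2L, mu), 2L, sd_, `/`)
    evaluate <- function(model, idx, fold_name, lr) {
      audit[[length(audit) + 1L]] <<- list(fold = fold_name, lr = lr, seed = s)
      pred <- predict(model, items[idx])
      pred <- sweep(sweep(pred, 2L, sd_, `*`), 2L, mu, `+`)
      eval_metric(as.vector(y[idx, ]), as.vector(pred), exp_cfg$metric)
    }
    best <- NULL
    for (lr in exp_cfg$lr_grid) {
      model0 <- rmat_model(cfg, n_outputs = n_out, task = exp_cfg$task,
                           seed = exp_cfg$init_seed)
      fit <- train_rmat(model0, items[tr], y_std[tr, , drop = FALSE], lr,
                        exp_cfg$epochs, exp_cfg$batch_size,
                        seed = s * 1000L + 1L, exp_cfg$warmup_frac)
      if (fit$diverged) {
        grid_rows[[length(grid_rows) + 1L]] <-
          data.frame(seed = s, lr = lr, valid = NA_real_, diverged = TRUE)
        next
      }
      vm <- evaluate(fit$model, va, "valid", lr)
      grid_rows[[length(grid_rows) + 1L]] <-
        data.frame(seed = s, lr = lr, valid = vm, diverged = FALSE)
      if (is.null(best) || (minimize && vm < best$valid) ||
          (!minimize && vm > best$valid)) {
        best <- list(model = fit$model, lr = lr, valid = vm)
      }
    }
    if (is.null(best)) stop("every learning rate diverged for split seed ", s)
    # remember the train-fold label scaling so checkpointed models predict
    # in label units
    best$model$label_center <- mu
    best$model$label_scale <- sd_
    tm <- evaluate(best$model, te, "test", best$lr)
    res_rows[[length(res_rows) + 1L]] <-
      data.frame(seed = s, lr = best$lr, valid = best$valid, test = tm)
    models[[as.character(s)]] <- best$model
  }
  results <- do.call(rbind, res_rows)
  structure(list(results = results,
                 mean_test = mean(results$test), sd_test = stats::sd(results$test),
                 grid = do.call(rbind, grid_rows), models = models,
                 audit = audit, metric = exp_cfg$metric),
            class = "rmat_finetune")
}

#' @export
print.rmat_finetune <- function(x, ...) {
  cat("<rmat_finetune> ", nrow(x$results), " split(s), metric = ", x$metric,
      "\n", sep = "")
  print(x$results, row.names = FALSE)
  cat(sprintf("test %s: %.4f (%.4f)\n", x$metric, x$mean_test,
              if (is.na(x$sd_test)) 0 else x$sd_test))
  invisible(x)
}
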