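# Cross-validated training with early stopping, task metrics, and
# across-dataset model ranking summaries.

#' Task metric: AUROC (classification) or RMSE (regression)
#'
#' @param predictions numeric predictions (probabilities for
#'   classification).
#' @param targets observed targets, aligned with `predictions`.
#' @param task "classification" or "regression".
#' @return scalar metric.
#' @export
evaluate <- function(predictions, targets,
                     task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(length(predictions) == length(targets))
  if (task == "classification") {
    if (length(unique(targets)) < 2) {
      stop("AUROC undefined: targets contain a single class",
           call. = FALSE)
    }
    as.numeric(pROC::auc(pROC::roc(response = targets,
                                   predictor = predictions,
                                   quiet = TRUE, direction = "<",
                                   levels = c(0, 1))))
  } else {
    sqrt(mean((predictions - targets)^2))
  }
}

metric_higher_better <- function(task) task == "classification"

subset_by_ids <- function(records, graphs, ids) {
  idx <- match(ids, records$id)
  stopifnot(!anyNA(idx))
  list(idx = idx, targets = records$target[idx], graphs = graphs[idx])
}

make_minibatches <- function(idx, batch_size) {
  n <- length(idx)
  shuffled <- sample(idx)
  split(shuffled, ceiling(seq_len(n) / batch_size))
}

#' Train one cross-validation fold
#'
#' Trains for at most `config$epochs` epochs with Adam, monitoring the
#' validation metric; stops early after `config$patience` epochs without
#' improvement, restores the best-validation weights, and evaluates the
#' held-out test set.
#'
#' @param records a `molecule_dataset`.
#' @param graphs per-molecule prepared graphs, aligned with `records`
#'   (see [prepare_scheme_graphs()]).
#' @param scheme representation codes or "A+J"-style label.
#' @param split a `dataset_split` from [make_splits()].
#' @param fold fold index (1-based).
#' @param config a [model_config()].
#' @param seed seed for weight init and batch order; defaults to
#'   `split$seed + fold`.
#' @return a `fold_result`: trained model, metrics, per-molecule test
#'   predictions, training history.
#' @export
train_fold <- function(records, graphs, scheme, split, fold,
                       config = model_config(), seed = NULL) {
  if (is.character(scheme) && length(scheme) == 1) {
    scheme <- parse_scheme(scheme)
  }
  stopifnot(fold >= 1, fold <= split$n_folds)
  if (is.null(seed)) seed <- split$seed + fold
  fd <- split$train_folds[[fold]]
  tr <- subset_by_ids(records, graphs, fd$train)
  va <- subset_by_ids(records, graphs, fd$validation)
  te <- subset_by_ids(records, graphs, split$test_ids)
  task <- config$task
  y_tr <- tr$targets
  t_center <- 0; t_scale <- 1
  if (task == "regression") {
    t_center <- mean(y_tr)
    t_scale <- stats::sd(y_tr)
    if (!is.finite(t_scale) || t_scale == 0) t_scale <- 1
    y_tr <- (y_tr - t_center) / t_scale
  }
  fw <- vapply(scheme, function(r)
    ncol(tr$graphs[[1]][[r]]$node_features), integer(1))
  names(fw) <- scheme
  model <- new_model(scheme, fw, config, seed = seed)

  va_batches <- lapply(setNames(scheme, scheme), function(r)
    graph_batch(lapply(va$graphs, `[[`, r)))
  higher <- metric_higher_better(task)

  destandardize <- function(p) if (task == "regression")
    p * t_scale + t_center else p

  history <- with_seed(seed, {
    mb_idx <- make_minibatches(seq_along(tr$idx), config$batch_size)
    mbs <- lapply(mb_idx, function(ii) list(
      y = y_tr[ii],
      batches = lapply(setNames(scheme, scheme), function(r)
        graph_batch(lapply(tr$graphs[ii], `[[`, r)))))
    opt <- adam_state(model$params)
    best_metric <- if (higher) -Inf else Inf
    best_params <- model$params
    best_epoch <- 0L
    stall <- 0L
    losses <- numeric(0)
    val_metrics <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      epoch_loss <- 0
      for (mb in mbs) {
        lg <- model_loss_grads(model, mb$batches, mb$y, train = TRUE)
        if (!is.finite(lg$loss)) {
          stop("non-finite loss at epoch ", epoch, "; aborting fold",
               call. = FALSE)
        }
        st <- adam_step(model$params, lg$grads, opt, config$learning_rate)
        model$params <- st$params
        opt <- st$state
        epoch_loss <- epoch_loss + lg$loss * length(mb$y)
      }
      losses <- c(losses, epoch_loss / length(tr$idx))
      va_pred <- destandardize(
        model_forward_batch(model, va_batches)$pred)
      vm <- evaluate(va_pred, va$targets, task)
      val_metrics <- c(val_metrics, vm)
      improved <- if (higher) vm > best_metric + config$min_improvement
                  else vm < best_metric - config$min_improvement
      if (improved) {
        best_metric <- vm
        best_params <- model$params
        best_epoch <- epoch
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    list(losses = losses, val_metrics = val_metrics,
         best_metric = best_metric, best_params = best_params,
         best_epoch = best_epoch)
  })
  model$params <- history$best_params
  te_batches <- lapply(setNames(scheme, scheme), function(r)
    graph_batch(lapply(te$graphs, `[[`, r)))
  te_pred <- destandardize(model_forward_batch(model, te_batches)$pred)
  test_metric <- evaluate(te_pred, te$targets, task)
  structure(list(
    fold_index = fold,
    scheme = scheme,
    best_validation_metric = history$best_metric,
    best_epoch = history$best_epoch,
    epochs_run = length(history$losses),
    test_metric = test_metric,
    model = model,
    target_center = t_center, target_scale = t_scale,
    test_predictions = data.frame(id = split$test_ids,
                                  target = te$targets,
                                  prediction = te_pred),
    loss_history = history$losses,
    validation_history = history$val_metrics
  ), class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf(
    "<fold_result> scheme %s fold %d: best val %.4f (epoch %d/%d), test %.4f\n",
    scheme_label(x$scheme), x$fold_index, x$best_validation_metric,
    x$best_epoch, x$epochs_run, x$test_metric))
  invisible(x)
}

#' Train all (or selected) folds of a scheme
#'
#' @inheritParams train_fold
#' @param folds fold indices to train (default: all).
#' @return a `scheme_result`: list of `fold_result`s plus the mean and sd
#'   of per-fold test metrics (the reported performance).
#' @export
train_scheme <- function(records, graphs, scheme, split,
                         config = model_config(), folds = NULL) {
  if (is.character(scheme) && length(scheme) == 1) {
    scheme <- parse_scheme(scheme)
  }
  if (is.null(folds)) folds <- seq_len(split$n_folds)
  fold_results <- lapply(folds, function(k)
    train_fold(records, graphs, scheme, split, k, config))
  tm <- vapply(fold_results, `[[`, numeric(1), "test_metric")
  structure(list(scheme = scheme, folds = fold_results,
                 test_metric_mean = mean(tm),
                 test_metric_sd = if (length(tm) > 1) stats::sd(tm) else NA_real_,
                 task = config$task),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat(sprintf("<scheme_result> %s: test %s = %.4f (sd %.4f) over %d fold(s)\n",
              scheme_label(x$scheme),
              if (x$task == "classification") "AUROC" else "RMSE",
              x$test_metric_mean, x$test_metric_sd, length(x$folds)))
  invisible(x)
}

#' Across-dataset model ranking summary
#'
#' For each dataset, models are ranked (1 = best, ties share the mean
#' rank) and z-scored against the across-model mean and standard deviation
#' of that dataset's metric, with the sign flipped for lower-is-better
#' metrics so that larger is always better. Ranks and z-scores are then
#' averaged over datasets.
#'
#' @param metrics numeric matrix, models x datasets, with dimnames.
#' @param higher_is_better logical vector per dataset (recycled).
#' @param sd_type "sample" (n-1 denominator, default) or "population".
#' @return data.frame with `model`, `avg_rank`, `avg_zscore`.
#' @export
summarize_model_ranking <- function(metrics, higher_is_better = TRUE,
                                    sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(is.matrix(metrics))
  n_mod <- nrow(metrics)
  n_ds <- ncol(metrics)
  higher_is_better <- rep_len(higher_is_better, n_ds)
  ranks <- matrix(0, n_mod, n_ds)
  zs <- matrix(0, n_mod, n_ds)
  for (j in seq_len(n_ds)) {
    x <- metrics[, j]
    dir <- if (higher_is_better[j]) 1 else -1
    ranks[, j] <- rank(-dir * x, ties.method = "average")
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((n_mod - 1) / n_mod)
    zs[, j] <- if (!is.finite(s) || s == 0) 0 else dir * (x - mean(x)) / s
  }
  data.frame(model = rownames(metrics) %||% paste0("model", seq_len(n_mod)),
             avg_rank = rowMeans(ranks),
             avg_zscore = rowMeans(zs),
             row.names = NULL)
}
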