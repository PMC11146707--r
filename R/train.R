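# Training protocol: Adam, cross-entropy, early stopping on validation
# loss with best-weight restoration.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with initial learning rate
#' 1e-4, at most 100 epochs, stopping as soon as the validation loss has
#' not improved its best value for 10 successive epochs (no minimum
#' improvement delta), cross-entropy loss.
#'
#' @param learning_rate Positive learning rate.
#' @param max_epochs Maximum epochs.
#' @param early_stop_patience Epochs without strict validation-loss
#'   improvement before stopping; must be < `max_epochs`.
#' @param batch_size Minibatch size.
#' @param seed Integer seed covering shuffling (and any other training
#'   randomness).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 100L,
                         early_stop_patience = 10L, batch_size = 64L,
                         seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0",
                               call. = FALSE)
  if (early_stop_patience >= max_epochs)
    stop("`early_stop_patience` must be < `max_epochs`", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = "cross_entropy"),
            class = "train_config")
}

# Shared epoch loop. epoch_fn(epoch) -> list(train_loss, val_loss, ...);
# snapshot_fn() captures the current weights. Stops after `patience`
# epochs without strict improvement of the best validation loss and
# reports the best snapshot.
fit_loop <- function(max_epochs, patience, epoch_fn, snapshot_fn) {
  best <- Inf; best_snap <- NULL; best_epoch <- 0L; since <- 0L
  rows <- vector("list", max_epochs)
  last <- 0L
  for (e in seq_len(max_epochs)) {
    r <- epoch_fn(e)
    rows[[e]] <- as.data.frame(c(list(epoch = e), r))
    last <- e
    if (r$val_loss < best) {
      best <- r$val_loss; best_snap <- snapshot_fn()
      best_epoch <- e; since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) break
    }
  }
  list(history = do.call(rbind, rows[seq_len(last)]),
       best_snapshot = best_snap, best_epoch = best_epoch,
       stopped_epoch = last)
}

# --- data plumbing ----------------------------------------------------------

# Per-signal normalization: zero mean, unit variance.
normalize_signal <- function(x) {
  s <- sd(x)
  (x - mean(x)) / if (s > 0) s else 1
}

# Stack segments into a zero-padded (L_max, 1, B) array.
batch_array <- function(segs) {
  xs <- lapply(segs, function(s) normalize_signal(s$samples))
  L <- max(vapply(xs, length, integer(1)))
  arr <- array(0, c(L, 1L, length(xs)))
  for (b in seq_along(xs)) arr[seq_along(xs[[b]]), 1L, b] <- xs[[b]]
  arr
}

label_indices <- function(dataset, classes) {
  labs <- dataset_labels(dataset)
  idx <- match(labs, classes)
  if (anyNA(idx))
    stop("dataset labels not covered by model classes: ",
         paste(unique(labs[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

batch_starts <- function(n, bs) split(seq_len(n),
                                      ceiling(seq_len(n) / bs))

# --- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||%
                                              length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, st = st)
}

# --- training ---------------------------------------------------------------

#' Train a model
#'
#' Generic. The `msdc_model` method runs minibatch Adam with softmax
#' cross-entropy, evaluates the validation loss each epoch, stops early
#' when the best validation loss has not strictly improved for
#' `early_stop_patience` successive epochs, and restores the
#' best-validation-loss weights. Fully seeded: identical configuration and
#' seed give identical history and weights.
#'
#' @param model A model object.
#' @param train_set,val_set Disjoint `ecg_dataset`s with labels covered by
#'   the model's classes.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @param ... Passed to methods.
#' @return An object of class `msdc_fit`: list with the trained `model`,
#'   `history` (data.frame epoch / train_loss / val_loss / val_acc),
#'   `best_epoch`, `stopped_epoch`.
#' @export
train <- function(model, train_set, val_set, cfg = train_config(), ...)
  UseMethod("train")

#' @rdname train
#' @export
train.msdc_model <- function(model, train_set, val_set,
                             cfg = train_config(), verbose = FALSE, ...) {
  stopifnot(inherits(cfg, "train_config"))
  if (!length(train_set) || !length(val_set))
    stop("training and validation sets must be non-empty", call. = FALSE)
  classes <- model$spec$classes
  y_train <- label_indices(train_set, classes)
  y_val <- label_indices(val_set, classes)
  n <- length(train_set)
  env <- new.env(parent = emptyenv())
  env$model <- model
  env$opt <- adam_init(model$params)
  run <- with_seed(cfg$seed, {
    epoch_fn <- function(e) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (ix in batch_starts(n, cfg$batch_size)) {
        sel <- ord[ix]
        x <- batch_array(train_set[sel])
        fw <- model_forward(env$model, x, training = TRUE)
        env$model$state <- fw$state
        sx <- softmax_xent(fw$scores, y_train[sel])
        losses <- c(losses, sx$loss)
        grads <- model_backward(env$model, fw$caches, sx$dscores)
        up <- adam_step(env$model$params, grads, env$opt,
                        cfg$learning_rate)
        env$model$params <- up$params
        env$opt <- up$st
      }
      ev <- eval_loss(env$model, val_set, y_val, cfg$batch_size)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                        e, mean(losses), ev$loss, ev$acc))
      list(train_loss = mean(losses), val_loss = ev$loss,
           val_acc = ev$acc)
    }
    fit_loop(cfg$max_epochs, cfg$early_stop_patience, epoch_fn,
             snapshot_fn = function()
               list(params = env$model$params, state = env$model$state))
  })
  if (!is.null(run$best_snapshot)) {
    env$model$params <- run$best_snapshot$params
    env$model$state <- run$best_snapshot$state
  }
  structure(list(model = env$model, history = run$history,
                 best_epoch = run$best_epoch,
                 stopped_epoch = run$stopped_epoch, cfg = cfg),
            class = "msdc_fit")
}

eval_loss <- function(model, dataset, y, batch_size) {
  losses <- numeric(0); nhit <- 0L
  for (ix in batch_starts(length(dataset), batch_size)) {
    x <- batch_array(dataset[ix])
    fw <- model_forward(model, x, training = FALSE)
    sx <- softmax_xent(fw$scores, y[ix])
    losses <- c(losses, sx$loss * length(ix))
    nhit <- nhit + sum(max.col(fw$scores, ties.method = "first") ==
                         y[ix])
  }
  list(loss = sum(losses) / length(dataset),
       acc = nhit / length(dataset))
}

#' Scripted stub model for protocol tests
#'
#' A model whose per-epoch training and validation losses follow a given
#' script; its "weights" are just the epoch number. Used to test the
#' early-stopping rule in isolation.
#'
#' @param val_losses Numeric vector of validation losses per epoch.
#' @param train_losses Optional matching train losses.
#' @return Object of class `scripted_model`.
#' @export
scripted_model <- function(val_losses, train_losses = val_losses) {
  structure(list(val_losses = val_losses, train_losses = train_losses,
                 epoch = 0L), class = "scripted_model")
}

#' @rdname train
#' @export
train.scripted_model <- function(model, train_set = NULL, val_set = NULL,
                                 cfg = train_config(), ...) {
  env <- new.env(parent = emptyenv())
  env$model <- model
  run <- fit_loop(cfg$max_epochs, cfg$early_stop_patience,
                  epoch_fn = function(e) {
                    env$model$epoch <- e
                    list(train_loss = model$train_losses[e],
                         val_loss = model$val_losses[e])
                  },
                  snapshot_fn = function() env$model$epoch)
  env$model$epoch <- run$best_snapshot
  structure(list(model = env$model, history = run$history,
                 best_epoch = run$best_epoch,
                 stopped_epoch = run$stopped_epoch, cfg = cfg),
            class = "msdc_fit")
}

#' Predict class labels
#'
#' @param object A trained `msdc_model` (or `msdc_fit`).
#' @param dataset An `ecg_dataset`.
#' @param batch_size Batch size for the forward passes.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.msdc_model <- function(object, dataset, batch_size = 64L, ...) {
  classes <- object$spec$classes
  out <- character(length(dataset))
  for (ix in batch_starts(length(dataset), batch_size)) {
    fw <- model_forward(object, batch_array(dataset[ix]),
                        training = FALSE)
    out[ix] <- classes[max.col(fw$scores, ties.method = "first")]
  }
  out
}

#' @export
predict.msdc_fit <- function(object, dataset, ...)
  predict(object$model, dataset, ...)

#' Evaluate a trained model
#'
#' Runs the model over a test set, tallies the confusion counts for the
#' requested task, and computes the task metrics: sensitivity/specificity
#' for the binary AF task, per-class and macro F1 for the four-class
#' task. The report also carries the architecture analyzer summary of the
#' model's block.
#'
#' @param model A trained `msdc_model` or `msdc_fit`.
#' @param test_set An `ecg_dataset`.
#' @param task `"binary"` or `"four_class"`.
#' @param positive Positive-class label for the binary task.
#' @return List of class `msdc_eval_report` with `counts`, `metrics`,
#'   `task`, `n`, and `architecture`.
#' @export
evaluate <- function(model, test_set,
                     task = c("binary", "four_class"),
                     positive = "af") {
  task <- match.arg(task)
  if (inherits(model, "msdc_fit")) model <- model$model
  classes <- model$spec$classes
  if (task == "binary" && model$spec$n_classes != 2L)
    stop("binary task requires a 2-class model", call. = FALSE)
  if (task == "four_class" && model$spec$n_classes != 4L)
    stop("four-class task requires a 4-class model", call. = FALSE)
  truth <- dataset_labels(test_set)
  label_indices(test_set, classes)   # validates coverage
  pred <- predict(model, test_set)
  if (task == "binary") {
    counts <- tally_binary(truth, pred, positive = positive)
    metrics <- sensitivity_specificity(counts)
    acc <- (counts$n_tp + counts$n_tn) /
      (counts$n_tp + counts$n_tn + counts$n_fp + counts$n_fn)
    metrics <- c(metrics, accuracy = acc)
  } else {
    counts <- tally_multiclass(truth, pred, classes = classes)
    metrics <- f1_scores(counts)
    metrics <- c(metrics, accuracy = mean(truth == pred))
  }
  structure(list(task = task, n = length(test_set), counts = counts,
                 metrics = metrics,
                 architecture = architecture_report(
                   list(model$spec$block))),
            class = "msdc_eval_report")
}

#' Write an evaluation report as JSON
#'
#' @param report An `msdc_eval_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "msdc_eval_report"))
  counts <- if (inherits(report$counts, "confusion_counts"))
    unclass(report$counts)
  else as.data.frame(as.table(unclass(report$counts)))
  jsonlite::write_json(
    list(task = report$task, n = report$n, counts = counts,
         metrics = as.list(report$metrics),
         architecture = report$architecture),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.msdc_fit <- function(x, ...) {
  cat(sprintf(
    "msdc fit: stopped at epoch %d (best epoch %d, val loss %.4f)\n",
    x$stopped_epoch, x$best_epoch,
    x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
print.msdc_eval_report <- function(x, ...) {
  cat(sprintf("evaluation (%s task, n = %d):\n", x$task, x$n))
  print(round(x$metrics, 4))
  invisible(x)
}
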