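# Training: cross-entropy loss, SGD with decoupled weight decay,
# plateau-based learning-rate reduction, early stopping, run history.

#' Multi-class cross-entropy loss
#'
#' Mean over observations of `-sum_c y_oc * log(p_oc)`. Probabilities are
#' clipped away from zero at `eps` before the logarithm.
#'
#' @param prob `N x M` matrix of predicted class probabilities (rows sum
#'   to 1).
#' @param target `N x M` one-hot matrix (exactly one 1 per row), or a vector
#'   of labels matching `colnames(prob)`.
#' @param eps Probability floor (default 1e-12).
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(prob, target, eps = 1e-12) {
  prob <- as.matrix(prob)
  if (!is.matrix(target)) {
    if (is.null(colnames(prob)))
      abort("Label targets need `colnames(prob)`.", class = "ecsanet_invalid_input")
    target <- outer(as.character(target), colnames(prob), "==") * 1
  }
  if (!all(dim(target) == dim(prob)))
    abort("prob and target shapes differ.", class = "ecsanet_invalid_input")
  if (!all(target %in% c(0, 1)) || !all(rowSums(target) == 1))
    abort("target must be one-hot (exactly one 1 per row).",
          class = "ecsanet_invalid_input")
  mean(-rowSums(target * log(pmax(prob, eps))))
}

#' SGD optimizer state and update
#'
#' The update is `w <- w - lr * (g + weight_decay * w)` (weight decay
#' decoupled from the loss; plain gradient descent when decay is 0), with
#' optional classical momentum.
#'
#' @param weights Numeric weights (any shape).
#' @param lr Learning rate (> 0).
#' @param weight_decay Decoupled weight decay (>= 0).
#' @param momentum Momentum coefficient (default 0, plain SGD).
#' @return An `optimizer_state` list.
#' @export
optimizer_state <- function(weights, lr = 0.001, weight_decay = 0.01,
                            momentum = 0) {
  stopifnot(lr > 0, weight_decay >= 0, momentum >= 0)
  structure(list(weights = weights, lr = lr, weight_decay = weight_decay,
                 momentum = momentum, velocity = NULL, step = 0L),
            class = "optimizer_state")
}

#' @param state An [optimizer_state()].
#' @param gradient Gradient with the shape of `state$weights`.
#' @rdname optimizer_state
#' @export
sgd_step <- function(state, gradient) {
  if (length(gradient) != length(state$weights))
    abort("Gradient shape does not match weights.", class = "ecsanet_invalid_input")
  if (!all(is.finite(gradient)))
    abort("Non-finite gradient; state unchanged.", class = "ecsanet_nonfinite_gradient")
  g <- gradient + state$weight_decay * state$weights
  if (state$momentum > 0) {
    if (is.null(state$velocity)) state$velocity <- 0 * state$weights
    state$velocity <- state$momentum * state$velocity + g
    g <- state$velocity
  }
  state$weights <- state$weights - state$lr * g
  state$step <- state$step + 1L
  state
}

#' Training configuration
#'
#' Defaults mirror the published training setup: lr 0.001, weight decay
#' 0.01, batch size 16, at most 50 epochs, early-stopping patience 25,
#' plateau factor 0.1. The scheduler patience (epochs without validation
#' improvement before the learning rate is cut) defaults to 5.
#'
#' @param lr,weight_decay,momentum Optimizer settings.
#' @param batch_size,max_epochs Loop sizes.
#' @param early_stop_patience Epochs without improvement before halting.
#' @param lr_factor Multiplicative learning-rate reduction on plateau.
#' @param scheduler_patience Epochs without improvement before reduction.
#' @param min_improvement Validation loss must drop by at least this to count
#'   as an improvement.
#' @param seed Integer seed for shuffling and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(lr = 0.001, weight_decay = 0.01, momentum = 0,
                            batch_size = 16L, max_epochs = 50L,
                            early_stop_patience = 25L, lr_factor = 0.1,
                            scheduler_patience = 5L, min_improvement = 1e-8,
                            seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, scheduler_patience >= 1,
            lr_factor > 0, lr_factor < 1)
  structure(as.list(environment()), class = "training_config")
}

new_progress_state <- function(config) {
  list(lr = config$lr, lr_factor = config$lr_factor,
       scheduler_patience = config$scheduler_patience,
       early_stop_patience = config$early_stop_patience,
       min_improvement = config$min_improvement,
       best_val_loss = Inf, plateau_count = 0L,
       epochs_since_improvement = 0L)
}

#' Plateau-based learning-rate reduction
#'
#' Improvement means a validation loss strictly below the best seen so far by
#' at least `min_improvement`; it resets both the scheduler and the
#' early-stopping counters. After `scheduler_patience` consecutive
#' non-improving epochs the learning rate is multiplied by `lr_factor` and
#' the scheduler counter restarts. The learning rate never increases.
#'
#' @param state Progress state (from the training loop).
#' @param val_loss Finite validation loss of the epoch just finished.
#' @return Updated state.
#' @export
reduce_lr_on_plateau <- function(state, val_loss) {
  stopifnot(is.finite(val_loss))
  if (val_loss < state$best_val_loss - state$min_improvement) {
    state$best_val_loss <- val_loss
    state$plateau_count <- 0L
    state$epochs_since_improvement <- 0L
  } else {
    state$plateau_count <- state$plateau_count + 1L
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  }
  if (state$plateau_count >= state$scheduler_patience) {
    state$lr <- state$lr * state$lr_factor
    state$plateau_count <- 0L
  }
  state
}

#' Early-stopping predicate
#'
#' @param state Progress state.
#' @return `TRUE` iff the validation loss has not improved for at least
#'   `early_stop_patience` epochs.
#' @export
early_stopping <- function(state) {
  state$epochs_since_improvement >= state$early_stop_patience
}

# ---- streams ----------------------------------------------------------------

#' In-memory tensor stream
#'
#' @param x Array `side x side x 3 x N` of standardized images.
#' @param y Vector of N class labels.
#' @return A `tensor_stream`.
#' @export
tensor_stream <- function(x, y) {
  stopifnot(length(dim(x)) == 4L, dim(x)[4] == length(y))
  structure(list(x = x, y = as.character(y), n = length(y)),
            class = "tensor_stream")
}

#' Materialize one balanced oversampled epoch into memory
#'
#' Runs [get_item()] for every `(class, position)` of the balance plan and
#' stacks the results -- the oversampled balanced dataset that the training
#' loop then iterates. With augmentation enabled in `config` this realizes
#' the balance (AugMix) and transform (geometric) steps.
#'
#' @param plan A [plan_balance()] result with file lists.
#' @param config A [stream_config()].
#' @return A [tensor_stream()].
#' @export
materialize_balanced_epoch <- function(plan, config = stream_config()) {
  sched <- epoch_schedule(plan)
  side <- config$side
  x <- array(0, dim = c(side, side, 3L, nrow(sched)))
  for (r in seq_len(nrow(sched)))
    x[, , , r] <- get_item(plan, sched$class[r], sched$i[r], config)$x
  tensor_stream(x, sched$class)
}

#' Load an evaluation split into memory
#'
#' Preprocess + standardize only; never augmented.
#'
#' @param index A split `dataset_index`.
#' @param split `"val"` or `"test"`.
#' @param config A [stream_config()].
#' @return A [tensor_stream()].
#' @export
collect_eval_stream <- function(index, split, config = stream_config()) {
  tbl <- tibble::as_tibble(index)
  tbl <- tbl[tbl$split %in% split, ]
  if (nrow(tbl) == 0) abort("Empty split.", class = "ecsanet_invalid_input")
  side <- config$side
  x <- array(0, dim = c(side, side, 3L, nrow(tbl)))
  for (r in seq_len(nrow(tbl))) x[, , , r] <- eval_item(tbl$path[r], config)
  tensor_stream(x, as.character(tbl$label))
}

one_hot <- function(labels, classes) {
  m <- outer(as.character(labels), classes, "==") * 1
  colnames(m) <- classes
  m
}

eval_stream_loss <- function(model, stream, batch_size = 32L) {
  n <- stream$n
  classes <- model$class_labels
  probs <- matrix(0, n, length(classes))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    xb <- stream$x[, , , b, drop = FALSE]
    probs[b, ] <- predict(model, xb, type = "prob")
  }
  colnames(probs) <- classes
  pred <- classes[max.col(probs, ties.method = "first")]
  list(loss = cross_entropy(probs, stream$y),
       acc = mean(pred == stream$y), probs = probs, pred = pred)
}

# ---- training loop ----------------------------------------------------------

#' Train the model
#'
#' SGD with decoupled weight decay on mini-batches of the balanced training
#' stream; after every epoch the validation stream (never augmented) is
#' scored, the plateau scheduler and early-stopping counters advance, and the
#' best-validation-loss weights are retained. Fully reproducible under a
#' fixed seed.
#'
#' @param model An [assemble_ecsanet()] model.
#' @param streams List with `train` and `val` [tensor_stream()]s.
#' @param config A [training_config()].
#' @param quiet Suppress per-epoch messages.
#' @return A `training_run`: `model` (best weights), `final_model`,
#'   `history` tibble (epoch, train/val loss and accuracy, learning rate),
#'   `config`, `stopped_early`.
#' @export
train_ecsanet <- function(model, streams, config = training_config(),
                          quiet = TRUE) {
  stopifnot(inherits(streams$train, "tensor_stream"),
            inherits(streams$val, "tensor_stream"))
  classes <- model$class_labels
  prog <- new_progress_state(config)
  history <- list()
  best_model <- model
  stopped_early <- FALSE
  withr::local_seed(as.integer(config$seed))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(streams$train$n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0; tr_correct <- 0
    for (b in batches) {
      xb <- streams$train$x[, , , b, drop = FALSE]
      yb <- one_hot(streams$train$y[b], classes)
      fp <- nn_forward(model$net, xb, training = TRUE)
      model$net <- fp$layer
      logits <- t(fp$y)
      p <- softmax_rows(logits)
      loss <- cross_entropy(p, yb)
      if (!is.finite(loss))
        abort(sprintf("Diverging loss (%.3g) at epoch %d.", loss, epoch),
              class = "ecsanet_divergence")
      tr_loss <- tr_loss + loss * length(b)
      tr_correct <- tr_correct + sum(classes[max.col(p, ties.method = "first")] ==
                                       streams$train$y[b])
      dlogits <- t((p - yb) / length(b))
      bp <- nn_backward(model$net, dlogits, fp$cache)
      model$net <- bp$layer
      lr <- prog$lr; wd <- config$weight_decay; mu <- config$momentum
      model$net <- walk_params(model$net, function(par, g, v, path) {
        if (is.null(g)) return(list(param = par, velocity = v))
        g <- g + wd * par
        if (mu > 0) {
          if (is.null(v)) v <- 0 * par
          v <- mu * v + g
          g <- v
        }
        list(param = par - lr * g, velocity = v)
      })
    }
    ev <- eval_stream_loss(model, streams$val)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = tr_loss / streams$train$n,
      train_acc = tr_correct / streams$train$n,
      val_loss = ev$loss, val_acc = ev$acc, lr = prog$lr)
    if (!quiet)
      message(sprintf("epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f | lr %.2g",
                      epoch, tr_loss / streams$train$n, tr_correct / streams$train$n,
                      ev$loss, ev$acc, prog$lr))
    improved <- ev$loss < prog$best_val_loss - prog$min_improvement
    prog <- reduce_lr_on_plateau(prog, ev$loss)
    if (improved) best_model <- model
    if (early_stopping(prog)) { stopped_early <- TRUE; break }
  }
  structure(list(model = best_model, final_model = model,
                 history = dplyr::bind_rows(history), config = config,
                 stopped_early = stopped_early),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  h <- x$history
  cat(sprintf("<training_run> %d epoch(s)%s; best val loss %.4f (epoch %d)\n",
              nrow(h), if (x$stopped_early) ", stopped early" else "",
              min(h$val_loss), which.min(h$val_loss)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.training_run <- function(x, ...) x$history

#' @export
glance.training_run <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_val_loss = min(h$val_loss),
                 best_val_acc = h$val_acc[which.min(h$val_loss)],
                 final_train_acc = h$train_acc[nrow(h)],
                 final_lr = h$lr[nrow(h)], stopped_early = x$stopped_early)
}

#' Training-history curves
#'
#' @param object A `training_run`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy curves by epoch and split.
#' @export
autoplot.training_run <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "train_acc",
                                             "val_loss", "val_acc"),
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Write per-epoch history and run manifest
#'
#' @param run A `training_run`.
#' @param dir Output directory.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$history, file.path(dir, "history.csv"), row.names = FALSE)
  jsonlite::write_json(list(config = unclass(run$config),
                            stopped_early = run$stopped_early,
                            epochs = nrow(run$history)),
                       file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}
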