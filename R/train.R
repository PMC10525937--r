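# Training protocol: Adam on categorical cross-entropy, learning rate
# multiplied by 0.9 whenever the validation loss fails to improve for 10
# consecutive epochs, weights checkpointed at the minimum validation loss.

#' Training configuration
#'
#' @param initial_lr Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum epochs (protocol default 200).
#' @param plateau_factor Learning-rate multiplier on plateau, in (0, 1)
#'   (default 0.9).
#' @param plateau_patience Epochs without strict validation-loss improvement
#'   before the factor fires; the counter resets on improvement and after
#'   each firing (default 10).
#' @param seed Seed controlling weight updates' batch order.
#' @param verbose Print one line per epoch.
#' @return A `"train_config"` list.
#' @export
train_config <- function(initial_lr = 1e-4, batch_size = 32L,
                         max_epochs = 200L, plateau_factor = 0.9,
                         plateau_patience = 10L, seed = 1L,
                         verbose = FALSE) {
  if (plateau_factor <= 0 || plateau_factor >= 1)
    abort_("locomode_bad_argument", "plateau_factor must be in (0, 1)")
  if (plateau_patience < 1L)
    abort_("locomode_bad_argument", "plateau_patience must be >= 1")
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function() list(t = 0L, m = list(), v = list())

# One Adam step over the whole nested gradient structure. Parameters are
# addressed by "heads/<h>/<i>/<name>" or "trunk/<i>/<name>" keys.
adam_step <- function(model, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  upd <- function(layer, g, key) {
    for (nm in names(g)) {
      k <- paste0(key, "/", nm)
      gv <- g[[nm]]
      m <- opt$m[[k]]; v <- opt$v[[k]]
      if (is.null(m)) { m <- gv * 0; v <- gv * 0 }
      m <- beta1 * m + (1 - beta1) * gv
      v <- beta2 * v + (1 - beta2) * gv * gv
      opt$m[[k]] <<- m
      opt$v[[k]] <<- v
      layer$params[[nm]] <- layer$params[[nm]] -
        lr * (m / corr1) / (sqrt(v / corr2) + eps)
    }
    layer
  }
  for (h in names(model$heads))
    for (i in seq_along(model$heads[[h]]))
      model$heads[[h]][[i]] <- upd(model$heads[[h]][[i]],
                                   grads$heads[[h]][[i]],
                                   paste0("heads/", h, "/", i))
  for (i in seq_along(model$trunk))
    model$trunk[[i]] <- upd(model$trunk[[i]], grads$trunk[[i]],
                            paste0("trunk/", i))
  list(model = model, opt = opt)
}

# ---- plateau learning-rate schedule ---------------------------------------

#' Plateau learning-rate schedule
#'
#' Pure state machine behind the training protocol: `plateau_init()` starts
#' the schedule and `plateau_step()` consumes one epoch's validation loss.
#' An epoch strictly below the best seen loss resets the patience counter
#' and marks a checkpoint; once `patience` consecutive epochs fail to
#' improve, the learning rate is multiplied by `factor` and the counter
#' restarts (the factor can fire repeatedly).
#'
#' @param lr Initial learning rate.
#' @param factor Multiplier in (0, 1).
#' @param patience Epochs without improvement before the factor fires.
#' @param state A schedule state.
#' @param val_loss This epoch's validation loss.
#' @return `plateau_init()`: a state list. `plateau_step()`: the updated
#'   state, with `improved` set when this epoch is the new best.
#' @export
plateau_init <- function(lr, factor = 0.9, patience = 10L) {
  list(lr = lr, factor = factor, patience = as.integer(patience),
       best = Inf, wait = 0L, improved = FALSE, epoch = 0L, best_epoch = 0L)
}

#' @rdname plateau_init
#' @export
plateau_step <- function(state, val_loss) {
  state$epoch <- state$epoch + 1L
  if (val_loss < state$best) {
    state$best <- val_loss
    state$best_epoch <- state$epoch
    state$wait <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  state
}

# ---- data plumbing ---------------------------------------------------------

onehot_ <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  y
}

dataset_inputs <- function(data, head_names) as_net_inputs(data, head_names)

dataset_labels <- function(data) {
  if (inherits(data, "window_set")) return(data$labels)
  if (is.list(data)) {
    for (el in data) if (inherits(el, "window_set")) return(el$labels)
  }
  abort_("locomode_bad_argument", "cannot find labels in the data")
}

# Mean cross-entropy loss and accuracy in evaluation mode.
eval_loss_ <- function(model, inputs, Y, batch_size = 256L) {
  n <- nrow(Y)
  loss <- 0; correct <- 0
  for (at in seq.int(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    batch <- lapply(inputs, function(x) x[idx, , , drop = FALSE])
    p <- net_forward(model, batch, training = FALSE)$probs
    loss <- loss - sum(log(pmax(rowSums(p * Y[idx, , drop = FALSE]), 1e-12)))
    correct <- correct + sum(max.col(p) == max.col(Y[idx, , drop = FALSE]))
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a network
#'
#' Minimises categorical cross-entropy with Adam under the plateau
#' learning-rate schedule: whenever the validation loss fails to strictly
#' improve for `plateau_patience` consecutive epochs the learning rate is
#' multiplied by `plateau_factor` (the counter then restarts). The weights
#' achieving the lowest validation loss are kept.
#'
#' @param model A `"locomode_net"`.
#' @param train,val Labelled data: a `"window_set"` or a named list of
#'   window sets per head (multi-head models).
#' @param config A [train_config()]; defaults to the spec-carried learning
#'   rate and batch size when the model was built from an [arch_spec()].
#' @return An object of class `"locomode_fit"`: the checkpointed `model`,
#'   the per-epoch `history` (losses, accuracies, learning-rate trace),
#'   `best_epoch` and the config.
#' @export
train_model <- function(model, train, val, config = NULL) {
  if (is.null(config)) {
    sp <- model$spec
    config <- train_config(initial_lr = sp$learning_rate %||% 1e-4,
                           batch_size = sp$batch_size %||% 32L)
  }
  classes <- ACTIVITIES[seq_len(model$n_classes)]
  xtr <- dataset_inputs(train, names(model$heads))
  ytr <- dataset_labels(train)
  xva <- dataset_inputs(val, names(model$heads))
  yva <- dataset_labels(val)
  n <- dim(xtr[[1]])[1]
  if (is.null(n) || n == 0L)
    abort_("locomode_empty_input", "empty training set")
  Ytr <- onehot_(ytr, classes)
  Yva <- onehot_(yva, classes)
  opt <- adam_init()
  sched <- plateau_init(config$initial_lr, config$plateau_factor,
                        config$plateau_patience)
  best_model <- model
  hist <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- sched$lr
    ord <- local_seed(config$seed * 10007L + epoch, sample.int(n))
    tr_loss <- 0; tr_correct <- 0
    for (at in seq.int(1L, n, by = config$batch_size)) {
      idx <- ord[at:min(n, at + config$batch_size - 1L)]
      xb <- lapply(xtr, function(x) x[idx, , , drop = FALSE])
      yb <- Ytr[idx, , drop = FALSE]
      fw <- local_seed(config$seed * 97L + opt$t + 1L,
                       net_forward(model, xb, training = TRUE, cache = TRUE))
      model <- fw$model
      p <- fw$probs
      bl <- -sum(log(pmax(rowSums(p * yb), 1e-12)))
      if (!is.finite(bl))
        abort_("locomode_diverged",
               "non-finite training loss at epoch %d (lr %g)", epoch, lr)
      tr_loss <- tr_loss + bl
      tr_correct <- tr_correct + sum(max.col(p) == max.col(yb))
      dlogits <- (p - yb) / length(idx)
      grads <- net_backward(model, fw$caches, dlogits)
      st <- adam_step(model, grads, opt, lr)
      model <- st$model
      opt <- st$opt
    }
    va <- eval_loss_(model, xva, Yva)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                train_loss = tr_loss / n,
                                train_acc = tr_correct / n,
                                val_loss = va$loss, val_acc = va$acc)
    if (config$verbose)
      cat(sprintf("epoch %3d  lr %.2e  train %.4f/%.3f  val %.4f/%.3f\n",
                  epoch, lr, tr_loss / n, tr_correct / n, va$loss, va$acc))
    sched <- plateau_step(sched, va$loss)
    if (sched$improved) best_model <- model
  }
  structure(list(model = best_model, history = do.call(rbind, hist),
                 best_epoch = sched$best_epoch, best_val_loss = sched$best,
                 config = config),
            class = "locomode_fit")
}

#' @export
print.locomode_fit <- function(x, ...) {
  cat(sprintf("<locomode_fit> %s: %d epochs, best val loss %.4f at epoch %d\n",
              x$model$name, nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.locomode_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("Training of %s (%d epochs)\n", object$model$name, nrow(h)))
  cat(sprintf("  best val loss %.4f (epoch %d), final val acc %.4f\n",
              object$best_val_loss, object$best_epoch,
              h$val_acc[nrow(h)]))
  cat(sprintf("  learning rate %g -> %g\n", h$lr[1], h$lr[nrow(h)]))
  print(count_parameters(object$model))
  invisible(object)
}

#' @export
predict.locomode_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Plot training history
#'
#' Loss and accuracy traces for training and validation, with the
#' checkpointed epoch marked.
#'
#' @param x A `"locomode_fit"`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
#' @importFrom graphics abline legend lines par
plot.locomode_fit <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss)))
  lines(h$epoch, h$val_loss, lty = 2)
  abline(v = x$best_epoch, col = "grey")
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  plot(h$epoch, h$train_acc, type = "l", xlab = "epoch", ylab = "accuracy",
       ylim = c(0, 1))
  lines(h$epoch, h$val_acc, lty = 2)
  abline(v = x$best_epoch, col = "grey")
  invisible(x)
}

#' Write a training history as CSV
#' @param fit A `"locomode_fit"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
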