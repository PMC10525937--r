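# Model container: one or more per-modality heads (conv / recurrent stacks
# ending in a 2-D feature matrix) followed by a shared trunk (dense stack and
# softmax). Sequential single-input models are the one-head special case.

new_network <- function(heads, trunk, input_shapes, n_classes, name,
                        spec = NULL) {
  structure(list(heads = heads, trunk = trunk, input_shapes = input_shapes,
                 n_classes = as.integer(n_classes), name = name, spec = spec),
            class = "locomode_net")
}

#' @export
print.locomode_net <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("<locomode_net> %s: %d head(s), %d classes\n",
              x$name, length(x$heads), x$n_classes))
  for (h in names(x$heads)) {
    sh <- x$input_shapes[[h]]
    cat(sprintf("  head %-6s (%d x %d): %s\n", h, sh[1], sh[2],
                paste(vapply(x$heads[[h]], `[[`, "", "type"), collapse = " > ")))
  }
  cat(sprintf("  trunk: %s\n",
              paste(vapply(x$trunk, `[[`, "", "type"), collapse = " > ")))
  cat(sprintf("  parameters: %s trainable, %s non-trainable\n",
              format(pc$trainable, big.mark = ","),
              format(pc$non_trainable, big.mark = ",")))
  invisible(x)
}

# Full forward pass. `inputs` is a named list of (n, T, C) arrays keyed by
# head name (a bare array is accepted for one-head models). Returns class
# probabilities; with `cache = TRUE` also everything backward needs.
net_forward <- function(model, inputs, training = FALSE, cache = FALSE) {
  if (!is.list(inputs)) inputs <- setNames(list(inputs), names(model$heads))
  head_caches <- list()
  feats <- list()
  widths <- integer(0)
  for (h in names(model$heads)) {
    x <- inputs[[h]]
    if (is.null(x))
      abort_("locomode_bad_argument", "no input supplied for head '%s'", h)
    caches <- vector("list", length(model$heads[[h]]))
    for (i in seq_along(model$heads[[h]])) {
      st <- layer_forward(model$heads[[h]][[i]], x, training)
      x <- st$out
      model$heads[[h]][[i]] <- st$layer
      if (cache) caches[[i]] <- st$cache
    }
    feats[[h]] <- x
    widths[h] <- ncol(x)
    head_caches[[h]] <- caches
  }
  x <- do.call(cbind, unname(feats))
  trunk_caches <- vector("list", length(model$trunk))
  for (i in seq_along(model$trunk)) {
    st <- layer_forward(model$trunk[[i]], x, training)
    x <- st$out
    model$trunk[[i]] <- st$layer
    if (cache) trunk_caches[[i]] <- st$cache
  }
  list(probs = x, model = model,
       caches = if (cache) list(heads = head_caches, trunk = trunk_caches,
                                widths = widths) else NULL)
}

# Backward pass for cross-entropy training. `dlogits` is the gradient at the
# softmax *input* ((P - Y)/n), so the trunk's final softmax layer is skipped.
net_backward <- function(model, caches, dlogits) {
  grads <- list(heads = list(), trunk = vector("list", length(model$trunk)))
  dy <- dlogits
  for (i in rev(seq_along(model$trunk))) {
    ly <- model$trunk[[i]]
    if (i == length(model$trunk) && ly$type == "softmax") {
      grads$trunk[[i]] <- list()
      next
    }
    bk <- layer_backward(ly, caches$trunk[[i]], dy)
    dy <- bk$dx
    grads$trunk[[i]] <- bk$grads
  }
  at <- 0L
  for (h in names(model$heads)) {
    w <- caches$widths[[h]]
    dh <- dy[, (at + 1L):(at + w), drop = FALSE]
    at <- at + w
    gh <- vector("list", length(model$heads[[h]]))
    for (i in rev(seq_along(model$heads[[h]]))) {
      bk <- layer_backward(model$heads[[h]][[i]], caches$heads[[h]][[i]], dh)
      dh <- bk$dx
      gh[[i]] <- bk$grads
    }
    grads$heads[[h]] <- gh
  }
  grads
}

#' Predict class probabilities or labels
#'
#' @param object A `"locomode_net"`.
#' @param newdata A `"window_set"`, a named list of window sets / arrays per
#'   head, or a bare (n, T, C) array for one-head models.
#' @param type `"prob"` for the n x 5 probability matrix, `"class"` for the
#'   factor of predicted activities.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Matrix of probabilities or factor of labels.
#' @export
predict.locomode_net <- function(object, newdata, type = c("prob", "class"),
                                 batch_size = 256L, ...) {
  type <- match.arg(type)
  inputs <- as_net_inputs(newdata, names(object$heads))
  n <- dim(inputs[[1]])[1]
  probs <- matrix(0, n, object$n_classes)
  for (at in seq.int(1L, n, by = batch_size)) {
    idx <- at:min(n, at + batch_size - 1L)
    batch <- lapply(inputs, function(x) x[idx, , , drop = FALSE])
    probs[idx, ] <- net_forward(object, batch, training = FALSE)$probs
  }
  colnames(probs) <- ACTIVITIES[seq_len(object$n_classes)]
  if (type == "prob") return(probs)
  factor(colnames(probs)[max.col(probs, ties.method = "first")],
         levels = colnames(probs))
}

# Normalise the many accepted input forms to a named list of arrays.
as_net_inputs <- function(newdata, head_names) {
  if (inherits(newdata, "window_set"))
    newdata <- setNames(list(newdata), newdata$modality)
  if (!is.list(newdata))
    newdata <- setNames(list(newdata), head_names)
  out <- lapply(newdata, function(x)
    if (inherits(x, "window_set")) x$windows else x)
  if (is.null(names(out)) && length(out) == length(head_names))
    names(out) <- head_names
  out[head_names]
}

#' Count model parameters
#'
#' Trainable and non-trainable parameter totals. For a built network the
#' counts are the sums of its weight-tensor sizes (batch-normalisation
#' running mean/variance are the non-trainable ones); for an architecture
#' spec the counts come from the closed-form accounting rules
#' (`conv1d: k*c_in*f + f`; `dense: n_in*n_out + n_out`; `batch-norm on c
#' channels: 2c trainable + 2c non-trainable`; `LSTM with input d and u
#' units: 4*((d+u)*u + u)`; pooling/flatten/activations: 0) without building
#' the model.
#'
#' @param x A `"locomode_net"` or an [arch_spec()].
#' @param ... Passed to methods ([count_parameters.arch_spec()] needs
#'   `input_shapes`).
#' @return An object of class `"param_count"`: list with `trainable`,
#'   `non_trainable`, `total`.
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.locomode_net <- function(x, ...) {
  tr <- 0; ntr <- 0
  for (ly in c(unlist(unname(x$heads), recursive = FALSE), x$trunk)) {
    tr <- tr + sum(vapply(ly$params, length, 0L))
    if (!is.null(ly$state))
      ntr <- ntr + sum(vapply(ly$state, length, 0L))
  }
  param_count(tr, ntr)
}

param_count <- function(trainable, non_trainable) {
  structure(list(trainable = as.integer(trainable),
                 non_trainable = as.integer(non_trainable),
                 total = as.integer(trainable + non_trainable)),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("trainable %s, non-trainable %s, total %s\n",
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ","),
              format(x$total, big.mark = ",")))
  invisible(x)
}
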