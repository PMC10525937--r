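# The three benchmark architectures reimplemented at the level their source
# descriptions pin down, with exact parameter accounting, plus their
# dual-head variants (one full single-modality branch per input, truncated
# before its classifier, concatenated into a single softmax).

#' Build the DeepConvLSTM benchmark
#'
#' Four temporal convolutions (64 filters, kernel 5, valid padding, ReLU)
#' followed by two 128-unit LSTM layers (tanh) and a softmax over the
#' classes; no batch normalisation, so the non-trainable count is zero.
#' On (3520, 8) the trainable count is 295,301; on (125, 7) it is 294,981 —
#' the difference is the first convolution's 5 x 64 input weights.
#'
#' @param input_shape `(T, C)`; T must survive four kernel-5 valid
#'   convolutions (T >= 17).
#' @param n_classes Number of classes (default 5).
#' @param seed Seed for weight initialisation.
#' @return A `"locomode_net"`.
#' @export
build_deepconvlstm <- function(input_shape, n_classes = 5L, seed = 1L) {
  T <- input_shape[1]; C <- input_shape[2]
  if (T < 17L)
    abort_("locomode_temporal_collapse",
           "input length %d too short for four kernel-5 valid convolutions", T)
  local_seed(seed, {
    head <- list(
      layer_conv1d(C, 64L, 5L, "valid"), layer_relu(),
      layer_conv1d(64L, 64L, 5L, "valid"), layer_relu(),
      layer_conv1d(64L, 64L, 5L, "valid"), layer_relu(),
      layer_conv1d(64L, 64L, 5L, "valid"), layer_relu(),
      layer_lstm(64L, 128L, return_sequences = TRUE),
      layer_lstm(128L, 128L, return_sequences = FALSE))
    trunk <- list(layer_dense(128L, n_classes), layer_softmax())
    new_network(setNames(list(head), "main"), trunk,
                setNames(list(input_shape), "main"), n_classes,
                "deepconvlstm")
  })
}

#' Build the LSTM-CNN benchmark
#'
#' Two 32-unit LSTM layers returning sequences, a 64-filter kernel-5
#' convolution, size-2 max-pooling, a 128-filter kernel-3 convolution,
#' global average pooling, batch normalisation and a softmax: the
#' L(32)-L(32)-C(64)-C(128)-GAP-BN stack. The single batch-norm layer on the
#' 128-wide pooled features contributes the 256 non-trainable parameters.
#'
#' @param input_shape `(T, C)`; T must survive conv(5), pool(2), conv(3).
#' @param n_classes Number of classes (default 5).
#' @param seed Seed for weight initialisation.
#' @return A `"locomode_net"`.
#' @export
build_lstm_cnn <- function(input_shape, n_classes = 5L, seed = 1L) {
  T <- input_shape[1]; C <- input_shape[2]
  if ((T - 4L) %/% 2L < 3L)
    abort_("locomode_temporal_collapse",
           "input length %d too short for the LSTM-CNN conv stack", T)
  local_seed(seed, {
    head <- list(
      layer_lstm(C, 32L, return_sequences = TRUE),
      layer_lstm(32L, 32L, return_sequences = TRUE),
      layer_conv1d(32L, 64L, 5L, "valid"), layer_relu(),
      layer_pool1d("max", 2L),
      layer_conv1d(64L, 128L, 3L, "valid"), layer_relu(),
      layer_gap(),
      layer_batchnorm(128L))
    trunk <- list(layer_dense(128L, n_classes), layer_softmax())
    new_network(setNames(list(head), "main"), trunk,
                setNames(list(input_shape), "main"), n_classes,
                "lstm_cnn")
  })
}

#' Build the DDLMI benchmark
#'
#' Four convolution/ReLU/max-pool stages, flatten, one dense layer followed
#' by batch normalisation and dropout, then softmax. The source description
#' does not pin down filter counts, kernel size or the dense width, so they
#' are configurable; the defaults use a 288-unit dense layer, making the
#' batch-normalised channel total 288 and hence the non-trainable count 576.
#'
#' @param input_shape `(T, C)`; T must survive four pool halvings.
#' @param filters Four conv filter counts.
#' @param kernel Convolution kernel size (same padding).
#' @param dense_units Width of the dense layer before batch-norm.
#' @param dropout Dropout rate.
#' @param n_classes Number of classes (default 5).
#' @param seed Seed for weight initialisation.
#' @return A `"locomode_net"`.
#' @export
build_ddlmi <- function(input_shape, filters = c(16L, 32L, 64L, 128L),
                        kernel = 3L, dense_units = 288L, dropout = 0.5,
                        n_classes = 5L, seed = 1L) {
  T <- input_shape[1]; C <- input_shape[2]
  if (T %/% 16L < 1L)
    abort_("locomode_temporal_collapse",
           "input length %d too short for four pool halvings", T)
  stopifnot(length(filters) == 4L)
  local_seed(seed, {
    head <- list()
    Tc <- T
    for (f in filters) {
      head <- c(head, list(layer_conv1d(C, f, kernel, "same"), layer_relu(),
                           layer_pool1d("max", 2L)))
      C <- f
      Tc <- Tc %/% 2L
    }
    head <- c(head, list(layer_flatten(),
                         layer_dense(Tc * C, dense_units),
                         layer_batchnorm(dense_units),
                         layer_dropout(dropout)))
    trunk <- list(layer_dense(dense_units, n_classes), layer_softmax())
    new_network(setNames(list(head), "main"), trunk,
                setNames(list(input_shape), "main"), n_classes, "ddlmi")
  })
}

#' Build a dual-head benchmark variant
#'
#' Two-modality variant of a benchmark: one full single-modality branch per
#' input, truncated before its final classification layer, the branch
#' outputs concatenated, and a single softmax over the classes on the
#' concatenation — the merge that keeps the original structures intact. For
#' DeepConvLSTM this concatenates the two 128-unit LSTM outputs (trainable
#' count 590,277 on the standard shapes); for LSTM-CNN the two
#' batch-normalised 128-wide GAP outputs (98,821 trainable, 512
#' non-trainable).
#'
#' @param base `"ddlmi"`, `"deepconvlstm"` or `"lstm_cnn"`.
#' @param input_shapes Named list of exactly two `(T, C)` shapes (typically
#'   `emg` and `robot`).
#' @param n_classes Number of classes (default 5).
#' @param seed Seed for weight initialisation.
#' @param ... Extra arguments passed to the single-modality builder.
#' @return A `"locomode_net"`.
#' @export
build_dual_head_variant <- function(base = c("ddlmi", "deepconvlstm",
                                             "lstm_cnn"),
                                    input_shapes, n_classes = 5L, seed = 1L,
                                    ...) {
  base <- match.arg(base)
  if (length(input_shapes) != 2L || is.null(names(input_shapes)))
    abort_("locomode_bad_argument",
           "input_shapes must name exactly two modalities")
  builder <- switch(base, ddlmi = build_ddlmi,
                    deepconvlstm = build_deepconvlstm,
                    lstm_cnn = build_lstm_cnn)
  local_seed(seed, {
    heads <- list()
    width <- 0L
    for (h in names(input_shapes)) {
      branch <- builder(input_shapes[[h]], n_classes = n_classes,
                        seed = sample.int(.Machine$integer.max, 1L), ...)
      # full branch minus its classifier: head layers only
      heads[[h]] <- branch$heads$main
      width <- width + branch_width(branch)
    }
    trunk <- list(layer_dense(width, n_classes), layer_softmax())
    new_network(heads, trunk, input_shapes, n_classes,
                paste0("dual_", base))
  })
}

# Feature width entering a benchmark's classifier.
branch_width <- function(net) net$trunk[[1]]$n_in

#' Closed-form parameter counts for named benchmark architectures
#'
#' Evaluates the accounting rules (conv1d `k*c_in*f + f`; LSTM
#' `4*((d+u)*u + u)`; dense `n_in*n_out + n_out`; batch-norm `2c` trainable
#' plus `2c` non-trainable) for a benchmark, without building it. Serves as
#' the independent cross-check against [count_parameters()] on the built
#' model.
#'
#' @param name `"deepconvlstm"`, `"lstm_cnn"`, or their `"dual_"` variants.
#' @param input_shapes A `(T, C)` pair, or a list of two for dual variants.
#' @param n_classes Number of classes (default 5).
#' @return A `"param_count"`.
#' @export
benchmark_param_count <- function(name, input_shapes, n_classes = 5L) {
  conv <- function(k, cin, f) k * cin * f + f
  lstm <- function(d, u) 4 * ((d + u) * u + u)
  dense <- function(nin, nout) nin * nout + nout
  single <- function(name, C) {
    switch(name,
      deepconvlstm = list(
        trainable = conv(5, C, 64) + 3 * conv(5, 64, 64) +
          lstm(64, 128) + lstm(128, 128),
        non_trainable = 0, width = 128),
      lstm_cnn = list(
        trainable = lstm(C, 32) + lstm(32, 32) + conv(5, 32, 64) +
          conv(3, 64, 128) + 2 * 128,
        non_trainable = 2 * 128, width = 128),
      abort_("locomode_bad_argument", "no closed form for '%s'", name))
  }
  if (startsWith(name, "dual_")) {
    stopifnot(length(input_shapes) == 2L)
    parts <- lapply(input_shapes, function(sh)
      single(sub("^dual_", "", name), sh[2]))
    tr <- sum(vapply(parts, `[[`, 0, "trainable")) +
      dense(sum(vapply(parts, `[[`, 0, "width")), n_classes)
    ntr <- sum(vapply(parts, `[[`, 0, "non_trainable"))
  } else {
    p <- single(name, input_shapes[2])
    tr <- p$trainable + dense(p$width, n_classes)
    ntr <- p$non_trainable
  }
  param_count(tr, ntr)
}
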