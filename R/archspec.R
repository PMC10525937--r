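# The constrained single-/multi-head CNN architecture family: every head is
# 1-3 blocks of 1-3 same-padded kernel-3 convolutions (batch-norm + ReLU
# after each) closed by a size-2 max or average pool; flattened head outputs
# feed a shared stack of 1-3 dense layers and a 5-way softmax. Filter counts
# come from {16, 32, 64, 128} and dense widths from {32, 64, 128, 256, 512},
# with consecutive parameterised layers differing by exactly a factor of two.

FILTER_SET <- c(16L, 32L, 64L, 128L)
UNIT_SET <- c(32L, 64L, 128L, 256L, 512L)

#' Convolutional block specification
#'
#' @param filters Integer vector (length 1-3) of filter counts, each in
#'   \{16, 32, 64, 128\}.
#' @param pooling `"max"` or `"average"` (pool size 2, valid padding).
#' @return A `"conv_block"` list.
#' @export
conv_block <- function(filters, pooling = c("max", "average")) {
  structure(list(filters = as.integer(filters),
                 pooling = match.arg(pooling)),
            class = "conv_block")
}

#' Architecture specification
#'
#' A point in the constrained search space. Single-head specs carry one
#' modality; multi-head specs concatenate the per-modality head outputs
#' before the shared dense stack.
#'
#' @param heads Named list (by modality) of lists of [conv_block()]s, 1-3
#'   blocks per head.
#' @param dense_units Integer vector (length 1-3) of dense-layer widths.
#' @param n_classes Number of output classes (default 5).
#' @param learning_rate Adam learning rate, `1e-4` or `1e-3`.
#' @param batch_size Mini-batch size in \{32, 64, 128, 256\}.
#' @param batch_norm_dense Also apply batch normalisation after dense layers
#'   (the family always applies it after convolutions).
#' @param allow_equal_boundary Permit equal filter counts across a block
#'   boundary (default: strict twofold adjacency everywhere).
#' @return A validated `"arch_spec"` object.
#' @export
arch_spec <- function(heads, dense_units, n_classes = 5L,
                      learning_rate = 1e-4, batch_size = 32L,
                      batch_norm_dense = FALSE,
                      allow_equal_boundary = FALSE) {
  spec <- structure(list(
    heads = heads, dense_units = as.integer(dense_units),
    n_classes = as.integer(n_classes), learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    batch_norm_dense = isTRUE(batch_norm_dense),
    allow_equal_boundary = isTRUE(allow_equal_boundary)
  ), class = "arch_spec")
  validate_arch_spec(spec)
  spec
}

#' Validate an architecture specification
#'
#' Checks block/layer counts, the allowed filter and unit sets, twofold
#' adjacency of consecutive filter counts (within a head, spanning block
#' boundaries) and of consecutive dense widths, and the training
#' hyperparameter domains. Raises a classed error on the first violation.
#'
#' @param spec An `"arch_spec"`.
#' @return `spec`, invisibly.
#' @export
validate_arch_spec <- function(spec) {
  if (length(spec$heads) < 1L || is.null(names(spec$heads)))
    abort_("locomode_bad_spec", "heads must be a named list")
  for (h in names(spec$heads)) {
    blocks <- spec$heads[[h]]
    if (length(blocks) < 1L || length(blocks) > 3L)
      abort_("locomode_bad_spec", "head '%s': 1-3 blocks required", h)
    seqf <- integer(0)
    boundary_after <- integer(0)    # positions in seqf that end a block
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      f <- blk$filters
      if (length(f) < 1L || length(f) > 3L)
        abort_("locomode_bad_spec",
               "head '%s' block %d: 1-3 conv layers required", h, bi)
      if (!all(f %in% FILTER_SET))
        abort_("locomode_bad_spec",
               "head '%s' block %d: filters must be in {%s}",
               h, bi, paste(FILTER_SET, collapse = ", "))
      if (!blk$pooling %in% c("max", "average"))
        abort_("locomode_bad_spec", "unknown pooling '%s'", blk$pooling)
      seqf <- c(seqf, f)
      boundary_after <- c(boundary_after, length(seqf))
    }
    for (j in seq_len(length(seqf) - 1L)) {
      r <- seqf[j + 1L] / seqf[j]
      ok <- r %in% c(2, 0.5) ||
        (spec$allow_equal_boundary && r == 1 && j %in% boundary_after)
      if (!ok)
        abort_("locomode_bad_spec",
               "head '%s': consecutive filter counts %d -> %d violate twofold adjacency",
               h, seqf[j], seqf[j + 1L])
    }
  }
  u <- spec$dense_units
  if (length(u) < 1L || length(u) > 3L)
    abort_("locomode_bad_spec", "1-3 dense layers required")
  if (!all(u %in% UNIT_SET))
    abort_("locomode_bad_spec", "dense units must be in {%s}",
           paste(UNIT_SET, collapse = ", "))
  if (length(u) > 1L && !all((u[-1] / u[-length(u)]) %in% c(2, 0.5)))
    abort_("locomode_bad_spec", "dense widths violate twofold adjacency")
  if (!spec$learning_rate %in% c(1e-4, 1e-3))
    abort_("locomode_bad_spec", "learning rate must be 1e-4 or 1e-3")
  if (!spec$batch_size %in% c(32L, 64L, 128L, 256L))
    abort_("locomode_bad_spec", "batch size must be 32, 64, 128 or 256")
  invisible(spec)
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("<arch_spec>\n")
  for (h in names(x$heads)) {
    blks <- vapply(x$heads[[h]], function(b)
      sprintf("[%s|%s]", paste(b$filters, collapse = ","), b$pooling), "")
    cat(sprintf("  head %-6s: %s\n", h, paste(blks, collapse = " ")))
  }
  cat(sprintf("  dense: %s -> softmax(%d)\n",
              paste(x$dense_units, collapse = ", "), x$n_classes))
  cat(sprintf("  lr %g, batch %d\n", x$learning_rate, x$batch_size))
  invisible(x)
}

# Shared builder for the family.
build_from_spec <- function(spec, input_shapes, seed = 1L) {
  validate_arch_spec(spec)
  if (!setequal(names(input_shapes), names(spec$heads)))
    abort_("locomode_bad_argument",
           "input_shapes must be named like the spec heads")
  local_seed(seed, {
    heads <- list()
    for (h in names(spec$heads)) {
      sh <- input_shapes[[h]]
      T <- sh[1]; C <- sh[2]
      layers <- list()
      for (blk in spec$heads[[h]]) {
        for (f in blk$filters) {
          layers <- c(layers, list(layer_conv1d(C, f, 3L, "same"),
                                   layer_batchnorm(f), layer_relu()))
          C <- f
        }
        if (T %/% 2L < 1L)
          abort_("locomode_temporal_collapse",
                 "head '%s': pooling collapses the temporal axis", h)
        T <- T %/% 2L
        layers <- c(layers, list(layer_pool1d(blk$pooling, 2L)))
      }
      layers <- c(layers, list(layer_flatten()))
      heads[[h]] <- layers
      attr(heads[[h]], "flat_width") <- T * C
    }
    n_in <- sum(vapply(heads, function(hh) attr(hh, "flat_width"), 0))
    trunk <- list()
    for (u in spec$dense_units) {
      trunk <- c(trunk, list(layer_dense(n_in, u)))
      if (spec$batch_norm_dense) trunk <- c(trunk, list(layer_batchnorm(u)))
      trunk <- c(trunk, list(layer_relu()))
      n_in <- u
    }
    trunk <- c(trunk, list(layer_dense(n_in, spec$n_classes), layer_softmax()))
    new_network(heads, trunk, input_shapes, spec$n_classes,
                name = if (length(heads) > 1L) "multi_head_cnn"
                       else "single_head_cnn",
                spec = spec)
  })
}

#' Build a single-head CNN
#'
#' Instantiates a one-head member of the architecture family: per block,
#' `[conv(k=3, same) - batch-norm - ReLU] x n` then a size-2 pool; flatten;
#' dense stack with ReLU; softmax over the classes.
#'
#' @param spec An [arch_spec()] with exactly one head.
#' @param input_shape `(T, C)` integer pair.
#' @param seed Seed for weight initialisation.
#' @return A `"locomode_net"`.
#' @export
build_single_head <- function(spec, input_shape, seed = 1L) {
  if (length(spec$heads) != 1L)
    abort_("locomode_bad_spec", "spec must have exactly one head")
  build_from_spec(spec, setNames(list(input_shape), names(spec$heads)), seed)
}

#' Build a multi-head CNN
#'
#' One convolutional head per modality; the flattened head outputs are
#' concatenated and fed to the shared dense stack and softmax.
#'
#' @param spec An [arch_spec()] with two or more heads.
#' @param input_shapes Named list of `(T, C)` pairs, one per head.
#' @param seed Seed for weight initialisation.
#' @return A `"locomode_net"`.
#' @export
build_multi_head <- function(spec, input_shapes, seed = 1L) {
  if (length(spec$heads) < 2L)
    abort_("locomode_bad_spec", "spec must have at least two heads")
  build_from_spec(spec, input_shapes, seed)
}

#' @describeIn count_parameters Closed-form accounting for a family spec on
#'   given input shapes, without building the model.
#' @param input_shapes Named list of `(T, C)` input shapes (or a single
#'   `(T, C)` pair for one-head specs).
#' @export
count_parameters.arch_spec <- function(x, input_shapes, ...) {
  if (!is.list(input_shapes))
    input_shapes <- setNames(list(input_shapes), names(x$heads))
  tr <- 0; ntr <- 0; flat <- 0
  for (h in names(x$heads)) {
    sh <- input_shapes[[h]]
    T <- sh[1]; C <- sh[2]
    for (blk in x$heads[[h]]) {
      for (f in blk$filters) {
        tr <- tr + 3 * C * f + f          # conv
        tr <- tr + 2 * f                  # BN gamma/beta
        ntr <- ntr + 2 * f                # BN running mean/var
        C <- f
      }
      T <- T %/% 2L
    }
    flat <- flat + T * C
  }
  n_in <- flat
  for (u in x$dense_units) {
    tr <- tr + n_in * u + u
    if (x$batch_norm_dense) { tr <- tr + 2 * u; ntr <- ntr + 2 * u }
    n_in <- u
  }
  tr <- tr + n_in * x$n_classes + x$n_classes
  param_count(tr, ntr)
}

#' Reference architectures
#'
#' The three selected instances of the family used as fixed references: the
#' EMG single-head model (3 blocks of 2 convolutions with max-pooling, one
#' 512-unit dense layer, learning rate 1e-4, batch 128), the exoskeleton
#' single-head model (same block structure, dense 128 then 256, batch 32),
#' and the two-head model (one head of 2 blocks with a single convolution
#' each, one head of 2 stacked 3-convolution blocks, one 128-unit dense
#' layer, batch 128). Filter counts are fixed package defaults chosen from
#' the admissible twofold sequences.
#'
#' @param name `"emg"`, `"robot"` or `"dual"`.
#' @return An [arch_spec()].
#' @export
reference_spec <- function(name = c("emg", "robot", "dual")) {
  switch(match.arg(name),
    emg = arch_spec(
      heads = list(emg = list(conv_block(c(16L, 32L)),
                              conv_block(c(64L, 128L)),
                              conv_block(c(64L, 128L)))),
      dense_units = 512L, learning_rate = 1e-4, batch_size = 128L),
    robot = arch_spec(
      heads = list(robot = list(conv_block(c(16L, 32L)),
                                conv_block(c(64L, 128L)),
                                conv_block(c(64L, 128L)))),
      dense_units = c(128L, 256L), learning_rate = 1e-4, batch_size = 32L),
    dual = arch_spec(
      heads = list(robot = list(conv_block(32L), conv_block(64L)),
                   emg = list(conv_block(c(16L, 32L, 64L)),
                              conv_block(c(128L, 64L, 32L)))),
      dense_units = 128L, learning_rate = 1e-4, batch_size = 128L))
}

#' Serialise an architecture spec as JSON
#' @param spec An [arch_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arch_spec <- function(spec, path) {
  x <- list(
    heads = lapply(spec$heads, function(blocks)
      lapply(blocks, function(b)
        list(filters = b$filters, pooling = b$pooling))),
    dense_units = spec$dense_units, n_classes = spec$n_classes,
    learning_rate = spec$learning_rate, batch_size = spec$batch_size,
    batch_norm_dense = spec$batch_norm_dense,
    allow_equal_boundary = spec$allow_equal_boundary)
  write_json_(x, path)
}

#' Read an architecture spec from JSON
#' @param path JSON written by [write_arch_spec()].
#' @return A validated [arch_spec()].
#' @export
read_arch_spec <- function(path) {
  x <- jsonlite::read_json(path)   # unsimplified: keep the block structure
  heads <- lapply(x$heads, function(blocks)
    lapply(blocks, function(b) conv_block(unlist(b$filters), b$pooling)))
  arch_spec(heads, unlist(x$dense_units), x$n_classes, x$learning_rate,
            x$batch_size, isTRUE(x$batch_norm_dense),
            isTRUE(x$allow_equal_boundary))
}

# Admissible filter/unit walks of a given length: each step multiplies or
# divides by two while staying in the value set.
twofold_walks <- function(set, len) {
  if (len == 1L) return(as.list(set))
  out <- list()
  grow <- function(seqv) {
    if (length(seqv) == len) { out[[length(out) + 1L]] <<- seqv; return() }
    last <- seqv[length(seqv)]
    for (nxt in c(last * 2L, last %/% 2L))
      if (nxt %in% set) grow(c(seqv, nxt))
  }
  for (v in set) grow(v)
  out
}

#' Search the family for specs matching a parameter count
#'
#' Enumerates single-head members of the constrained space (blocks,
#' per-block convolution counts, twofold filter walks, dense stacks) and
#' returns those whose closed-form counts match the requested totals.
#' Intended as a constraint-satisfaction aid for recovering undocumented
#' instances from printed parameter tables.
#'
#' @param input_shape `(T, C)` input shape.
#' @param trainable Target trainable count.
#' @param non_trainable Optional target non-trainable count.
#' @param modality Head name used in the returned specs.
#' @param max_results Stop after this many matches.
#' @return List of [arch_spec()]s (possibly empty).
#' @export
find_matching_specs <- function(input_shape, trainable, non_trainable = NULL,
                                modality = "emg", max_results = 10L) {
  res <- list()
  dense_opts <- unlist(lapply(1:3, function(l) twofold_walks(UNIT_SET, l)),
                       recursive = FALSE)
  for (nb in 1:3) {
    convs_per_block <- expand.grid(rep(list(1:3), nb))
    for (ci in seq_len(nrow(convs_per_block))) {
      nconv <- as.integer(convs_per_block[ci, ])
      for (walk in twofold_walks(FILTER_SET, sum(nconv))) {
        blocks <- list()
        at <- 0L
        for (b in seq_len(nb)) {
          blocks[[b]] <- conv_block(walk[(at + 1L):(at + nconv[b])])
          at <- at + nconv[b]
        }
        spec <- try(arch_spec(setNames(list(blocks), modality),
                              dense_units = 32L), silent = TRUE)
        if (inherits(spec, "try-error")) next
        for (du in dense_opts) {
          spec$dense_units <- as.integer(du)
          pc <- count_parameters(spec, input_shape)
          if (pc$trainable == trainable &&
              (is.null(non_trainable) || pc$non_trainable == non_trainable)) {
            res[[length(res) + 1L]] <- spec
            if (length(res) >= max_results) return(res)
          }
        }
      }
    }
  }
  res
}
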