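emg_shape <- c(3520L, 8L)
robot_shape <- c(125L, 7L)
both_shapes <- list(emg = emg_shape, robot = robot_shape)

test_that("benchmark parameter counts match closed-form accounting exactly", {
  cases <- list(
    list(build_deepconvlstm(emg_shape), "deepconvlstm", emg_shape),
    list(build_deepconvlstm(robot_shape), "deepconvlstm", robot_shape),
    list(build_lstm_cnn(emg_shape), "lstm_cnn", emg_shape),
    list(build_lstm_cnn(robot_shape), "lstm_cnn", robot_shape),
    list(build_dual_head_variant("deepconvlstm", both_shapes),
         "dual_deepconvlstm", both_shapes),
    list(build_dual_head_variant("lstm_cnn", both_shapes),
         "dual_lstm_cnn", both_shapes))
  for (cs in cases) {
    built <- count_parameters(cs[[1]])
    closed <- benchmark_param_count(cs[[2]], cs[[3]])
    expect_identical(built$trainable, closed$trainable)
    expect_identical(built$non_trainable, closed$non_trainable)
  }
})

test_that("changing 7 to 8 input channels shifts only first-layer weights", {
  # DeepConvLSTM: first conv k=5, 64 filters -> delta 5*64 = 320
  d_dcl <- count_parameters(build_deepconvlstm(emg_shape))$trainable -
    count_parameters(build_deepconvlstm(robot_shape))$trainable
  expect_identical(d_dcl, 5L * 64L)
  # LSTM-CNN: first LSTM 32 units -> delta 4*32 = 128
  d_lc <- count_parameters(build_lstm_cnn(emg_shape))$trainable -
    count_parameters(build_lstm_cnn(robot_shape))$trainable
  expect_identical(d_lc, 4L * 32L)
})

test_that("dual-head accounting equals branches minus classifiers plus merge", {
  for (base in c("deepconvlstm", "lstm_cnn", "ddlmi")) {
    builder <- switch(base, deepconvlstm = build_deepconvlstm,
                      lstm_cnn = build_lstm_cnn, ddlmi = build_ddlmi)
    b_emg <- count_parameters(builder(emg_shape))
    b_rob <- count_parameters(builder(robot_shape))
    dual <- count_parameters(build_dual_head_variant(base, both_shapes))
    w <- switch(base, deepconvlstm = 128L, lstm_cnn = 128L, ddlmi = 288L)
    single_cls <- w * 5L + 5L
    merged_cls <- 2L * w * 5L + 5L
    expect_identical(dual$trainable,
                     b_emg$trainable + b_rob$trainable -
                       2L * single_cls + merged_cls)
    expect_identical(dual$non_trainable,
                     b_emg$non_trainable + b_rob$non_trainable)
  }
})

test_that("DDLMI batch-norm channel total fixes the non-trainable count", {
  m <- build_ddlmi(robot_shape)
  expect_identical(count_parameters(m)$non_trainable, 2L * 288L)
  m2 <- build_ddlmi(robot_shape, dense_units = 64L)
  expect_identical(count_parameters(m2)$non_trainable, 2L * 64L)
})

test_that("built models emit probability vectors over the five classes", {
  set.seed(9)
  x_rob <- array(rnorm(4 * 125 * 7), c(4, 125, 7))
  x_emg <- array(rnorm(2 * 200 * 8), c(2, 200, 8))
  m1 <- build_single_head(reference_spec("robot"), robot_shape, seed = 2)
  p1 <- predict(m1, x_rob)
  expect_equal(dim(p1), c(4L, 5L))
  expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p1 >= 0))
  # minimal one-block, one-conv, one-dense spec
  tiny <- arch_spec(heads = list(robot = list(conv_block(16L))),
                    dense_units = 32L)
  p2 <- predict(build_single_head(tiny, c(8L, 2L),
                                  seed = 1),
                array(rnorm(3 * 8 * 2), c(3, 8, 2)))
  expect_equal(rowSums(p2), rep(1, 3), tolerance = 1e-6)
  # benchmarks forward too
  p3 <- predict(build_deepconvlstm(c(40L, 7L), seed = 1),
                array(rnorm(2 * 40 * 7), c(2, 40, 7)))
  expect_equal(rowSums(p3), rep(1, 2), tolerance = 1e-6)
})

test_that("multi-head models concatenate head features before the trunk", {
  spec <- reference_spec("dual")
  shapes <- list(robot = c(40L, 7L), emg = c(64L, 8L))
  m <- build_multi_head(spec, shapes, seed = 3)
  # concatenated width = sum of flattened head widths = trunk input
  w_rob <- (40L %/% 4L) * 64L
  w_emg <- (64L %/% 4L) * 32L
  expect_identical(m$trunk[[1]]$n_in, w_rob + w_emg)
  p <- predict(m, list(robot = array(rnorm(2 * 40 * 7), c(2, 40, 7)),
                       emg = array(rnorm(2 * 64 * 8), c(2, 64, 8))))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
})

test_that("family spec counts agree between closed form and built model", {
  for (nm in c("emg", "robot")) {
    spec <- reference_spec(nm)
    shape <- if (nm == "emg") emg_shape else robot_shape
    closed <- count_parameters(spec, shape)
    built <- count_parameters(build_single_head(spec, shape))
    expect_identical(closed$trainable, built$trainable)
    expect_identical(closed$non_trainable, built$non_trainable)
  }
  spec <- reference_spec("dual")
  closed <- count_parameters(spec, both_shapes[c("robot", "emg")])
  built <- count_parameters(build_multi_head(spec, both_shapes[c("robot", "emg")]))
  expect_identical(closed$trainable, built$trainable)
})

test_that("spec validation rejects out-of-space architectures", {
  ok <- list(robot = list(conv_block(c(16L, 32L))))
  expect_s3_class(arch_spec(ok, 64L), "arch_spec")
  expect_error(arch_spec(list(robot = list(conv_block(c(16L, 48L)))), 64L),
               class = "locomode_bad_spec")
  expect_error(arch_spec(list(robot = list(conv_block(c(16L, 64L)))), 64L),
               class = "locomode_bad_spec")   # fourfold jump
  expect_error(arch_spec(ok, c(64L, 256L)), class = "locomode_bad_spec")
  expect_error(arch_spec(ok, 48L), class = "locomode_bad_spec")
  expect_error(arch_spec(ok, 64L, learning_rate = 5e-4),
               class = "locomode_bad_spec")
  expect_error(arch_spec(ok, 64L, batch_size = 100L),
               class = "locomode_bad_spec")
  expect_error(
    arch_spec(list(robot = list(conv_block(16L), conv_block(16L))), 64L),
    class = "locomode_bad_spec")   # equal at boundary, strict default
  eq <- arch_spec(list(robot = list(conv_block(16L), conv_block(16L))), 64L,
                  allow_equal_boundary = TRUE)
  expect_s3_class(eq, "arch_spec")
  expect_error(
    arch_spec(list(robot = list(conv_block(c(16L, 32L, 16L, 32L)))), 64L),
    class = "locomode_bad_spec")   # too many convs per block
  too_deep <- list(robot = rep(list(conv_block(16L)), 4))
  expect_error(arch_spec(too_deep, 64L), class = "locomode_bad_spec")
})

test_that("temporal collapse is caught at build time", {
  spec <- arch_spec(list(robot = list(conv_block(16L), conv_block(32L),
                                      conv_block(64L))), 32L)
  expect_error(build_single_head(spec, c(4L, 7L)),
               class = "locomode_temporal_collapse")
  expect_error(build_deepconvlstm(c(16L, 7L)),
               class = "locomode_temporal_collapse")
})

test_that("arch specs round-trip through JSON", {
  spec <- reference_spec("dual")
  path <- withr::local_tempfile(fileext = ".json")
  write_arch_spec(spec, path)
  back <- read_arch_spec(path)
  expect_equal(back$heads, spec$heads, ignore_attr = TRUE)
  expect_identical(back$dense_units, spec$dense_units)
  expect_identical(back$batch_size, spec$batch_size)
})

test_that("the spec solver recovers architectures from parameter totals", {
  target <- reference_spec("robot")
  pc <- count_parameters(target, c(125L, 7L))
  hits <- find_matching_specs(c(125L, 7L), pc$trainable, pc$non_trainable,
                              modality = "robot", max_results = 5)
  expect_gt(length(hits), 0)
  ok <- vapply(hits, function(s) {
    p <- count_parameters(s, c(125L, 7L))
    p$trainable == pc$trainable && p$non_trainable == pc$non_trainable
  }, TRUE)
  expect_true(all(ok))
})
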