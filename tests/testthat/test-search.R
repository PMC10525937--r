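ns <- asNamespace("locomode")

# Deterministic discrete surrogate: best at conv depth 2 and first dense
# width 128.
surrogate <- function(spec) {
  depth <- sum(vapply(spec$heads[[1]], function(b) length(b$filters), 0L))
  -(depth - 2)^2 - (log2(spec$dense_units[1]) - 7)^2 / 10
}

test_that("sampled specs stay inside the constrained space", {
  space <- search_space("robot")
  set.seed(31)
  depths <- integer(0)
  for (i in 1:300) {
    spec <- sample_spec(space)
    expect_s3_class(spec, "arch_spec")   # constructor validates
    for (b in spec$heads$robot) {
      expect_true(all(b$filters %in% c(16, 32, 64, 128)))
      expect_lte(length(b$filters), 3)
    }
    expect_true(length(spec$heads$robot) %in% 1:3)
    expect_true(all(spec$dense_units %in% c(32, 64, 128, 256, 512)))
    expect_true(spec$batch_size %in% c(32, 64, 128, 256))
    depths <- c(depths, length(spec$heads$robot))
  }
  # every legal block depth is reachable
  expect_setequal(unique(depths), 1:3)
})

test_that("the search keeps an exact evaluation budget and logs every trial", {
  space <- search_space("robot")
  calls <- 0
  obj <- function(spec) { calls <<- calls + 1; surrogate(spec) }
  log_file <- withr::local_tempfile(fileext = ".jsonl")
  res <- run_search(space, obj, max_evals = 23, seed = 4,
                    log_file = log_file)
  expect_equal(calls, 23)
  expect_length(res$trials, 23)
  expect_identical(length(readLines(log_file)), 23L)
  # best = argmax over the log
  ys <- vapply(res$trials, `[[`, 0, "y")
  expect_equal(res$best$y, max(ys))
  # max_evals = 1 returns the only trial
  one <- run_search(space, obj, max_evals = 1, seed = 9)
  expect_identical(one$best$trial_index, 1L)
})

test_that("the optimum of a discrete surrogate is found within 50 evaluations", {
  space <- search_space("robot")
  # exhaustive enumeration oracle over the quantities the surrogate uses
  best_possible <- max(vapply(1:9, function(d)
    max(vapply(c(32, 64, 128, 256, 512), function(u)
      -(d - 2)^2 - (log2(u) - 7)^2 / 10, 0)), 0))
  res <- run_search(space, surrogate, max_evals = 50, seed = 7)
  # within the optimum's immediate neighbourhood (one step in depth or
  # width costs at most 1 + 0.1 on this surface)
  expect_gte(res$best$y, best_possible - 1.1)
  depth <- sum(vapply(res$best$spec$heads[[1]],
                      function(b) length(b$filters), 0L))
  expect_lte(abs(depth - 2L), 1L)
})

test_that("searches are reproducible and failures become -Inf trials", {
  space <- search_space("robot")
  flaky <- function(spec) {
    if (spec$batch_size == 256L) stop("boom")
    surrogate(spec)
  }
  r1 <- run_search(space, flaky, max_evals = 30, seed = 2)
  r2 <- run_search(space, flaky, max_evals = 30, seed = 2)
  expect_equal(vapply(r1$trials, `[[`, 0, "y"),
               vapply(r2$trials, `[[`, 0, "y"))
  expect_identical(r1$best$encoding, r2$best$encoding)
  failed <- vapply(r1$trials, function(t) identical(t$y, -Inf), TRUE)
  expect_gt(sum(failed), 0)
  expect_lt(sum(failed), 30)
  # ties break by lower validation loss, then index
  res <- run_search(space, function(s) list(score = 1, val_loss = 0.5),
                    max_evals = 3, seed = 1)
  expect_identical(res$best$trial_index, 1L)
  res2 <- run_search(
    space, function(s) list(score = 1, val_loss = runif(1)),
    max_evals = 5, seed = 6)
  vls <- vapply(res2$trials, `[[`, 0, "val_loss")
  expect_identical(res2$best$trial_index, which.min(vls))
})

test_that("TPE matches or beats random search on the surrogate", {
  space <- search_space("robot")
  wins <- 0
  for (s in 1:20) {
    tpe <- run_search(space, surrogate, max_evals = 25, seed = s,
                      sampler = "tpe")
    rnd <- run_search(space, surrogate, max_evals = 25, seed = 1000 + s,
                      sampler = "random")
    if (tpe$best$y >= rnd$best$y) wins <- wins + 1
  }
  expect_gte(wins, 12)   # >= 60% of paired runs
})

test_that("objective_eval trains a spec and scores it on validation data", {
  splits <- segmented_robot(n_subjects = 4, seed = 19)
  spec <- arch_spec(heads = list(robot = list(conv_block(16L))),
                    dense_units = 32L, learning_rate = 1e-3,
                    batch_size = 64L)
  res <- objective_eval(spec, list(train = splits$train$robot,
                                   val = splits$val$robot),
                        epochs = 2, seed = 1)
  expect_gte(res$score, 0)
  expect_lte(res$score, 1)
  expect_true(is.finite(res$val_loss))
  # a spec the input cannot support becomes a failed trial inside run_search
  deep <- arch_spec(heads = list(robot = list(conv_block(16L),
                                              conv_block(32L),
                                              conv_block(64L))),
                    dense_units = 32L)
  tiny_data <- list(train = splits$train$robot, val = splits$val$robot)
  tiny_data$train$windows <- tiny_data$train$windows[, 1:6, , drop = FALSE]
  tiny_data$val$windows <- tiny_data$val$windows[, 1:6, , drop = FALSE]
  expect_error(objective_eval(deep, tiny_data, epochs = 1),
               class = "locomode_temporal_collapse")
})
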