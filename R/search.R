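# Conditional encoding of the constrained architecture search space and
# sequential optimisation of validation macro F-measure, with a
# tree-structured Parzen estimator (TPE) sampler over the discrete space and
# a uniform-random fallback. Per-block decisions exist only for instantiated
# blocks; filter/width walks are encoded as a start value plus up/down moves
# clamped to the admissible sets, so every sampled point is valid by
# construction.

#' Describe the structural search space
#'
#' Blocks and convolutions per block in 1-3, filters in \{16, 32, 64, 128\},
#' kernel 3 / stride 1 / same padding, max or average pooling of size 2,
#' 1-3 dense layers with widths in \{32, 64, 128, 256, 512\}, batch
#' normalisation on, Adam with learning rate 1e-4 or 1e-3, batch size in
#' \{32, 64, 128, 256\}, 20 epochs per evaluation. With two modalities the
#' head layout (emg-only, robot-only, or both heads) is itself part of the
#' space.
#'
#' @param modalities Modalities available to the search (`"emg"`,
#'   `"robot"`, or both).
#' @param trial_epochs Training epochs per candidate evaluation (default 20).
#' @return A `"search_space"` list.
#' @export
search_space <- function(modalities = "robot", trial_epochs = 20L) {
  modalities <- match.arg(modalities, c("emg", "robot"), several.ok = TRUE)
  structure(list(modalities = modalities,
                 trial_epochs = as.integer(trial_epochs)),
            class = "search_space")
}

# Decision domains, by key prefix.
.domain <- function(name) {
  if (name == "head_mode") return(c("emg", "robot", "both"))
  if (grepl("^(nb|nc)", name)) return(1:3)
  if (grepl("^pool", name)) return(c("max", "average"))
  if (name == "f0") return(FILTER_SET)
  if (name == "u0") return(UNIT_SET)
  if (grepl("^(fdir|udir)", name)) return(c("up", "down"))
  if (name == "nd") return(1:3)
  if (name == "lr") return(c(1e-4, 1e-3))
  if (name == "bs") return(c(32L, 64L, 128L, 256L))
  abort_("locomode_bad_argument", "unknown decision '%s'", name)
}

# Pick one value from a domain with the supplied weighting function.
pick_ <- function(key, weight_fn) {
  dom <- .domain(strip_key(key))
  w <- if (is.null(weight_fn)) rep(1, length(dom)) else weight_fn(key, dom)
  dom[sample.int(length(dom), 1L, prob = w)]
}

# "nc_emg_2" -> "nc"; "head_mode" stays itself.
strip_key <- function(key) {
  if (key == "head_mode") return(key)
  sub("_.*$", "", key)
}

# Walk a value sequence from a start and up/down moves, clamping to the set.
walk_values <- function(set, start, dirs) {
  out <- start
  cur <- start
  for (d in dirs) {
    nxt <- if (d == "up") cur * 2L else cur %/% 2L
    if (!nxt %in% set) nxt <- if (d == "up") cur %/% 2L else cur * 2L
    cur <- nxt
    out <- c(out, cur)
  }
  out
}

# Sample a full conditional encoding; `weight_fn(key, domain)` biases each
# decision (NULL = uniform).
sample_encoding <- function(space, weight_fn = NULL) {
  enc <- list()
  put <- function(key) enc[[key]] <<- pick_(key, weight_fn)
  if (length(space$modalities) > 1L) put("head_mode")
  mode <- enc$head_mode %||% space$modalities
  mods <- if (identical(mode, "both")) c("emg", "robot") else mode
  for (m in mods) {
    put(paste0("nb_", m))
    nb <- enc[[paste0("nb_", m)]]
    total <- 0L
    for (b in seq_len(nb)) {
      put(paste0("nc_", m, "_", b))
      put(paste0("pool_", m, "_", b))
      total <- total + enc[[paste0("nc_", m, "_", b)]]
    }
    put(paste0("f0_", m))
    if (total > 1L)
      for (j in 2:total) put(paste0("fdir_", m, "_", j))
  }
  put("nd")
  put("u0")
  if (enc$nd > 1L) for (j in 2:enc$nd) put(paste0("udir_", j))
  put("lr")
  put("bs")
  enc
}

# Decode an encoding into a validated arch_spec.
decode_encoding <- function(space, enc) {
  mode <- enc$head_mode %||% space$modalities
  mods <- if (identical(mode, "both")) c("emg", "robot") else mode
  heads <- list()
  for (m in mods) {
    nb <- enc[[paste0("nb_", m)]]
    ncv <- vapply(seq_len(nb), function(b) enc[[paste0("nc_", m, "_", b)]], 0L)
    dirs <- character(0)
    if (sum(ncv) > 1L)
      dirs <- vapply(2:sum(ncv), function(j)
        enc[[paste0("fdir_", m, "_", j)]], "")
    filters <- walk_values(FILTER_SET, enc[[paste0("f0_", m)]], dirs)
    blocks <- list()
    at <- 0L
    for (b in seq_len(nb)) {
      blocks[[b]] <- conv_block(filters[(at + 1L):(at + ncv[b])],
                                enc[[paste0("pool_", m, "_", b)]])
      at <- at + ncv[b]
    }
    heads[[m]] <- blocks
  }
  udirs <- character(0)
  if (enc$nd > 1L)
    udirs <- vapply(2:enc$nd, function(j) enc[[paste0("udir_", j)]], "")
  arch_spec(heads,
            dense_units = walk_values(UNIT_SET, enc$u0, udirs),
            learning_rate = enc$lr, batch_size = enc$bs)
}

#' Sample an architecture from the search space
#'
#' Draws one point uniformly over the conditional encoding; every sampled
#' spec satisfies the family constraints by construction, and every legal
#' depth/width combination is reachable.
#'
#' @param space A [search_space()].
#' @return An [arch_spec()] with the raw encoding attached as attribute
#'   `"encoding"`.
#' @export
sample_spec <- function(space) {
  enc <- sample_encoding(space)
  spec <- decode_encoding(space, enc)
  attr(spec, "encoding") <- enc
  spec
}

# ---- TPE -------------------------------------------------------------------

# Laplace-smoothed categorical density of `value` within `obs` over `dom`.
cat_density <- function(value, obs, dom) {
  (sum(obs == value) + 1) / (length(obs) + length(dom))
}

# Weighting closure over the good set, for candidate generation.
good_weight_fn <- function(good_encs) {
  function(key, dom) {
    obs <- unlist(lapply(good_encs, function(e) e[[key]]))
    vapply(dom, function(v) cat_density(v, obs, dom), 0)
  }
}

# log l(x)/g(x) of a candidate encoding under the two Parzen models.
tpe_score <- function(enc, good_encs, bad_encs) {
  s <- 0
  for (key in names(enc)) {
    dom <- .domain(strip_key(key))
    gobs <- unlist(lapply(good_encs, function(e) e[[key]]))
    bobs <- unlist(lapply(bad_encs, function(e) e[[key]]))
    s <- s + log(cat_density(enc[[key]], gobs, dom)) -
      log(cat_density(enc[[key]], bobs, dom))
  }
  s
}

tpe_propose <- function(space, history, gamma = 0.25, n_candidates = 24L) {
  ok <- !vapply(history, function(t) is.infinite(t$y) && t$y < 0, TRUE)
  hist_ok <- history[ok]
  if (length(hist_ok) < 2L) return(sample_encoding(space))
  ys <- vapply(hist_ok, `[[`, 0, "y")
  n_good <- max(1L, ceiling(gamma * length(ys)))
  ord <- order(-ys)
  good <- lapply(hist_ok[ord[seq_len(n_good)]], `[[`, "encoding")
  bad <- lapply(hist_ok[ord[-seq_len(n_good)]], `[[`, "encoding")
  if (length(bad) == 0L) bad <- good
  wfn <- good_weight_fn(good)
  cands <- replicate(n_candidates, sample_encoding(space, wfn),
                     simplify = FALSE)
  scores <- vapply(cands, tpe_score, 0, good_encs = good, bad_encs = bad)
  cands[[which.max(scores)]]
}

#' Run structural hyperparameter search
#'
#' Evaluates exactly `max_evals` sampled architectures with the supplied
#' objective, maximising the returned score (validation macro F-measure in
#' the standard pipeline). The first `n_startup` trials are random; later
#' proposals come from a tree-structured Parzen estimator over the
#' conditional encoding (top `gamma` fraction as the "good" density,
#' Laplace-smoothed categorical Parzen models, best of `n_candidates`
#' draws by density ratio). An objective that throws is recorded as a failed
#' trial with score `-Inf` and the search continues. The best trial is the
#' highest score, ties broken by lower validation loss, then lower trial
#' index.
#'
#' @param space A [search_space()].
#' @param objective Function of an [arch_spec()] returning a numeric score
#'   or a list with `score` and optionally `val_loss`.
#' @param max_evals Number of objective evaluations (default 50).
#' @param seed Seed for the whole trial sequence.
#' @param sampler `"tpe"` or `"random"`.
#' @param n_startup Random trials before TPE proposals start.
#' @param gamma Quantile split between the good and bad densities.
#' @param n_candidates Candidate draws per TPE proposal.
#' @param log_file Optional path; one JSON line per trial is appended.
#' @return A `"locomode_search"`: `best` trial, `trials` list, and the
#'   settings used.
#' @export
run_search <- function(space, objective, max_evals = 50L, seed = 1L,
                       sampler = c("tpe", "random"), n_startup = 10L,
                       gamma = 0.25, n_candidates = 24L, log_file = NULL) {
  sampler <- match.arg(sampler)
  history <- vector("list", max_evals)
  for (i in seq_len(max_evals)) {
    enc <- local_seed(seed * 131071L + i, {
      if (sampler == "tpe" && i > n_startup)
        tpe_propose(space, history[seq_len(i - 1L)], gamma, n_candidates)
      else
        sample_encoding(space)
    })
    spec <- decode_encoding(space, enc)
    res <- tryCatch(objective(spec), error = function(e)
      list(score = -Inf, val_loss = Inf, error = conditionMessage(e)))
    if (is.numeric(res)) res <- list(score = res)
    trial <- list(trial_index = i, encoding = enc, spec = spec,
                  y = res$score, val_loss = res$val_loss %||% NA_real_,
                  error = res$error %||% NULL, seed = seed)
    history[[i]] <- trial
    if (!is.null(log_file)) {
      line <- jsonlite::toJSON(list(
        trial_index = i, y = trial$y, val_loss = trial$val_loss,
        error = trial$error, encoding = enc), auto_unbox = TRUE,
        digits = NA, null = "null")
      cat(line, "\n", file = log_file, append = TRUE, sep = "")
    }
  }
  ys <- vapply(history, `[[`, 0, "y")
  vl <- vapply(history, function(t) {
    v <- t$val_loss
    if (is.null(v) || is.na(v)) Inf else v
  }, 0)
  best <- history[[order(-ys, vl, seq_along(ys))[1]]]
  structure(list(best = best, trials = history, sampler = sampler,
                 max_evals = as.integer(max_evals), seed = as.integer(seed),
                 gamma = gamma, n_startup = as.integer(n_startup),
                 n_candidates = as.integer(n_candidates)),
            class = "locomode_search")
}

#' @export
print.locomode_search <- function(x, ...) {
  cat(sprintf("<locomode_search> %s, %d evaluations (seed %d)\n",
              x$sampler, x$max_evals, x$seed))
  cat(sprintf("  best trial %d: y = %.4f\n", x$best$trial_index, x$best$y))
  print(x$best$spec)
  invisible(x)
}

#' Evaluate one architecture on train/validation data
#'
#' Builds the spec's model, trains it for the trial budget (20 epochs in the
#' search protocol) with the spec's learning rate and batch size, and scores
#' it by validation macro F-measure. A spec the input shapes cannot support
#' (temporal collapse) propagates as an error, which [run_search()] records
#' as a failed trial.
#'
#' @param spec An [arch_spec()].
#' @param data List with `train` and `val` entries (window sets or named
#'   lists of window sets per modality).
#' @param epochs Training epochs (default 20).
#' @param seed Seed for initialisation and batch order.
#' @return A list with `spec`, `score` (macro F on validation), `val_loss`
#'   and the fitted model's history.
#' @export
objective_eval <- function(spec, data, epochs = 20L, seed = 1L) {
  inputs_tr <- dataset_inputs(data$train, names(spec$heads))
  if (any(vapply(inputs_tr, is.null, TRUE)))
    abort_("locomode_bad_argument", "training data missing a spec modality")
  shapes <- lapply(inputs_tr, function(x) dim(x)[2:3])
  model <- build_from_spec(spec, shapes, seed = seed)
  cfg <- train_config(initial_lr = spec$learning_rate,
                      batch_size = spec$batch_size, max_epochs = epochs,
                      seed = seed)
  sub_tr <- if (inherits(data$train, "window_set")) data$train
            else data$train[names(spec$heads)]
  sub_va <- if (inherits(data$val, "window_set")) data$val
            else data$val[names(spec$heads)]
  fit <- train_model(model, sub_tr, sub_va, cfg)
  rep <- evaluate_model(fit, sub_va)
  list(spec = spec, score = rep$macro$f_measure,
       val_loss = fit$best_val_loss, history = fit$history)
}
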