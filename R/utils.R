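# Internal helpers shared across modules.

#' @importFrom stats rnorm runif qnorm pnorm dnorm uniroot sd predict
#'   setNames aggregate
#' @importFrom utils modifyList packageVersion
NULL

# Raise a classed error so callers can distinguish failure modes.
abort_ <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "locomode_error")))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit hash of a character/numeric key, for per-trial seeds.
hash31 <- function(...) {
  key <- paste(unlist(list(...)), collapse = "\r")
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_json_ <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

write_json_ <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
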