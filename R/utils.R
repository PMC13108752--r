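#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n distinct rename across all_of pull
#' @importFrom stats pf pt qt sd quantile median rnorm runif splinefun setNames
#' @importFrom utils head tail
NULL

# Deterministic substream seeds: mix a base seed with string labels so that
# adding one consumer (e.g. a camera) never perturbs the draws of another.
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647L
  as.integer(h)
}

# Run `expr` under a named substream without disturbing the caller's RNG.
with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, ...))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  invisible(x)
}
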