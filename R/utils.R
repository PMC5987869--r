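#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded generators do not perturb the
#' surrounding random stream. A `NULL` seed evaluates `expr` unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-stage random seed from a global seed
#'
#' Deterministic substreams: toggling one pipeline stage must not shift the
#' randomness consumed by any other stage. Seeds stay below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character) or index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 7919) %%
               2147483647)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
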