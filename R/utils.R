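#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif quantile cor sd p.adjust phyper setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed (< 2^31) from a master seed and a stage name,
# so independent stage reruns stay reproducible.
derive_seed <- function(master, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 48271 + h) %% 2147483647)
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
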