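#' @keywords internal
#' @useDynLib mgcna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Derive a stage-specific seed from a global seed
#'
#' One global seed fans out to per-stage substreams by hashing the stage name,
#' so individual pipeline stages (simulation, rebalancing, splitting, model
#' initialization, training) are independently reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @param index Optional integer (e.g. fold or patient number).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  abort_if(!is_scalar(seed), "`seed` must be a single number")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 1299721 + as.numeric(index) * 7919) %%
               2147483647)
}

# Evaluate expr with a local RNG state; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Recursively apply f over parallel nested lists of numeric arrays.
param_map <- function(f, ...) {
  ps <- list(...)
  p1 <- ps[[1L]]
  if (is.list(p1)) {
    out <- lapply(seq_along(p1), function(i) {
      do.call(param_map, c(list(f), lapply(ps, `[[`, i)))
    })
    names(out) <- names(p1)
    out
  } else {
    do.call(f, ps)
  }
}

param_zeros_like <- function(p) param_map(function(x) x * 0, p)

param_dot <- function(p, q) {
  s <- 0
  walk <- function(a, b) {
    if (is.list(a)) for (i in seq_along(a)) walk(a[[i]], b[[i]])
    else s <<- s + sum(a * b)
  }
  walk(p, q)
  s
}

param_count <- function(p) {
  n <- 0L
  walk <- function(a) {
    if (is.list(a)) for (x in a) walk(x) else n <<- n + length(a)
  }
  walk(p)
  n
}
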