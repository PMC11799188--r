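# Small internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

tc_log <- function(fmt, ...) {
  if (isTRUE(getOption("tcgrad.verbose", FALSE))) message(sprintf(fmt, ...))
  invisible(NULL)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so seeded generators do not disturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Derive a distinct, reproducible substream seed from a base seed.
# Kept below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483629
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

# Pairwise-complete Pearson correlation of two vectors; errors on zero
# variance when `strict` is TRUE, otherwise returns NA.
pearson_pairwise <- function(x, y, strict = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("fewer than 3 pairwise-complete observations", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    if (strict) stop("zero variance in correlation input", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}
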