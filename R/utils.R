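# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed` and restores
#' the caller's RNG state afterwards, so that generators are pure functions of
#' their arguments and library users never lose their own random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed plus a stage label to a new 32-bit
#' seed, so every stochastic stage of a pipeline draws from an independent,
#' reproducible stream.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage.
#' @param index optional integer sub-index (e.g. a replicate counter).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (as.numeric(seed) %% 2147483647) * 48271 + h * 7919 + as.numeric(index) * 104729
  as.integer(val %% 2147483646) + 1L
}

# argument checks ------------------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name, closed_upper = TRUE) {
  hi_ok <- if (closed_upper) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || !hi_ok) {
    stop(sprintf("`%s` must be a fraction in [0, 1%s", name,
                 if (closed_upper) "]" else ")"), call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pearson correlation that errors informatively on degenerate input.
safe_cor <- function(x, y, what = "map") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) {
    stop("fewer than 3 defined pairs available for correlation", call. = FALSE)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(sprintf("correlation undefined: constant %s", what), call. = FALSE)
  }
  stats::cor(x, y)
}
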