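# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation helpers do
#' not perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# djb2 string hash; used only to tag peak lists with their acquisition
# parameters so a mismatch is detectable, not cryptographic.
str_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-decimal number formatting (never scientific); used by the text
# writers so output is byte-stable across runs.
fmt_num <- function(x, digits = 10L) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, scientific = FALSE, digits = digits, trim = TRUE)
  }, character(1))
  out
}
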