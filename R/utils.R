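# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic routines in the package draw their randomness from a
#' single integer master seed; per-school and per-replicate seeds are
#' derived deterministically so that partial re-runs are consistent.
#' The derivation is a multiplicative congruential step modulo
#' 2^31 - 1, so derived seeds always fit a 32-bit integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in 1..2147483646.
#' @export
derive_seed <- function(master, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  s <- (abs(master) %% m) * 48271 + (index %% m) * 69621 + 1
  as.integer(s %% (m - 1) + 1)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Numerically stable softmax.
softmax <- function(u) {
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

# Stable hash of an arbitrary R object via its deparsed source text.
object_hash <- function(x) {
  txt <- paste(deparse(x, control = c("exact")), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
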