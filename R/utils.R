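#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr` and
#' restores the previous state, so seeded operations never disturb the
#' session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
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

#' Derive a child seed from a master seed and a tag
#'
#' Deterministic arithmetic hash keeping every derived seed in the 32-bit
#' signed integer range, so one master seed reproducibly drives independent
#' per-stage and per-item RNG streams.
#'
#' @param master integer master seed.
#' @param tag character tag naming the stream.
#' @param index optional integer index within the stream.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag, index = 0L) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  v <- (abs(as.numeric(master)) %% 2147483647) * 69621 + h * 7919 + as.numeric(index) * 104729
  as.integer(v %% 2147483646) + 1L
}

# clamp numeric values into [lo, hi]
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
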