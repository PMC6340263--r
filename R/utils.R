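#' Run code with a temporarily seeded RNG
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so package functions never clobber the global stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps (master seed, stage name) to an integer below
#' 2^31, so every stochastic stage of the pipeline consumes its own stream.
#'
#' @param master integer master seed.
#' @param name character stage name.
#' @return integer sub-seed.
#' @export
derive_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(master) * 7919 + h * 104729) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angular differences to (-180, 180] degrees
#' @param x angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
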