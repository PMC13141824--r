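## Internal unit and validation helpers. All user-facing lengths are in
## micrometres; SI conversion happens here and nowhere else.

#' @keywords internal
.UM <- 1e-6

.asMetres <- function(x_um) x_um * .UM

.stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.checkPositive <- function(x, name) {
  .stopIfNot(is.numeric(x) && length(x) >= 1L && all(is.finite(x)) && all(x > 0),
             sprintf("'%s' must be finite and > 0", name))
  invisible(x)
}

.checkNonNegative <- function(x, name) {
  .stopIfNot(is.numeric(x) && all(is.finite(x)) && all(x >= 0),
             sprintf("'%s' must be finite and >= 0", name))
  invisible(x)
}

## Wrap an angle into (-pi, pi].
.wrapAngle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- a[a <= -pi] + 2 * pi
  a
}

## Deterministic child seeds for multi-replicate routines; stays well below
## .Machine$integer.max for any small parent seed.
.childSeeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% 2147483587L
}

## Run an expression under a fixed RNG state without disturbing the caller's.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
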