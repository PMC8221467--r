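# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_cm <- function(...) stop(..., call. = FALSE)

check_matrix3 <- function(x, what = "coordinate matrix") {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L) {
    stop_cm(what, " must be a numeric k x 3 matrix")
  }
  if (!all(is.finite(x))) stop_cm(what, " contains missing or non-finite values")
  invisible(x)
}
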