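# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# run `expr` with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# rolling min/max with reflected edges; half = (width - 1) / 2
roll_extreme <- function(x, width, fun) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  padded <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  vapply(seq_len(n), function(i) fun(padded[i:(i + 2L * half)]), numeric(1))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

stop_lwc <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "lwcspec_error")
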