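# internal helpers shared across modules

# Run code with a temporarily-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax along a vector; numerically stable
softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

assert_count <- function(x, name) {
  if (!is_count(x)) stop(sprintf("`%s` must be a positive integer, got %s",
                                 name, deparse(substitute(x))), call. = FALSE)
  invisible(as.integer(x))
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Moore-Penrose pseudo-inverse via SVD (used when normal equations are singular)
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
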