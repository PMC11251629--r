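#' Deterministic child seed derivation
#'
#' Derives a reproducible child seed from a root seed and an arbitrary set of
#' labels (strings or integers). Child streams are independent in the sense
#' that adding a new label combination never perturbs the draws of another:
#' each (root, labels) pair maps to its own seed, so e.g. adding a motor unit
#' to a pool leaves the random properties of the existing units untouched.
#'
#' A simple polynomial rolling hash over the decimal/UTF-8 expansion of the
#' labels, reduced modulo 2^31 - 1, is sufficient here: we need stable
#' stream separation, not cryptographic quality.
#'
#' @param root integer root seed.
#' @param ... labels (character or numeric scalars) identifying the stream.
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @export
child_seed <- function(root, ...) {
  labels <- list(...)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(root) %% m
  for (lab in labels) {
    codes <- if (is.character(lab)) {
      utf8ToInt(paste(lab, collapse = "\x1f"))
    } else {
      utf8ToInt(paste(format(lab, digits = 15), collapse = "\x1f"))
    }
    for (cc in codes) h <- (h * 131 + cc) %% m
    h <- (h * 2654435761) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the prior
#' RNG state, so library functions taking a `seed` argument do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
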