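# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' functions do not disturb the caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# canonical unordered pair key "a||b" with a < b
pair_key <- function(g1, g2) {
  a <- pmin(g1, g2)
  b <- pmax(g1, g2)
  paste(a, b, sep = "||")
}

# upper-triangle index pairs of 1..n as a 2-column matrix (i < j)
upper_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  cbind(i, j)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
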