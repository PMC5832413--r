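#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring the
#' caller's RNG state afterwards so package functions do not clobber the global
#' stream. `seed = NULL` evaluates `code` with the current stream.
#'
#' @param seed integer seed or NULL
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cosine similarity between the rows of a matrix
#'
#' @param x numeric matrix, one vector per row
#' @return symmetric matrix of pairwise cosine similarities
#' @keywords internal
cosine_rows <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-norm vector: ",
                          paste(rownames(x)[nrm == 0], collapse = ", "))
  s <- (x %*% t(x)) / outer(nrm, nrm)
  (s + t(s)) / 2
}
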