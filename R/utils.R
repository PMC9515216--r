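#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All
#' stochastic operations in the package route their randomness through
#' this helper so that cohorts, splits, initializations and batch orders
#' are pure functions of their declared seeds.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject seed stream; keeps values < 2^31.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 10007) %% 2147483629)
}

# Tiny stable rolling hash of an R object (hex string); used for run manifests.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopIfNot2d <- function(x, what = "pixels") {
  if (!is.matrix(x) || !is.numeric(x) || any(dim(x) < 1L))
    stop(what, " must be a non-empty numeric matrix", call. = FALSE)
}
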