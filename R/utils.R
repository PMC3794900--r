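`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and stream indices
#'
#' Deterministic integer hashing so that every (replicate, branch, purpose)
#' combination gets its own independent random stream while the whole
#' experiment stays reproducible from one master seed.  All arithmetic stays
#' below 2^53 so it is exact in doubles; results lie in 1..(2^31 - 2).
#'
#' @param master integer master seed
#' @param ... further integer stream indices
#' @return a scalar double holding an exact positive integer < 2^31
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (as.numeric(master) %% 2147483647) + 1
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  h + 1
}

# log-spaced snapshot grid (t = 0 is prepended by callers that want it)
logspace <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# run an expression with a local RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("ps%06d-%d", i, as.integer(Sys.time()) %% 100000L)
  }
})
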