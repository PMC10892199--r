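#' @useDynLib ecgstack, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif median quantile cor sd approx
#' @importFrom utils write.csv read.csv
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is required for stochastic operations",
         call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed; stays inside 32-bit range.
child_seed <- function(seed, index) {
  (as.integer(seed) * 1009L + as.integer(index) * 101L) %% 2147480000L
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}
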