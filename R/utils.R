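#' @useDynLib gpensemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd cor cov median quantile rnorm runif rpois rbinom
#'   setNames predict aggregate weighted.mean
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Deterministic child-seed derivation
#'
#' Derives a reproducible child seed from a global seed and an arbitrary set of
#' labels (population id, ratio index, replicate index, stage tag, ...) via a
#' polynomial string hash.  Identical inputs always give identical seeds;
#' distinct stage tags give distinct streams so that, e.g., the train/test
#' split and the MLP weight initialisation of the same scenario never share a
#' random stream.
#'
#' @param global_seed integer global seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(global_seed, ...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  key <- paste(c(as.character(as.integer(global_seed)), parts), collapse = "\x1f")
  bytes <- utf8ToInt(key)
  # two independent rolling hashes (multipliers chosen so h * m + b stays
  # exact in double precision), combined mod 2^31 - 1
  h1 <- 5381; h2 <- 7919
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 1073741789   # < 2^30, 131 * h1 < 2^53
    h2 <- (h2 * 137 + b) %% 1073741827
  }
  as.integer((h1 * 65537 + h2) %% 2147483647)
}

# Seeded evaluation that restores the caller's RNG state.
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
  expr
}
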