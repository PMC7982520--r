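#' @useDynLib erpdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var predict coef fft complete.cases
#' @importFrom utils head modifyList read.table write.table
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All randomized entry points funnel through this
# so that a single integer seed fixes every draw.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and a stage tag, keeping the result a
# valid 32-bit R integer. Deterministic, order-free mixing.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x > 0

sigmoid <- function(x) 1 / (1 + exp(-x))
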