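# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rexp rbinom median mad qlogis plogis sd
#'   quantile cor prcomp kmeans pchisq predict setNames
#' @importFrom utils head read.delim write.table
NULL

# Derive a stage-specific seed from a root seed. Keeps the result a valid
# 32-bit integer so set.seed() never overflows.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate an expression under a fixed seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Clip to [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopMsg <- function(...) stop(sprintf(...), call. = FALSE)

checkMatrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stopMsg("'%s' must be a numeric matrix", name)
  if (anyNA(x)) stopMsg("'%s' contains missing values", name)
  invisible(x)
}
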