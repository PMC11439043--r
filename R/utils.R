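#' @keywords internal
"_PACKAGE"

#' @useDynLib mitosel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim pchisq qchisq rnorm runif setNames anova coef logLik simulate
#' @importFrom utils read.delim write.table head tail modifyList read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

msg <- function(..., verbose = getOption("mitosel.verbose", TRUE)) {
  if (isTRUE(verbose)) message("mitosel: ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stopf("%s must be a single probability strictly inside (0, 1)", name)
  }
  invisible(x)
}
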