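## Internal helpers: argument checks and named random-number streams.

#' @importFrom methods new validObject is slot show
#' @importFrom stats rnorm runif rpois rlnorm rmultinom rgamma prcomp sd
#'   setNames coef fitted residuals predict AIC shapiro.test cor.test
#'   gaussian Gamma as.formula formula nobs qnorm
#' @importFrom utils read.csv write.csv head packageVersion
#' @importFrom mgcv gam summary.gam
#' @importFrom vegan diversity specnumber
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Derive a reproducible 31-bit sub-seed from a global seed and a stream
## name, so each sub-generator has its own stream: changing how one
## component consumes random numbers leaves the others untouched.
streamSeed <- function(seed, stream) {
  .assert(.is_number(seed), "seed must be a single finite number")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

## Evaluate `expr` under a named stream of the global seed, restoring the
## caller's RNG state afterwards.
withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(streamSeed(seed, stream))
  expr
}
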