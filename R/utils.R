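#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif pnorm setNames
#' @importFrom utils combn
NULL

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. Generators must be pure in (spec, seed).
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a per-stage child seed from a root seed; kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(stage) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(seed) * 48271 + offs) %% 2147483587)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
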