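#' @useDynLib coneUNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Run expr with a fixed RNG state, restoring the caller's state afterwards.
# Keeps generator functions deterministic without clobbering the session RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stage label, so pipeline
# stages can be rerun in isolation with reproducible, de-correlated streams.
childSeed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h * 131 + index) %% 2147483587) + 1L
}

stopIfNot2D <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Sample standard deviation (n - 1 denominator), NA-free by construction.
sampleSD <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
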