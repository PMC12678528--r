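#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous RNG state
#' so library internals never perturb the caller's random stream.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

wmlr_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wmlr_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic child seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483563) + 1L
}
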