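# Internal helpers shared across modules.

#' Run code with a locally scoped RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so library functions do not perturb user-level
#' reproducibility. A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed, so per-sample
# draws are independent of sample order.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lowbiome <- function(..., class) {
  stop(structure(
    class = c(class, "lowbiome_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
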