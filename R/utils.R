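#' @keywords internal
"_PACKAGE"

# Canonical wavelength grid: avian-visible range at 1 nm resolution.
CANONICAL_GRID <- 300:700

# Seven standard body regions; "undertail" is admitted only for
# parakeet-style layouts where undertail colors can be measured reliably.
STANDARD_REGIONS <- c("crown", "cheek", "throat", "upperparts",
                      "wing", "tail", "underparts")

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded package
#' operations never perturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed for operation `k` from a master seed,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
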