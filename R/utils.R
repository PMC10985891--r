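#' @useDynLib vessel3, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma predict
#' @importFrom utils head modifyList write.csv read.csv
NULL

# Run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-item seed derived from a master seed; kept < 2^31.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_v3 <- function(msg, class, ...) {
  stop(structure(class = c(class, "vessel3_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Coerce a 2-D or 3-D array to the canonical (H, W, C, N) tensor layout.
as_tensor4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_v3("expected a matrix or array, got a vector", "vessel3_shape_error")
  if (length(d) == 2) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3) dim(x) <- c(d, 1L)
  else if (length(d) != 4) stop_v3("expected 2-4 dimensions, got %d", "vessel3_shape_error", length(d))
  x
}

vessel_classes <- function() c("PA", "Ao", "SVC")
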