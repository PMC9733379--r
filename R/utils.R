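#' @keywords internal
#' @importFrom stats aggregate coef complete.cases dist lm quantile
#'   reformulate rexp rnorm rpois runif setNames step terms
"_PACKAGE"

## Condition constructors -----------------------------------------------------
## All user-facing errors carry a subclass so callers (and tests) can
## distinguish bad inputs from degenerate geometry or numeric failures.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cottoncanopy_validation_error", "cottoncanopy_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cottoncanopy_degenerate_error", "cottoncanopy_error")))
}

stop_numeric <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cottoncanopy_numeric_error", "cottoncanopy_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cottoncanopy_io_error", "cottoncanopy_error")))
}

## Seed scoping ---------------------------------------------------------------

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so reproducible generators never leak state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Tiny provenance hash (FNV-1a over the serialized object) so reports can be
## matched to the configuration that produced them without extra dependencies.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL))
  ## cheap vectorized digest (provenance tag, not cryptographic)
  w1 <- (seq_along(bytes) * 2654435761) %% 1000003
  h1 <- sum((bytes + 1) * w1) %% 2147483647
  h2 <- sum((bytes + 7) * rev(w1)) %% 65521
  sprintf("%08x%04x", h1, h2)
}

as_xyz_matrix <- function(points, what = "points") {
  m <- as.matrix(points)
  if (!is.numeric(m) || ncol(m) != 3)
    stop_validation("%s must be an n x 3 numeric matrix", what)
  if (anyNA(m)) stop_validation("%s contains missing coordinates", what)
  unname(m)
}
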