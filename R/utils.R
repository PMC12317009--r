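#' @keywords internal
"_PACKAGE"

#' @importFrom stats cov pf sd cor dist cmdscale rnorm runif rbinom median
#'   quantile p.adjust setNames aggregate approx
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; keeps every derived seed a valid
# 32-bit integer.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(synth = 11L, gli = 23L, borders = 37L, volumes = 53L,
               atlas = 71L, similarity = 89L, pipeline = 101L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 127L + off) %% .Machine$integer.max)
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
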