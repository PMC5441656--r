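#' @keywords internal
"_PACKAGE"

#' @useDynLib seqinfer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim dbeta dnorm rbeta rnorm rgamma pbeta plogis qlogis
#'   lm residuals cor pt sd median rbinom runif complete.cases setNames
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("seqinfer_config_error", "error", "condition")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("seqinfer_data_error", "error", "condition")))
}

stop_state <- function(msg) {
  stop(errorCondition(msg, class = c("seqinfer_state_error", "error", "condition")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit seeds derived from a master seed (kept < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
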