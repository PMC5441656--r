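#' Sequential-inference advantage (delta log-likelihood)
#'
#' The per-subject log-likelihood advantage of the best sequential-inference
#' model over pure filtering: max LL over S2-S5 minus the LL of S1. May be
#' negative when filtering predicts the subject's choices best.
#'
#' @param fits Named list of `seqfit` objects for S1..S5 (one subject).
#' @return The delta-LL value.
#' @export
compute_delta_ll <- function(fits) {
  need <- paste0("S", 1:5)
  miss <- setdiff(need, names(fits))
  if (length(miss) > 0)
    stop_data(paste("missing fit(s):", paste(miss, collapse = ", ")))
  ll <- vapply(fits[need], function(f) f$log_likelihood, numeric(1))
  max(ll[paste0("S", 2:5)]) - ll[["S1"]]
}

#' Inferred sequence length (L)
#'
#' The window length (model order) of the subject's best-fitting sequential
#' model by BIC under the larger-is-better convention; exact ties are broken
#' toward the shorter sequence.
#'
#' @param fits Named list of `seqfit` objects for S1..S5 (one subject).
#' @return An integer in 1..5.
#' @export
compute_sequence_length_L <- function(fits) {
  need <- paste0("S", 1:5)
  miss <- setdiff(need, names(fits))
  if (length(miss) > 0)
    stop_data(paste("missing fit(s):", paste(miss, collapse = ", ")))
  bic <- vapply(fits[need], function(f) f$bic, numeric(1))
  unname(which.max(bic))  # first maximum = smallest order among ties
}

#' Partial correlation controlling for covariates
#'
#' Product-moment correlation of the residuals of `x` and `y` after linear
#' removal of the covariates from both, with the p-value from the
#' t-distribution on `n - n_covariates - 2` degrees of freedom. Rows with any
#' missing value are dropped (listwise deletion). With no covariates this is
#' the plain correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional data frame (or matrix) of control variables.
#' @return A list with `estimate`, `p.value`, `df` and `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (length(x) != length(y)) stop_data("`x` and `y` must have equal length")
  ncov <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(x))
      stop_data("`covariates` must have one row per observation")
    ncov <- ncol(covariates)
    keep <- complete.cases(x, y, covariates)
  } else {
    keep <- complete.cases(x, y)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n <= ncov + 2) stop_data("too few complete observations")
  if (ncov > 0) {
    covariates <- covariates[keep, , drop = FALSE]
    x <- residuals(lm(x ~ ., data = covariates))
    y <- residuals(lm(y ~ ., data = covariates))
  }
  if (sd(x) == 0 || sd(y) == 0)
    stop_data("degenerate (constant) residuals; correlation undefined")
  r <- cor(x, y)
  df <- n - ncov - 2L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(estimate = r, p.value = 2 * pt(-abs(tval), df), df = df, n = n)
}
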