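#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects and estimates
#' the population frequencies of the candidate models by variational Bayes on
#' a Dirichlet-multinomial hierarchy. Iterates subject-responsibility and
#' Dirichlet-concentration updates to convergence, then reports the expected
#' posterior model probabilities and the exceedance probability of each model
#' (the probability that it is the most frequent model in the population).
#' For two models the exceedance probability is computed exactly from the
#' Beta CDF; otherwise by Monte-Carlo sampling of the Dirichlet posterior.
#'
#' @param evidence Subjects x models matrix of log model evidence (here,
#'   BIC/2 under the larger-is-better sign convention). Column names label
#'   the models.
#' @param alpha0 Prior Dirichlet counts (scalar or per-model vector;
#'   default 1, a uniform prior over model frequencies).
#' @param mc_samples Number of Monte-Carlo draws for exceedance probabilities
#'   with three or more models.
#' @param seed Seed for the Monte-Carlo draws.
#' @param tol,max_iter Convergence tolerance (max change in alpha) and
#'   iteration cap for the variational loop.
#' @return An object of class `bms_result`: `alpha` (posterior Dirichlet
#'   concentrations), `expected_prob`, `exceedance_prob`, `responsibilities`
#'   (subjects x models posterior assignment probabilities), `n_subjects`.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, mc_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  evidence <- as.matrix(evidence)
  if (!all(is.finite(evidence))) stop_data("`evidence` must be finite")
  n_sub <- nrow(evidence)
  n_mod <- ncol(evidence)
  if (n_mod < 2) stop_config("need at least 2 models to compare")
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, n_mod)
  if (length(alpha0) != n_mod || any(alpha0 <= 0))
    stop_config("`alpha0` must be positive, one value per model")

  alpha <- alpha0
  for (iter in seq_len(max_iter)) {
    lu <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  expected <- alpha / sum(alpha)
  if (n_mod == 2) {
    xp1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    xp <- c(xp1, 1 - xp1)
  } else {
    xp <- with_seed(seed, {
      draws <- matrix(rgamma(mc_samples * n_mod, shape = rep(alpha, each = mc_samples)),
                      mc_samples, n_mod)
      winners <- max.col(draws, ties.method = "first")
      tabulate(winners, nbins = n_mod) / mc_samples
    })
  }
  names(expected) <- names(xp) <- names(alpha) <- colnames(evidence)
  structure(list(alpha = alpha, expected_prob = expected,
                 exceedance_prob = xp, responsibilities = u,
                 n_subjects = n_sub, alpha0 = alpha0,
                 mc_samples = if (n_mod > 2) mc_samples else NA_integer_,
                 seed = seed),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("Random-effects model comparison over %d subjects:\n", x$n_subjects))
  tab <- rbind(`expected prob` = x$expected_prob,
               `exceedance prob` = x$exceedance_prob)
  print(round(tab, 4))
  invisible(x)
}

#' Per-subject posterior model probabilities
#'
#' Softmax of one subject's log model evidences under a uniform model prior.
#'
#' @param evidence_row Vector of log model evidences for one subject.
#' @return Probabilities summing to 1.
#' @export
subject_model_posteriors <- function(evidence_row) {
  if (!all(is.finite(evidence_row))) stop_data("evidences must be finite")
  w <- exp(evidence_row - max(evidence_row))
  w / sum(w)
}

#' Bayesian parameter averaging
#'
#' Convex combination of one subject's per-model parameter estimates,
#' weighted by the per-model posterior probabilities.
#'
#' @param params_by_model List (one element per model) of named parameter
#'   lists/vectors.
#' @param posteriors Per-model weights summing to 1.
#' @param parameters Which parameters to average (default: those present in
#'   every model with non-zero weight).
#' @return Named vector of averaged parameter values.
#' @export
bayesian_parameter_average <- function(params_by_model, posteriors,
                                       parameters = NULL) {
  if (length(params_by_model) != length(posteriors))
    stop_config("one weight per model required")
  if (abs(sum(posteriors) - 1) > 1e-8)
    stop_config("`posteriors` must sum to 1")
  active <- which(posteriors > 0)
  if (is.null(parameters)) {
    parameters <- Reduce(intersect, lapply(params_by_model[active], names))
    if (length(parameters) == 0)
      stop_config("models with non-zero weight share no parameters")
  }
  vapply(parameters, function(nm) {
    vals <- vapply(active, function(i) {
      v <- params_by_model[[i]][[nm]]
      if (is.null(v))
        stop_config(sprintf("parameter `%s` missing from a model with non-zero weight", nm))
      as.numeric(v)
    }, numeric(1))
    sum(vals * posteriors[active])
  }, numeric(1))
}
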