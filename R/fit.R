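#' Prior specification for MAP estimation
#'
#' Largely uninformative priors used for maximum a posteriori fitting:
#' Beta(1.1, 1.1) on every probability/rate parameter (r, v, phi, alpha) and
#' a normal prior on the log softmax precision, ln(gamma) ~ N(1, 0.25)
#' (variance 0.25). These mainly keep parameters away from extreme values.
#'
#' @param rate_shape1,rate_shape2 Beta shape parameters for rate priors.
#' @param log_gamma_mean,log_gamma_var Mean and variance of the normal prior
#'   on ln(gamma).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(rate_shape1 = 1.1, rate_shape2 = 1.1,
                       log_gamma_mean = 1, log_gamma_var = 0.25) {
  if (rate_shape1 <= 0 || rate_shape2 <= 0 || log_gamma_var <= 0)
    stop_config("prior shape/scale parameters must be strictly positive")
  structure(list(rate_shape1 = rate_shape1, rate_shape2 = rate_shape2,
                 log_gamma_mean = log_gamma_mean, log_gamma_var = log_gamma_var),
            class = "prior_spec")
}

# Names of the free parameters of a model (gamma last when free).
free_param_names <- function(model) {
  base <- switch(model$name,
                 S1 = , S2 = , S3 = , S4 = , S5 = c("r", "v"),
                 Q1 = , Q2 = "phi",
                 Q3 = c("alpha_gain", "alpha_loss"))
  if (model$gamma_mode == "free") c(base, "gamma") else base
}

# Build a full parameter object (with effective gamma) from a named list of
# free parameter values.
assemble_params <- function(model, values) {
  gamma <- if (model$gamma_mode == "fixed") model$fixed_gamma else values[["gamma"]]
  if (model$family == "sequential") {
    structure(list(r = values[["r"]], v = values[["v"]], gamma = gamma),
              class = "hmm_parameters")
  } else if (model$variant == "Q3") {
    structure(list(phi = NULL, alpha_gain = values[["alpha_gain"]],
                   alpha_loss = values[["alpha_loss"]], gamma = gamma),
              class = "q_parameters")
  } else {
    structure(list(phi = values[["phi"]], alpha_gain = NULL, alpha_loss = NULL,
                   gamma = gamma), class = "q_parameters")
  }
}

model_loglik <- function(model, params, trials) {
  gamma <- effective_gamma(model, params)
  if (model$family == "sequential") {
    seq_inference_cpp(model$order, params$r, params$v, gamma,
                      trials$cue, trials$action, trials$outcome,
                      FALSE)$log_likelihood
  } else {
    vnum <- as.integer(substr(model$variant, 2, 2))
    rates <- if (model$variant == "Q3") c(params$alpha_gain, params$alpha_loss)
             else c(params$phi, params$phi)
    q_inference_cpp(vnum, rates[1], rates[2], gamma,
                    trials$cue, trials$action, trials$outcome,
                    FALSE)$log_likelihood
  }
}

#' Log posterior density of model parameters
#'
#' The action log-likelihood of the trial sequence plus the log prior
#' densities of the free parameters, evaluated in natural parameter space
#' (the normal prior applies to ln(gamma)). Evaluation exactly on the support
#' boundary of a rate parameter returns `-Inf`.
#'
#' @param model Model name or `model_spec`.
#' @param params Parameter object ([hmm_parameters()] / [q_parameters()]) or
#'   named list covering the model's free parameters.
#' @param trials Trial data frame (`cue`, `action`, `outcome`).
#' @param priors A [prior_spec()].
#' @return The log posterior (up to the model-evidence constant).
#' @export
log_posterior <- function(model, params, trials, priors = prior_spec()) {
  model <- as_model_spec(model)
  trials <- validate_trials(trials)
  pnames <- free_param_names(model)
  vals <- unclass(params)
  miss <- setdiff(pnames, names(vals)[!vapply(vals, is.null, logical(1))])
  if (length(miss) > 0)
    stop_config(paste("missing free parameter(s):", paste(miss, collapse = ", ")))
  rate_names <- setdiff(pnames, "gamma")
  for (nm in rate_names) {
    if (vals[[nm]] < 0 || vals[[nm]] > 1)
      stop_config(sprintf("`%s` outside [0, 1]", nm))
  }
  lp <- 0
  for (nm in rate_names)
    lp <- lp + dbeta(vals[[nm]], priors$rate_shape1, priors$rate_shape2, log = TRUE)
  if ("gamma" %in% pnames) {
    if (vals$gamma < 0) stop_config("`gamma` must be non-negative")
    lp <- lp + if (vals$gamma == 0) -Inf else
      dnorm(log(vals$gamma), priors$log_gamma_mean, sqrt(priors$log_gamma_var),
            log = TRUE)
  }
  if (!is.finite(lp)) return(-Inf)
  prm <- assemble_params(model, vals)
  lp + model_loglik(model, prm, trials)
}

#' BIC under the larger-is-better sign convention
#'
#' `BIC = 2 * log_likelihood - k * ln(n)`; larger values favour the model.
#'
#' @param log_likelihood Total action log-likelihood at the MAP estimate.
#' @param k Number of free parameters.
#' @param n_trials Number of trials (data points).
#' @return The BIC value.
#' @export
compute_bic <- function(log_likelihood, k, n_trials) {
  if (n_trials < 1) stop_config("`n_trials` must be >= 1")
  2 * log_likelihood - k * log(n_trials)
}

#' McFadden pseudo-R-squared against the coin-flip baseline
#'
#' `1 - LL / (n * ln 0.5)`: 0 for chance-level prediction, 1 for perfect
#' prediction of every choice.
#'
#' @inheritParams compute_bic
#' @return The pseudo-R-squared.
#' @export
compute_pseudo_r2 <- function(log_likelihood, n_trials) {
  if (n_trials < 1) stop_config("`n_trials` must be >= 1")
  1 - log_likelihood / (n_trials * log(0.5))
}

transform_to_unconstrained <- function(values, pnames) {
  vapply(pnames, function(nm) {
    if (nm == "gamma") log(values[[nm]]) else qlogis(values[[nm]])
  }, numeric(1))
}

transform_to_natural <- function(theta, pnames) {
  out <- lapply(seq_along(pnames), function(i) {
    if (pnames[i] == "gamma") exp(theta[i]) else plogis(theta[i])
  })
  names(out) <- pnames
  out
}

default_start <- function(pnames) {
  defaults <- c(r = 0.1, v = 0.8, phi = 0.3, alpha_gain = 0.3, alpha_loss = 0.3,
                gamma = exp(1))
  as.list(defaults[pnames])
}

draw_start <- function(pnames, priors) {
  out <- lapply(pnames, function(nm) {
    if (nm == "gamma") exp(rnorm(1, priors$log_gamma_mean, sqrt(priors$log_gamma_var)))
    else rbeta(1, priors$rate_shape1, priors$rate_shape2)
  })
  names(out) <- pnames
  out
}

#' MAP fit of one model to one subject
#'
#' Maximises the log posterior with the Nelder-Mead simplex on transformed
#' coordinates (logit for rates, log for the precision; the objective is
#' evaluated in natural space, with no Jacobian term -- the transform is a
#' search mechanism only). Multiple restarts are used: the first from a fixed
#' canonical start (or `init` if supplied), the rest drawn from the priors
#' under the given seed, so the fit is deterministic.
#'
#' @param model Model name or `model_spec` (gamma free or fixed).
#' @param trials Trial data frame for one subject (at least 20 trials).
#' @param priors A [prior_spec()].
#' @param n_starts Number of optimizer restarts.
#' @param seed Integer seed controlling the restart draws.
#' @param init Optional named list of natural-space starting values for the
#'   first restart (e.g. a previous fit's estimates).
#' @param control Passed to [stats::optim()] (defaults: `maxit = 1000`,
#'   `reltol = 1e-6`).
#' @return An object of class `seqfit`: `model`, `map_params`,
#'   `log_likelihood`, `log_posterior`, `k`, `n_trials`, `bic`, `pseudo_r2`,
#'   `convergence` (TRUE if the best restart converged), `restarts`,
#'   `best_start`.
#' @export
fit_map <- function(model, trials, priors = prior_spec(), n_starts = 10,
                    seed = 1, init = NULL, control = list()) {
  model <- as_model_spec(model)
  trials <- validate_trials(trials)
  if (nrow(trials) < 20) stop_data("need at least 20 trials to fit")
  pnames <- free_param_names(model)
  control <- utils::modifyList(list(maxit = 1000, reltol = 1e-6), control)

  # Fast objective: same quantity as log_posterior(), with validation and
  # dispatch hoisted out of the optimizer loop.
  cue <- trials$cue; act <- trials$action; out <- trials$outcome
  gamma_fixed <- if (model$gamma_mode == "fixed") model$fixed_gamma else NULL
  is_gamma <- pnames == "gamma"
  n_free <- length(pnames)
  if (model$family == "sequential") {
    ord <- model$order
    ll_fun <- function(nat) seq_inference_cpp(ord, nat[1], nat[2],
                                              gamma_fixed %||% nat[3],
                                              cue, act, out, FALSE)$log_likelihood
  } else {
    vnum <- as.integer(substr(model$variant, 2, 2))
    ll_fun <- if (model$variant == "Q3") {
      function(nat) q_inference_cpp(vnum, nat[1], nat[2], gamma_fixed %||% nat[3],
                                    cue, act, out, FALSE)$log_likelihood
    } else {
      function(nat) q_inference_cpp(vnum, nat[1], nat[1], gamma_fixed %||% nat[2],
                                    cue, act, out, FALSE)$log_likelihood
    }
  }
  sh1 <- priors$rate_shape1; sh2 <- priors$rate_shape2
  g_mean <- priors$log_gamma_mean; g_sd <- sqrt(priors$log_gamma_var)
  objective <- function(theta) {
    nat <- ifelse(is_gamma, exp(theta), plogis(theta))
    lp <- sum(dbeta(nat[!is_gamma], sh1, sh2, log = TRUE))
    if (any(is_gamma)) lp <- lp + dnorm(theta[is_gamma], g_mean, g_sd, log = TRUE)
    if (!is.finite(lp)) return(1e10)
    lp <- lp + ll_fun(nat)
    if (!is.finite(lp)) 1e10 else -lp
  }

  starts <- with_seed(seed, {
    s <- vector("list", n_starts)
    s[[1]] <- if (is.null(init)) default_start(pnames) else {
      st <- default_start(pnames)
      st[intersect(names(init), pnames)] <- init[intersect(names(init), pnames)]
      st
    }
    if (n_starts > 1)
      for (i in 2:n_starts) s[[i]] <- draw_start(pnames, priors)
    s
  })

  best <- NULL
  for (i in seq_along(starts)) {
    theta0 <- transform_to_unconstrained(starts[[i]], pnames)
    fit <- if (length(pnames) == 1L) {
      optim(theta0, objective, method = "Brent", lower = -20, upper = 20,
            control = control[names(control) != "reltol"])
    } else {
      optim(theta0, objective, method = "Nelder-Mead", control = control)
    }
    if (is.null(best) || fit$value < best$fit$value)
      best <- list(fit = fit, start = i)
  }
  if (best$fit$value >= 1e10)
    stop_data("all optimizer restarts failed to find a finite posterior")

  map_vals <- transform_to_natural(best$fit$par, pnames)
  full_params <- assemble_params(model, map_vals)
  ll <- model_loglik(model, full_params, trials)
  k <- length(pnames)
  n <- nrow(trials)
  structure(list(
    model = model,
    map_params = map_vals,
    params = full_params,
    log_likelihood = ll,
    log_posterior = -best$fit$value,
    k = k,
    n_trials = n,
    bic = compute_bic(ll, k, n),
    pseudo_r2 = compute_pseudo_r2(ll, n),
    convergence = best$fit$convergence == 0,
    restarts = n_starts,
    best_start = best$start,
    seed = seed
  ), class = "seqfit")
}

#' @export
print.seqfit <- function(x, ...) {
  pars <- paste(sprintf("%s = %.4g", names(x$map_params), unlist(x$map_params)),
                collapse = ", ")
  cat(sprintf("%s MAP fit (%d trials): LL = %.3f, BIC = %.3f, pseudo-R2 = %.3f\n  %s\n",
              x$model$name, x$n_trials, x$log_likelihood, x$bic, x$pseudo_r2, pars))
  invisible(x)
}

#' Two-pass cohort fit with fixed softmax precision
#'
#' Pass 1 fits every subject with the precision gamma free; the group mean of
#' the gamma estimates (in natural space) is then clamped, and pass 2 refits
#' every subject with gamma fixed and one fewer free parameter. The per-
#' subject BIC comparison between the two passes is reported; fixing gamma
#' mitigates the redundancy between precision and the other parameters.
#'
#' @param model Model name or `model_spec`.
#' @param cohort A `seqinfer_cohort`, a long trial data frame with a
#'   `subject_id` column, or a named list of per-subject trial data frames
#'   (at least 2 subjects).
#' @param priors A [prior_spec()].
#' @param n_starts Optimizer restarts per fit.
#' @param seed Master seed; per-subject fitting seeds are derived from it.
#' @param control Passed to [fit_map()].
#' @return An object of class `seqfit_cohort`: `model`, `fixed_gamma`,
#'   `pass1` and `pass2` (named lists of `seqfit`), and `comparison` (data
#'   frame of per-subject BICs for the free- and fixed-gamma fits).
#' @export
fit_cohort_fixed_gamma <- function(model, cohort, priors = prior_spec(),
                                   n_starts = 10, seed = 1, control = list()) {
  model <- as_model_spec(model)
  subjects <- as_cohort_list(cohort)
  if (length(subjects) < 2) stop_config("need at least 2 subjects")

  # the same fitting seed for every subject: identical logs then yield
  # identical fits, and the data supply the between-subject variation
  model_free <- model_spec(model$name, gamma_mode = "free")
  pass1 <- lapply(seq_along(subjects), function(i) {
    fit_map(model_free, subjects[[i]], priors, n_starts, seed = seed,
            control = control)
  })
  names(pass1) <- names(subjects)
  gammas <- vapply(pass1, function(f) f$map_params$gamma, numeric(1))
  fixed_gamma <- mean(gammas)

  model_fixed <- model_spec(model$name, gamma_mode = "fixed",
                            fixed_gamma = fixed_gamma)
  pass2 <- lapply(seq_along(subjects), function(i) {
    fit_map(model_fixed, subjects[[i]], priors, n_starts, seed = seed,
            init = pass1[[i]]$map_params, control = control)
  })
  names(pass2) <- names(subjects)

  comparison <- data.frame(
    subject_id = names(subjects),
    bic_free = vapply(pass1, function(f) f$bic, numeric(1)),
    bic_fixed = vapply(pass2, function(f) f$bic, numeric(1)),
    row.names = NULL
  )
  comparison$favours_fixed <- comparison$bic_fixed > comparison$bic_free

  structure(list(model = model$name, fixed_gamma = fixed_gamma,
                 pass1 = pass1, pass2 = pass2, comparison = comparison),
            class = "seqfit_cohort")
}

#' @export
print.seqfit_cohort <- function(x, ...) {
  cat(sprintf("Cohort fit of %s: %d subjects, fixed gamma = %.4g; fixed gamma favoured in %d/%d subjects\n",
              x$model, nrow(x$comparison), x$fixed_gamma,
              sum(x$comparison$favours_fixed), nrow(x$comparison)))
  invisible(x)
}

as_cohort_list <- function(cohort) {
  if (inherits(cohort, "seqinfer_cohort")) return(split_cohort(cohort$trials))
  if (is.data.frame(cohort)) return(split_cohort(cohort))
  if (is.list(cohort)) {
    if (is.null(names(cohort)) || anyDuplicated(names(cohort)))
      stop_config("per-subject list must have unique names")
    return(cohort)
  }
  stop_config("cannot interpret `cohort`")
}
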