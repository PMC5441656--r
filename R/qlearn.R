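#' Action-value (delta-rule) model parameters
#'
#' Parameters for the Q-learning baselines: a single learning rate `phi`
#' (variants Q1 and Q2) or separate rates for positive and negative feedback
#' (`alpha_gain`, `alpha_loss`; variant Q3), plus the softmax precision.
#'
#' @param phi Learning rate in \[0, 1\] (Q1/Q2).
#' @param alpha_gain,alpha_loss Valence-specific learning rates in \[0, 1\]
#'   (Q3).
#' @param gamma Softmax precision, non-negative.
#' @return An object of class `q_parameters`.
#' @export
q_parameters <- function(phi = NULL, alpha_gain = NULL, alpha_loss = NULL,
                         gamma) {
  for (nm in c("phi", "alpha_gain", "alpha_loss")) {
    val <- get(nm)
    if (!is.null(val) && !is_prob(val))
      stop_config(sprintf("`%s` must be a rate in [0, 1]", nm))
  }
  if (!(length(gamma) == 1L && is.numeric(gamma) && is.finite(gamma) && gamma >= 0))
    stop_config("`gamma` must be a non-negative real")
  structure(list(phi = phi, alpha_gain = alpha_gain, alpha_loss = alpha_loss,
                 gamma = gamma), class = "q_parameters")
}

#' Initial action-value table
#'
#' A 2x2 table of expected reward indexed (cue, action), initialised at the
#' indifference point 0.5.
#'
#' @param init Initial value for every state-action pair, in \[0, 1\].
#' @return A 2x2 numeric matrix.
#' @export
q_value_table <- function(init = 0.5) {
  if (!is_prob(init)) stop_config("`init` must be in [0, 1]")
  matrix(init, 2L, 2L, dimnames = list(cue = c("1", "2"), action = c("1", "2")))
}

#' Delta-rule value update
#'
#' Updates the action-value table after one trial. `Q1` moves only the chosen
#' (cue, action) pair toward the reward (1 for positive, 0 for negative
#' feedback). `Q2` and `Q3` exploit the task's anti-correlated structure and
#' update all four pairs simultaneously: the chosen pair and its logical twin
#' (other cue, other action) move toward the reward, while the two mirrored
#' pairs move toward its complement, each with its own prediction error. `Q3`
#' uses `alpha_gain` after positive and `alpha_loss` after negative feedback
#' for all four updates.
#'
#' @param table A 2x2 value table as from [q_value_table()].
#' @param cue,action,outcome Trial codes in {1, 2}.
#' @param params A `q_parameters` object.
#' @param variant `"Q1"`, `"Q2"` or `"Q3"`.
#' @return The updated value table.
#' @examples
#' q_update(q_value_table(), 1, 1, 1, q_parameters(phi = 0.2, gamma = 1), "Q1")
#' @export
q_update <- function(table, cue, action, outcome, params, variant) {
  if (!variant %in% c("Q1", "Q2", "Q3")) stop_config("invalid `variant`")
  check_codes(cue, action, outcome, what = "cue/action/outcome codes")
  R <- if (outcome == 1L) 1 else 0
  rate <- if (variant == "Q3") {
    if (outcome == 1L) params$alpha_gain else params$alpha_loss
  } else {
    params$phi
  }
  if (is.null(rate)) stop_config("required learning rate missing for this variant")
  if (variant == "Q1") {
    table[cue, action] <- table[cue, action] + rate * (R - table[cue, action])
  } else {
    oy <- 3L - cue; oa <- 3L - action
    table[cue, action] <- table[cue, action] + rate * (R - table[cue, action])
    table[oy, oa] <- table[oy, oa] + rate * (R - table[oy, oa])
    table[cue, oa] <- table[cue, oa] + rate * ((1 - R) - table[cue, oa])
    table[oy, action] <- table[oy, action] + rate * ((1 - R) - table[oy, action])
  }
  table
}

#' Softmax action probability from a value table
#'
#' @param table A 2x2 value table.
#' @param cue Cue code in {1, 2}.
#' @param gamma Softmax precision.
#' @return The probability of action 1 for the given cue.
#' @export
q_action_prob <- function(table, cue, gamma) {
  if (!cue %in% c(1L, 2L)) stop_data("`cue` must be 1 or 2")
  if (gamma < 0) stop_config("`gamma` must be non-negative")
  plogis(gamma * (table[cue, 1L] - table[cue, 2L]))
}

#' Run a delta-rule model over a trial sequence
#'
#' Applies Q1, Q2 or Q3 to a time-ordered trial log with values initialised
#' at 0.5, returning per-trial action probabilities and the total action
#' log-likelihood.
#'
#' @param variant `"Q1"`, `"Q2"` or `"Q3"` (or a `model_spec`).
#' @param params A `q_parameters` object.
#' @param trials Trial data frame with `cue`, `action`, `outcome` columns.
#' @param engine `"cpp"` (default) or `"r"` (stepwise reference built from
#'   [q_update()] and [q_action_prob()]).
#' @param keep_values If `TRUE`, also return the per-trial value tables
#'   (matrix with columns Q11, Q12, Q21, Q22, recorded after each update).
#' @return A list of class `q_inference` with `log_likelihood`, `trace` and
#'   optionally `values`.
#' @export
run_q_inference <- function(variant, params, trials, engine = c("cpp", "r"),
                            keep_values = FALSE) {
  engine <- match.arg(engine)
  model <- as_model_spec(variant)
  if (model$family != "action_value")
    stop_config("run_q_inference() handles Q models; see run_inference()")
  trials <- validate_trials(trials)
  gamma <- effective_gamma(model, params)
  vnum <- as.integer(substr(model$variant, 2, 2))
  rates <- switch(model$variant,
                  Q1 = , Q2 = c(params$phi, params$phi),
                  Q3 = c(params$alpha_gain, params$alpha_loss))
  if (any(vapply(rates, is.null, logical(1))) || length(rates) < 2)
    stop_config("learning rate(s) missing for this variant")
  if (engine == "cpp") {
    res <- q_inference_cpp(vnum, rates[1], rates[2], gamma,
                           trials$cue, trials$action, trials$outcome,
                           keep_values)
    p_action1 <- res$p_action1
    ll <- res$log_likelihood
    values <- if (keep_values) res$values_matrix else NULL
  } else {
    n <- nrow(trials)
    tab <- q_value_table()
    p_action1 <- numeric(n)
    values <- if (keep_values) matrix(NA_real_, n, 4L) else NULL
    ll <- 0
    for (t in seq_len(n)) {
      p_action1[t] <- q_action_prob(tab, trials$cue[t], gamma)
      p_ch <- if (trials$action[t] == 1L) p_action1[t] else 1 - p_action1[t]
      ll <- ll + log(p_ch)
      tab <- q_update(tab, trials$cue[t], trials$action[t], trials$outcome[t],
                      params, model$variant)
      if (keep_values) values[t, ] <- c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    }
  }
  if (keep_values && !is.null(values))
    colnames(values) <- c("Q11", "Q12", "Q21", "Q22")
  out <- list(
    log_likelihood = ll,
    trace = data.frame(
      trial = seq_len(nrow(trials)),
      cue = trials$cue, action = trials$action, outcome = trials$outcome,
      p_action1 = p_action1,
      p_chosen = ifelse(trials$action == 1L, p_action1, 1 - p_action1)
    ),
    values = values,
    model = model,
    params = params
  )
  class(out) <- "q_inference"
  out
}

#' @export
print.q_inference <- function(x, ...) {
  cat(sprintf("%s over %d trials: log-likelihood = %.4f\n",
              x$model$name, nrow(x$trace), x$log_likelihood))
  invisible(x)
}
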