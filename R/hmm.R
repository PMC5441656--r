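#' Hidden Markov model parameters for the reversal task
#'
#' Bundles the three parameters of the belief-updating models: the subjective
#' per-trial reversal probability `r` (the off-diagonal of the state
#' transition matrix), the cue validity `v` (the probability that feedback is
#' veridical given the chosen action), and the softmax precision `gamma`
#' (inverse temperature; `gamma = 0` yields random choice).
#'
#' @param r Probability of a context reversal between consecutive trials, in
#'   \[0, 1\].
#' @param v Cue validity: probability of positive feedback after a correct
#'   choice (and of negative feedback after an incorrect one), in \[0, 1\].
#' @param gamma Softmax precision, a non-negative real.
#' @return An object of class `hmm_parameters`.
#' @examples
#' hmm_parameters(r = 0.05, v = 0.8, gamma = 3)
#' @export
hmm_parameters <- function(r, v, gamma) {
  if (!is_prob(r)) stop_config("`r` must be a probability in [0, 1]")
  if (!is_prob(v)) stop_config("`v` must be a probability in [0, 1]")
  if (!(length(gamma) == 1L && is.numeric(gamma) && is.finite(gamma) && gamma >= 0))
    stop_config("`gamma` must be a non-negative real")
  structure(list(r = r, v = v, gamma = gamma), class = "hmm_parameters")
}

#' @export
print.hmm_parameters <- function(x, ...) {
  cat(sprintf("HMM parameters: r = %.4g, v = %.4g, gamma = %.4g\n",
              x$r, x$v, x$gamma))
  invisible(x)
}

#' State transition matrix
#'
#' The 2x2 transition matrix over task contexts: the context repeats with
#' probability `1 - r` and reverses with probability `r`.
#'
#' @param r Per-trial reversal probability.
#' @return A 2x2 matrix with `E[i, j] = P(x_t = j | x_{t-1} = i)`.
#' @export
transition_matrix <- function(r) {
  if (!is_prob(r)) stop_config("`r` must be a probability in [0, 1]")
  matrix(c(1 - r, r, r, 1 - r), 2L, 2L, byrow = TRUE)
}

#' Observation model
#'
#' The probability of positive feedback given context, action and cue:
#' `A[x, a, y] = P(o = 1 | x, a, y)`, equal to `v` when the action is correct
#' for (x, y) and `1 - v` otherwise. The correct action is `a = x` for cue
#' `y = 1` and `a = 3 - x` for cue `y = 2`.
#'
#' @param v Cue validity.
#' @return A 2x2x2 array indexed (context, action, cue).
#' @export
observation_tensor <- function(v) {
  if (!is_prob(v)) stop_config("`v` must be a probability in [0, 1]")
  array(c(v, 1 - v, 1 - v, v,      # y = 1: correct iff a == x
          1 - v, v, v, 1 - v),     # y = 2: correct iff a == 3 - x
        dim = c(2L, 2L, 2L),
        dimnames = list(context = c("1", "2"), action = c("1", "2"),
                        cue = c("1", "2")))
}

#' Correct action for a context/cue pair
#'
#' @param context Latent task context code(s) in {1, 2}.
#' @param cue Cue code(s) in {1, 2}.
#' @return Action code(s) in {1, 2}.
#' @export
correct_action <- function(context, cue) {
  ifelse(cue == 1L, context, 3L - context)
}

check_codes <- function(..., what = "codes") {
  vals <- c(...)
  if (!all(vals %in% c(1L, 2L)))
    stop_data(sprintf("%s must all be in {1, 2}", what))
  invisible(TRUE)
}

# Likelihood of one observed outcome as a function of the latent context:
# c(P(o | x = 1, a, y), P(o | x = 2, a, y)).
outcome_likelihood <- function(cue, action, outcome, v) {
  conc1 <- action == correct_action(1L, cue)   # action correct if x = 1
  if (outcome == 1L) {
    c(if (conc1) v else 1 - v, if (conc1) 1 - v else v)
  } else {
    c(if (conc1) 1 - v else v, if (conc1) v else 1 - v)
  }
}

#' Model specification
#'
#' Identifies one member of the model family: sequential-inference models
#' `S1`-`S5` (`S1` is pure Bayesian filtering; `Sn` performs joint inference
#' over the current and the `n - 1` most recent past states) or action-value
#' models `Q1`-`Q3`. Also records whether the softmax precision is a free
#' parameter or clamped to a fixed value.
#'
#' @param name Model label: one of `"S1"`..`"S5"`, `"Q1"`..`"Q3"`.
#' @param gamma_mode `"free"` (precision estimated) or `"fixed"`.
#' @param fixed_gamma The clamped precision value; required iff
#'   `gamma_mode = "fixed"`.
#' @return An object of class `model_spec` with fields `name`, `family`
#'   (`"sequential"` or `"action_value"`), `order` (for sequential models),
#'   `variant` (for action-value models), `gamma_mode` and `fixed_gamma`.
#' @examples
#' model_spec("S2")
#' model_spec("Q3", gamma_mode = "fixed", fixed_gamma = 2.5)
#' @export
model_spec <- function(name, gamma_mode = c("free", "fixed"), fixed_gamma = NULL) {
  gamma_mode <- match.arg(gamma_mode)
  name <- toupper(as.character(name))
  if (!name %in% c(paste0("S", 1:5), paste0("Q", 1:3)))
    stop_config("`name` must be one of S1..S5, Q1..Q3")
  if (gamma_mode == "fixed") {
    if (is.null(fixed_gamma) || !(is.numeric(fixed_gamma) && fixed_gamma >= 0))
      stop_config("`fixed_gamma` must be a non-negative real when gamma_mode = 'fixed'")
  } else if (!is.null(fixed_gamma)) {
    stop_config("`fixed_gamma` must be absent when gamma_mode = 'free'")
  }
  family <- if (startsWith(name, "S")) "sequential" else "action_value"
  structure(list(
    name = name,
    family = family,
    order = if (family == "sequential") as.integer(substr(name, 2, 2)) else NULL,
    variant = if (family == "action_value") name else NULL,
    gamma_mode = gamma_mode,
    fixed_gamma = fixed_gamma
  ), class = "model_spec")
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) return(model)
  if (is.character(model) && length(model) == 1L) return(model_spec(model))
  if (is.numeric(model) && length(model) == 1L) return(model_spec(paste0("S", model)))
  stop_config("cannot interpret `model` as a model specification")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s (%s, gamma %s%s)\n", x$name, x$family, x$gamma_mode,
              if (x$gamma_mode == "fixed") sprintf(" at %.4g", x$fixed_gamma) else ""))
  invisible(x)
}

#' Initialise a windowed belief state
#'
#' Creates the empty belief for a sequential-inference model of the given
#' order: no states in the window yet and a uniform boundary belief over the
#' (notional) state preceding the first trial.
#'
#' @param order Window length `n` of the model, an integer in 1..5.
#' @return An object of class `belief_state` with fields `order`,
#'   `window_length`, `joint` (probability vector of length
#'   `2^window_length`, indexed by the binary expansion of the window's state
#'   sequence with the oldest state in the most significant position and
#'   state 1 mapping to bit 0), `boundary` (2-vector over the state
#'   immediately preceding the window) and `factors` (the retained trials'
#'   cue/action/outcome records).
#' @export
init_belief <- function(order) {
  if (!is_count(order) || order < 1 || order > 5)
    stop_config("`order` must be an integer in 1..5")
  structure(list(
    order = as.integer(order),
    window_length = 0L,
    joint = numeric(0),
    boundary = c(0.5, 0.5),
    factors = list()
  ), class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("Belief state: order %d, window length %d\n", x$order, x$window_length))
  if (x$window_length > 0) {
    cat("  joint:", paste(sprintf("%.4f", x$joint), collapse = " "), "\n")
    cat("  current-state marginal:",
        paste(sprintf("%.4f", marginal_current_state(x)), collapse = " "), "\n")
  }
  cat("  boundary:", paste(sprintf("%.4f", x$boundary), collapse = " "), "\n")
  invisible(x)
}

# One transition-extension of a joint: append the next state.
# joint over w states -> joint over w + 1 states (unnormalised in = out scale).
extend_joint <- function(joint, r) {
  w2 <- length(joint)
  last_bit <- (seq_len(w2) - 1L) %% 2L               # current-state bit of each entry
  stay <- ifelse(last_bit == 0L, 1 - r, r)           # P(new = 1 | last)
  as.vector(rbind(joint * stay, joint * (1 - stay)))
}

#' Advance the inference window by one trial
#'
#' Appends the upcoming trial's latent state to the joint belief. While the
#' window is still filling (fewer than `order` trials seen) the joint is
#' simply extended through the transition matrix. Once full, the oldest state
#' is evicted: its marginal becomes the new frozen boundary belief, the joint
#' over the retained states is rebuilt by re-multiplying their stored
#' outcome-likelihood factors against the boundary-propagated prior, and the
#' result is extended for the new state. The returned joint is normalised.
#'
#' @param belief A `belief_state`.
#' @param params An `hmm_parameters` object.
#' @return The advanced `belief_state` (window includes the new trial's
#'   state, for which no outcome has yet been incorporated).
#' @export
advance_window <- function(belief, params) {
  stopifnot(inherits(belief, "belief_state"))
  r <- params$r
  w <- belief$window_length
  if (w > 0 && length(belief$joint) != 2^w)
    stop_state("joint length inconsistent with window length")

  if (w == 0L) {
    joint <- belief$boundary[1] * c(1 - r, r) + belief$boundary[2] * c(r, 1 - r)
  } else if (w < belief$order) {
    joint <- extend_joint(belief$joint, r)
  } else {
    # Evict the oldest state.
    msb <- (seq_len(2^w) - 1L) %/% 2^(w - 1L)
    boundary <- c(sum(belief$joint[msb == 0L]), sum(belief$joint[msb == 1L]))
    boundary <- boundary / sum(boundary)
    belief$boundary <- boundary
    belief$factors <- belief$factors[-1L]
    # Rebuild the joint over the retained states: boundary-propagated prior
    # times each retained trial's likelihood factor, in order; then extend
    # for the new state. (For order 1 there are no retained states and the
    # boundary propagation directly yields the new state's prior.)
    joint <- boundary[1] * c(1 - r, r) + boundary[2] * c(r, 1 - r)
    facs <- belief$factors
    if (length(facs) > 0) {
      f <- facs[[1L]]
      lik <- outcome_likelihood(f$cue, f$action, f$outcome, params$v)
      joint <- joint * lik
      if (length(facs) > 1) {
        for (i in 2:length(facs)) {
          joint <- extend_joint(joint, r)
          f <- facs[[i]]
          lik <- outcome_likelihood(f$cue, f$action, f$outcome, params$v)
          cur <- (seq_along(joint) - 1L) %% 2L
          joint <- joint * lik[cur + 1L]
        }
      }
      joint <- extend_joint(joint, r)
    }
  }
  belief$joint <- joint / sum(joint)
  belief$window_length <- min(w + 1L, belief$order)
  belief
}

#' Incorporate a trial's outcome into the belief
#'
#' Multiplies every joint entry by the outcome likelihood evaluated at that
#' entry's current-state value, renormalises, and appends the trial's
#' (cue, action, outcome) record to the stored factors used by later window
#' rebuilds.
#'
#' @param belief A `belief_state` that was just advanced for this trial.
#' @param cue,action,outcome Trial codes in {1, 2}.
#' @param params An `hmm_parameters` object.
#' @return The updated `belief_state`.
#' @export
incorporate_outcome <- function(belief, cue, action, outcome, params) {
  stopifnot(inherits(belief, "belief_state"))
  check_codes(cue, action, outcome, what = "cue/action/outcome codes")
  if (belief$window_length < 1L)
    stop_state("window is empty; advance it before incorporating an outcome")
  lik <- outcome_likelihood(cue, action, outcome, params$v)
  cur <- (seq_along(belief$joint) - 1L) %% 2L
  joint <- belief$joint * lik[cur + 1L]
  s <- sum(joint)
  if (s <= 0) stop_data("outcome has zero likelihood under the model")
  belief$joint <- joint / s
  belief$factors <- c(belief$factors,
                      list(list(cue = cue, action = action, outcome = outcome)))
  belief
}

#' Marginal belief over the current state
#'
#' Sums the joint over all past states in the window, returning the belief
#' over the current latent context.
#'
#' @param belief A `belief_state` with a non-empty window.
#' @return A 2-vector `c(P(x = 1), P(x = 2))` summing to 1.
#' @export
marginal_current_state <- function(belief) {
  stopifnot(inherits(belief, "belief_state"))
  if (belief$window_length < 1L) stop_state("window is empty")
  cur <- (seq_along(belief$joint) - 1L) %% 2L
  c(sum(belief$joint[cur == 0L]), sum(belief$joint[cur == 1L]))
}

#' Softmax action probability from a state belief
#'
#' Maps the predictive belief over the current context into the probability
#' of responding "old" (action 1) under the softmax decision rule: for cue
#' `y = 1`, `P(a = i) = exp(gamma p_i) / sum_j exp(gamma p_j)`; for `y = 2`
#' the complement.
#'
#' @param marginal Predictive 2-vector over the current context (computed
#'   after advancing the window, before incorporating the trial's outcome).
#' @param cue Cue code in {1, 2}.
#' @param gamma Softmax precision.
#' @return The probability of action 1.
#' @examples
#' predict_action_prob(c(0.8, 0.2), cue = 1, gamma = 3)  # ~0.8581
#' @export
predict_action_prob <- function(marginal, cue, gamma) {
  if (!cue %in% c(1L, 2L)) stop_data("`cue` must be 1 or 2")
  p1 <- plogis(gamma * (marginal[[1]] - marginal[[2]]))
  if (cue == 1L) p1 else 1 - p1
}

#' Run belief updating and choice prediction over a trial sequence
#'
#' Applies a sequential-inference model to a time-ordered trial log: for each
#' trial the window is advanced, the predictive action probability for the
#' recorded action is computed, and the outcome is incorporated. Returns
#' per-trial predictive and posterior context beliefs, action probabilities,
#' and the total action log-likelihood.
#'
#' @param model A `model_spec` with `family = "sequential"`, a model name
#'   such as `"S2"`, or a bare order in 1..5.
#' @param params An `hmm_parameters` object.
#' @param trials A data frame with columns `cue`, `action`, `outcome` (codes
#'   in {1, 2}), time-ordered.
#' @param engine `"cpp"` (compiled recursion, default) or `"r"` (reference
#'   implementation composed from [advance_window()] and
#'   [incorporate_outcome()]).
#' @param keep_joints If `TRUE`, also return the per-trial posterior joint
#'   distributions (a list of probability vectors).
#' @return A list of class `seq_inference` with elements `log_likelihood`,
#'   `trace` (data frame: `trial`, `cue`, `action`, `outcome`, `pred_p1`,
#'   `post_p1`, `p_action1`, `p_chosen`) and optionally `joints`.
#' @examples
#' trials <- data.frame(cue = c(1, 1), action = c(1, 1), outcome = c(1, 1))
#' run_inference("S2", hmm_parameters(0.05, 0.8, 3), trials)$trace
#' @export
run_inference <- function(model, params, trials, engine = c("cpp", "r"),
                          keep_joints = FALSE) {
  engine <- match.arg(engine)
  model <- as_model_spec(model)
  if (model$family != "sequential")
    stop_config("run_inference() handles sequential models; see run_q_inference()")
  trials <- validate_trials(trials)
  gamma <- effective_gamma(model, params)
  if (engine == "cpp") {
    res <- seq_inference_cpp(model$order, params$r, params$v, gamma,
                             trials$cue, trials$action, trials$outcome,
                             keep_joints)
    joints <- NULL
    if (keep_joints) {
      J <- res$joints_matrix
      joints <- lapply(seq_len(nrow(J)), function(t) {
        v <- J[t, ]
        v[!is.na(v)]
      })
    }
    out <- list(
      log_likelihood = res$log_likelihood,
      trace = data.frame(
        trial = seq_len(nrow(trials)),
        cue = trials$cue, action = trials$action, outcome = trials$outcome,
        pred_p1 = res$pred_p1, post_p1 = res$post_p1,
        p_action1 = res$p_action1,
        p_chosen = ifelse(trials$action == 1L, res$p_action1, 1 - res$p_action1)
      ),
      joints = joints
    )
  } else {
    out <- run_inference_r(model$order, params, trials, gamma, keep_joints)
  }
  out$model <- model
  out$params <- params
  class(out) <- "seq_inference"
  out
}

effective_gamma <- function(model, params) {
  if (identical(model$gamma_mode, "fixed")) model$fixed_gamma else params$gamma
}

run_inference_r <- function(order, params, trials, gamma, keep_joints = FALSE) {
  n <- nrow(trials)
  b <- init_belief(order)
  pred_p1 <- post_p1 <- p_action1 <- numeric(n)
  joints <- if (keep_joints) vector("list", n) else NULL
  ll <- 0
  for (t in seq_len(n)) {
    b <- advance_window(b, params)
    m <- marginal_current_state(b)
    pred_p1[t] <- m[1]
    p_action1[t] <- predict_action_prob(m, trials$cue[t], gamma)
    p_ch <- if (trials$action[t] == 1L) p_action1[t] else 1 - p_action1[t]
    ll <- ll + log(p_ch)
    b <- incorporate_outcome(b, trials$cue[t], trials$action[t],
                             trials$outcome[t], params)
    post_p1[t] <- marginal_current_state(b)[1]
    if (keep_joints) joints[[t]] <- b$joint
  }
  list(
    log_likelihood = ll,
    trace = data.frame(
      trial = seq_len(n),
      cue = trials$cue, action = trials$action, outcome = trials$outcome,
      pred_p1 = pred_p1, post_p1 = post_p1, p_action1 = p_action1,
      p_chosen = ifelse(trials$action == 1L, p_action1, 1 - p_action1)
    ),
    joints = joints
  )
}

#' @export
print.seq_inference <- function(x, ...) {
  cat(sprintf("%s inference over %d trials: log-likelihood = %.4f\n",
              x$model$name, nrow(x$trace), x$log_likelihood))
  invisible(x)
}

validate_trials <- function(trials) {
  if (!is.data.frame(trials)) stop_data("`trials` must be a data frame")
  need <- c("cue", "action", "outcome")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    stop_data(paste("`trials` is missing column(s):", paste(miss, collapse = ", ")))
  if (nrow(trials) == 0) stop_data("`trials` has no rows")
  for (col in need) {
    vals <- trials[[col]]
    bad <- which(!vals %in% c(1L, 2L))
    if (length(bad) > 0)
      stop_data(sprintf("column `%s` has a code outside {1, 2} at row %d",
                        col, bad[1]))
    trials[[col]] <- as.integer(vals)
  }
  trials
}
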