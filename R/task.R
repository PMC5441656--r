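#' Probabilistic reversal task configuration
#'
#' Holds the task constants: total trial count, number of sessions (runs),
#' feedback reliability, and the performance-triggered reversal rule (if the
#' proportion of gains over the most recent `trigger_window` trials strictly
#' exceeds `trigger_threshold`, a reversal of the task-relevant category is
#' implemented within the next `reversal_lag_min`..`reversal_lag_max` trials).
#'
#' @param n_trials Total number of trials across all sessions.
#' @param n_sessions Number of sessions; trials are split evenly and the
#'   latent context and trigger window continue across session boundaries.
#' @param feedback_reliability Probability that feedback is veridical, in
#'   \[0.5, 1\].
#' @param trigger_window Number of most recent trials inspected by the
#'   reversal trigger.
#' @param trigger_threshold Gain proportion that must be strictly exceeded to
#'   schedule a reversal, in (0, 1).
#' @param reversal_lag_min,reversal_lag_max Bounds (in trials) of the uniform
#'   lag between trigger and implemented reversal.
#' @param initial_context `"random"` (fair coin), `"face"` (context 1) or
#'   `"house"` (context 2).
#' @param cue_schedule `"iid_uniform"` (each cue a fair coin) or `"balanced"`
#'   (equal cue counts within each session, order shuffled).
#' @return An object of class `task_config`.
#' @examples
#' task_config()  # the default 128-trial, 4-session task
#' @export
task_config <- function(n_trials = 128L, n_sessions = 4L,
                        feedback_reliability = 0.85,
                        trigger_window = 10L, trigger_threshold = 0.80,
                        reversal_lag_min = 1L, reversal_lag_max = 3L,
                        initial_context = c("random", "face", "house"),
                        cue_schedule = c("iid_uniform", "balanced")) {
  initial_context <- match.arg(initial_context)
  cue_schedule <- match.arg(cue_schedule)
  if (!is_count(n_trials)) stop_config("`n_trials` must be a positive integer")
  if (!is_count(n_sessions)) stop_config("`n_sessions` must be a positive integer")
  if (!is_prob(feedback_reliability) || feedback_reliability < 0.5)
    stop_config("`feedback_reliability` must be in [0.5, 1]")
  if (!is_count(trigger_window)) stop_config("`trigger_window` must be a positive integer")
  if (!(is_prob(trigger_threshold) && trigger_threshold > 0 && trigger_threshold < 1))
    stop_config("`trigger_threshold` must be in (0, 1)")
  if (!is_count(reversal_lag_min) || !is_count(reversal_lag_max) ||
      reversal_lag_min > reversal_lag_max)
    stop_config("need 1 <= reversal_lag_min <= reversal_lag_max")
  if (n_trials < trigger_window)
    stop_config("`n_trials` must be at least `trigger_window`")
  structure(list(
    n_trials = as.integer(n_trials), n_sessions = as.integer(n_sessions),
    feedback_reliability = feedback_reliability,
    trigger_window = as.integer(trigger_window),
    trigger_threshold = trigger_threshold,
    reversal_lag_min = as.integer(reversal_lag_min),
    reversal_lag_max = as.integer(reversal_lag_max),
    initial_context = initial_context, cue_schedule = cue_schedule
  ), class = "task_config")
}

#' Fixed benchmark policies
#'
#' Simple reference policies for exercising the task generator: always choose
#' the correct action, always the wrong one, or choose uniformly at random.
#'
#' @param type `"correct"`, `"wrong"` or `"random"`.
#' @return A task agent usable with [generate_session()].
#' @export
fixed_policy <- function(type = c("correct", "wrong", "random")) {
  type <- match.arg(type)
  act <- switch(type,
    correct = function(cue, correct) correct,
    wrong = function(cue, correct) 3L - correct,
    random = function(cue, correct) if (runif(1) < 0.5) 1L else 2L)
  structure(list(act = act,
                 observe = function(cue, action, outcome) invisible(NULL),
                 reset = function() invisible(NULL),
                 trace = function() NULL),
            class = "seqinfer_agent")
}

#' Model-based task agent
#'
#' Wraps any implemented model (S1-S5 or Q1-Q3) as a closed-loop agent: on
#' each trial it computes its predictive action probabilities, samples an
#' action, and updates its internal beliefs or values from the feedback.
#' Per-trial belief/value traces are retained and available via
#' `agent$trace()` after a run.
#'
#' @param model Model name, order, or `model_spec`.
#' @param params `hmm_parameters` (S models) or `q_parameters` (Q models).
#' @return A task agent usable with [generate_session()].
#' @export
model_agent <- function(model, params) {
  model <- as_model_spec(model)
  gamma <- effective_gamma(model, params)
  env <- new.env(parent = emptyenv())
  reset <- function() {
    if (model$family == "sequential") env$belief <- init_belief(model$order)
    else env$table <- q_value_table()
    env$pred_p1 <- env$post_p1 <- env$p_action1 <- numeric(0)
  }
  reset()
  act <- function(cue, correct) {
    if (model$family == "sequential") {
      env$belief <- advance_window(env$belief, params)
      m <- marginal_current_state(env$belief)
      p1 <- predict_action_prob(m, cue, gamma)
      env$pred_p1 <- c(env$pred_p1, m[1])
    } else {
      p1 <- q_action_prob(env$table, cue, gamma)
      env$pred_p1 <- c(env$pred_p1, NA_real_)
    }
    env$p_action1 <- c(env$p_action1, p1)
    if (runif(1) < p1) 1L else 2L
  }
  observe <- function(cue, action, outcome) {
    if (model$family == "sequential") {
      env$belief <- incorporate_outcome(env$belief, cue, action, outcome, params)
      env$post_p1 <- c(env$post_p1, marginal_current_state(env$belief)[1])
    } else {
      env$table <- q_update(env$table, cue, action, outcome, params, model$variant)
      env$post_p1 <- c(env$post_p1, NA_real_)
    }
    invisible(NULL)
  }
  trace <- function() {
    if (length(env$p_action1) == 0) return(NULL)
    data.frame(trial = seq_along(env$p_action1), pred_p1 = env$pred_p1,
               post_p1 = env$post_p1, p_action1 = env$p_action1)
  }
  structure(list(act = act, observe = observe, reset = reset, trace = trace,
                 model = model, params = params),
            class = "seqinfer_agent")
}

as_agent <- function(policy) {
  if (inherits(policy, "seqinfer_agent")) return(policy)
  if (is.function(policy)) {
    return(structure(list(act = policy,
                          observe = function(cue, action, outcome) invisible(NULL),
                          reset = function() invisible(NULL),
                          trace = function() NULL),
                     class = "seqinfer_agent"))
  }
  stop_config("`policy` must be a seqinfer_agent or a function(cue, correct)")
}

#' Simulate one probabilistic reversal session set
#'
#' Runs the task closed-loop with an agent policy: each trial a cue is drawn,
#' the policy chooses an action, feedback is veridical with probability
#' `feedback_reliability`, and performance-triggered reversals flip the latent
#' context. A reversal is scheduled (at a uniform lag of
#' `reversal_lag_min`..`reversal_lag_max` trials) whenever the gain proportion
#' over the last `trigger_window` outcomes strictly exceeds
#' `trigger_threshold`; the trailing gain window is then reset and no further
#' trigger fires while a reversal is pending. Sessions are concatenated with
#' full context and trigger continuity.
#'
#' @param config A [task_config()].
#' @param policy A task agent (see [model_agent()], [fixed_policy()]) or a
#'   function `(cue, correct_action) -> action`.
#' @param seed Integer seed; all session randomness flows from it.
#' @return A data frame of trial records: `trial`, `session`, `cue`, `action`,
#'   `outcome`, `true_state`, `reversal_flag`, with the config and seed kept
#'   as attributes.
#' @examples
#' s <- generate_session(task_config(), fixed_policy("correct"), seed = 1)
#' mean(s$outcome == 1)   # close to the 0.85 feedback reliability
#' @export
generate_session <- function(config, policy, seed) {
  if (!inherits(config, "task_config")) stop_config("`config` must be a task_config")
  agent <- as_agent(policy)
  agent$reset()
  n <- config$n_trials
  with_seed(seed, {
    x <- switch(config$initial_context,
                face = 1L, house = 2L,
                random = if (runif(1) < 0.5) 1L else 2L)
    session_of <- ceiling(seq_len(n) * config$n_sessions / n)
    cues <- if (config$cue_schedule == "iid_uniform") {
      ifelse(runif(n) < 0.5, 1L, 2L)
    } else {
      unlist(lapply(split(seq_len(n), session_of), function(idx) {
        k <- length(idx)
        base <- rep(c(1L, 2L), length.out = k)
        base[sample.int(k)]
      }), use.names = FALSE)
    }
    action <- outcome <- true_state <- integer(n)
    reversal_flag <- logical(n)
    trailing <- integer(0)
    pending <- NA_integer_
    lags <- seq(config$reversal_lag_min, config$reversal_lag_max)
    for (t in seq_len(n)) {
      if (!is.na(pending) && pending == t) {
        x <- 3L - x
        reversal_flag[t] <- TRUE
        pending <- NA_integer_
      }
      true_state[t] <- x
      corr <- correct_action(x, cues[t])
      a <- agent$act(cues[t], corr)
      if (length(a) != 1L || !a %in% c(1L, 2L))
        stop_data(sprintf("policy returned an out-of-range action at trial %d", t))
      action[t] <- as.integer(a)
      veridical <- runif(1) < config$feedback_reliability
      correct <- action[t] == corr
      outcome[t] <- if (correct == veridical) 1L else 2L
      agent$observe(cues[t], action[t], outcome[t])
      trailing <- c(trailing, outcome[t])
      if (length(trailing) > config$trigger_window)
        trailing <- trailing[-1L]
      if (is.na(pending) && length(trailing) == config$trigger_window &&
          mean(trailing == 1L) > config$trigger_threshold) {
        lag <- lags[sample.int(length(lags), 1L)]
        pending <- t + lag
        trailing <- integer(0)
      }
    }
    out <- data.frame(trial = seq_len(n), session = session_of, cue = cues,
                      action = action, outcome = outcome,
                      true_state = true_state, reversal_flag = reversal_flag)
    attr(out, "config") <- config
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a model-driven subject
#'
#' Convenience wrapper: builds a [model_agent()] for the given model and runs
#' [generate_session()] closed-loop. The agent's per-trial belief/value trace
#' is attached as the `"trace"` attribute.
#'
#' @param model Model name, order, or `model_spec` (S1-S5, Q1-Q3).
#' @param params Model parameters.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A trial data frame as from [generate_session()].
#' @examples
#' tr <- simulate_agent("S2", hmm_parameters(0.05, 0.8, 3), task_config(), seed = 1)
#' head(attr(tr, "trace"))
#' @export
simulate_agent <- function(model, params, config = task_config(), seed) {
  agent <- model_agent(model, params)
  out <- generate_session(config, agent, seed)
  attr(out, "trace") <- agent$trace()
  attr(out, "model") <- agent$model$name
  out
}

#' Cohort specification for synthetic-data studies
#'
#' @param n_subjects Number of subjects.
#' @param model Generating model for every subject (single value) or a list
#'   with one entry per subject.
#' @param params Generating parameters, single or per subject.
#' @param master_seed Integer master seed; per-subject seeds are derived from
#'   it deterministically.
#' @param ids Optional subject identifiers (must be unique).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, model, params, master_seed,
                        ids = sprintf("sub%02d", seq_len(n_subjects))) {
  if (!is_count(n_subjects)) stop_config("`n_subjects` must be a positive integer")
  if (anyDuplicated(ids)) stop_config("duplicate subject ids")
  if (length(ids) != n_subjects) stop_config("`ids` must have length `n_subjects`")
  rep_per_subject <- function(x) {
    if (is.list(x) && !inherits(x, c("model_spec", "hmm_parameters", "q_parameters")))
      { if (length(x) != n_subjects) stop_config("per-subject list has wrong length"); x }
    else rep(list(x), n_subjects)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 model = rep_per_subject(model),
                 params = rep_per_subject(params),
                 master_seed = as.integer(master_seed),
                 ids = as.character(ids)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Simulates every subject of a [cohort_spec()] on the task, deterministically
#' given the master seed, and records the generating model and parameters per
#' subject (the ground truth for recovery studies).
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @return A list of class `seqinfer_cohort` with `trials` (one data frame,
#'   all subjects, leading `subject_id` column) and `manifest` (named list of
#'   `model`, `parameters`, `seed` per subject).
#' @export
generate_cohort <- function(spec, config = task_config()) {
  if (!inherits(spec, "cohort_spec")) stop_config("`spec` must be a cohort_spec")
  seeds <- derive_seeds(spec$master_seed, spec$n_subjects)
  per <- vector("list", spec$n_subjects)
  manifest <- vector("list", spec$n_subjects)
  names(manifest) <- spec$ids
  for (i in seq_len(spec$n_subjects)) {
    model <- as_model_spec(spec$model[[i]])
    tr <- simulate_agent(model, spec$params[[i]], config, seed = seeds[i])
    tr <- cbind(subject_id = spec$ids[i], tr, stringsAsFactors = FALSE)
    per[[i]] <- tr
    manifest[[i]] <- list(model = model$name,
                          parameters = unclass(spec$params[[i]]),
                          seed = seeds[i])
  }
  structure(list(trials = do.call(rbind, per), manifest = manifest,
                 master_seed = spec$master_seed),
            class = "seqinfer_cohort")
}

#' @export
print.seqinfer_cohort <- function(x, ...) {
  models <- vapply(x$manifest, function(m) m$model, character(1))
  cat(sprintf("Synthetic cohort: %d subjects, %d trials each (models: %s)\n",
              length(x$manifest), sum(x$trials$subject_id == names(x$manifest)[1]),
              paste(unique(models), collapse = ", ")))
  invisible(x)
}

# Split a long trial log into a named per-subject list.
split_cohort <- function(trials) {
  if (!"subject_id" %in% names(trials))
    return(list(sub01 = trials))
  split(trials, factor(trials$subject_id, levels = unique(trials$subject_id)))
}

#' Proportion of correct choices
#'
#' Correctness is defined by the actual task contingency: the action matching
#' [correct_action()] for the trial's true context and cue.
#'
#' @param trials Trial data frame containing `true_state` (and `subject_id`
#'   when `by = "subject"`).
#' @param by `"trial"`: proportion over all trials with a binomial standard
#'   error; `"subject"`: mean of per-subject proportions with the standard
#'   error over subjects.
#' @return A list with `proportion_correct`, `se` and `n`.
#' @export
summarize_accuracy <- function(trials, by = c("trial", "subject")) {
  by <- match.arg(by)
  if (!"true_state" %in% names(trials) || all(is.na(trials$true_state)))
    stop_data("`trials` must contain the true latent context (`true_state`)")
  correct <- trials$action == correct_action(trials$true_state, trials$cue)
  if (by == "trial") {
    p <- mean(correct)
    list(proportion_correct = p,
         se = sqrt(p * (1 - p) / length(correct)),
         n = length(correct))
  } else {
    if (!"subject_id" %in% names(trials))
      stop_data("per-subject accuracy needs a `subject_id` column")
    per <- tapply(correct, trials$subject_id, mean)
    list(proportion_correct = mean(per),
         se = stats::sd(per) / sqrt(length(per)),
         n = length(per),
         per_subject = per)
  }
}
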