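#' Enumeration oracle for windowed sequential inference
#'
#' Independently recomputes, for every trial, the joint posterior over the
#' inference window by explicit summation over all assignments of the window
#' states plus the boundary state. The boundary belief is defined exactly as
#' in [advance_window()]: uniform while the window is filling, thereafter the
#' marginal of the evicted state taken from the previous trial's posterior.
#' Intended as a test oracle for the recursive implementation; it shares no
#' code with it beyond the observation-tensor definition.
#'
#' @param order Model order (window length), 1..5.
#' @param params An `hmm_parameters` object.
#' @param trials Trial data frame with `cue`, `action`, `outcome` columns.
#' @return A list with `joints` (per-trial posterior joint vectors),
#'   `pred_p1`, `post_p1`, `boundaries` (per-trial boundary beliefs used) and
#'   `log_likelihood`.
#' @export
enumeration_oracle <- function(order, params, trials) {
  if (!is_count(order) || order < 1 || order > 5)
    stop_config("`order` must be an integer in 1..5")
  trials <- validate_trials(trials)
  n_tr <- nrow(trials)
  r <- params$r
  A <- observation_tensor(params$v)
  E <- transition_matrix(r)

  # Per-trial likelihood pairs from the observation tensor.
  likmat <- matrix(0, n_tr, 2L)
  for (t in seq_len(n_tr)) {
    p_pos <- A[, trials$action[t], trials$cue[t]]
    likmat[t, ] <- if (trials$outcome[t] == 1L) p_pos else 1 - p_pos
  }

  # Assignment matrices: for window length w, all 2^(w+1) assignments of
  # (boundary state, window states); column 1 = boundary, column w+1 = newest.
  states_mat <- function(m) {
    idx <- 0:(2^m - 1)
    vapply(seq_len(m), function(i) as.integer((idx %/% 2^(m - i)) %% 2) + 1L,
           integer(2^m))
  }
  assign_mats <- lapply(1:(order + 1L), states_mat)
  # Transition-chain product along each assignment (independent of data).
  chain_prods <- lapply(assign_mats, function(S) {
    m <- ncol(S)
    p <- rep(1, nrow(S))
    if (m >= 2) for (i in 1:(m - 1)) p <- p * E[cbind(S[, i], S[, i + 1])]
    p
  })

  joints <- vector("list", n_tr)
  pred_p1 <- post_p1 <- numeric(n_tr)
  boundaries <- matrix(0, n_tr, 2L)
  boundary <- c(0.5, 0.5)
  ll <- 0
  for (t in seq_len(n_tr)) {
    w <- min(order, t)
    S <- assign_mats[[w + 1L]]
    weights <- boundary[S[, 1L]] * chain_prods[[w + 1L]]
    # Likelihoods of the retained (already-observed) trials, oldest first.
    win_trials <- (t - w + 1L):t
    for (i in seq_len(w - 1L))
      weights <- weights * likmat[win_trials[i], S[, i + 1L]]
    # Predictive marginal over the current state (before trial t's outcome).
    cur <- S[, w + 1L]
    pred <- c(sum(weights[cur == 1L]), sum(weights[cur == 2L]))
    pred <- pred / sum(pred)
    pred_p1[t] <- pred[1]
    p1 <- plogis(params$gamma * (pred[1] - pred[2]))
    p_act1 <- if (trials$cue[t] == 1L) p1 else 1 - p1
    ll <- ll + log(if (trials$action[t] == 1L) p_act1 else 1 - p_act1)
    # Posterior joint including trial t's outcome.
    weights <- weights * likmat[t, cur]
    joint_idx <- (0:(nrow(S) - 1L)) %% 2^w
    joint <- as.vector(rowsum(weights, joint_idx))
    joint <- joint / sum(joint)
    joints[[t]] <- joint
    post_p1[t] <- sum(joint[(seq_along(joint) - 1L) %% 2L == 0L])
    boundaries[t, ] <- boundary
    # Boundary for the next trial: evict the oldest state once the window is full.
    if (w == order) {
      oldest <- (seq_along(joint) - 1L) %/% 2^(w - 1L)
      boundary <- c(sum(joint[oldest == 0L]), sum(joint[oldest == 1L]))
      boundary <- boundary / sum(boundary)
    }
  }
  list(joints = joints, pred_p1 = pred_p1, post_p1 = post_p1,
       boundaries = boundaries, log_likelihood = ll)
}

#' Textbook forward filter
#'
#' The standard predict-update Bayesian filter over the current context,
#' implemented directly from the transition matrix and observation tensor.
#' Serves as an independent oracle for the order-1 sequential model.
#'
#' @inheritParams enumeration_oracle
#' @return A list with `pred_p1`, `post_p1` and `log_likelihood`.
#' @export
forward_filter <- function(params, trials) {
  trials <- validate_trials(trials)
  n_tr <- nrow(trials)
  E <- transition_matrix(params$r)
  A <- observation_tensor(params$v)
  b <- c(0.5, 0.5)
  pred_p1 <- post_p1 <- numeric(n_tr)
  ll <- 0
  for (t in seq_len(n_tr)) {
    pred <- as.vector(b %*% E)
    pred_p1[t] <- pred[1]
    p1 <- plogis(params$gamma * (pred[1] - pred[2]))
    p_act1 <- if (trials$cue[t] == 1L) p1 else 1 - p1
    ll <- ll + log(if (trials$action[t] == 1L) p_act1 else 1 - p_act1)
    p_pos <- A[, trials$action[t], trials$cue[t]]
    lik <- if (trials$outcome[t] == 1L) p_pos else 1 - p_pos
    b <- pred * lik
    b <- b / sum(b)
    post_p1[t] <- b[1]
  }
  list(pred_p1 = pred_p1, post_p1 = post_p1, log_likelihood = ll)
}
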