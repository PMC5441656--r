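# Shared fixtures: all synthetic, generated in code.

random_trials <- function(n, seed) {
  set.seed(seed)
  data.frame(cue = sample(1:2, n, TRUE),
             action = sample(1:2, n, TRUE),
             outcome = sample(1:2, n, TRUE))
}

random_hmm_params <- function(seed) {
  set.seed(seed)
  hmm_parameters(r = runif(1, 0.01, 0.5),
                 v = runif(1, 0.55, 0.95),
                 gamma = runif(1, 0, 8))
}

# Constructed observation sequences in the style of the belief-trace
# simulations: a stable block under context 1 followed by a reversal, and a
# stable block with a single misleading outcome. Cue and action are held at 1
# so outcomes alone drive beliefs.
reversal_sequence <- function(n_stable = 15, n_after = 15) {
  data.frame(cue = 1L, action = 1L,
             outcome = c(rep(1L, n_stable), rep(2L, n_after)))
}

misleading_sequence <- function(n_stable = 15, n_after = 14) {
  data.frame(cue = 1L, action = 1L,
             outcome = c(rep(1L, n_stable), 2L, rep(1L, n_after)))
}

# Independent replay of the performance-triggered reversal rule: every
# flagged reversal must be preceded, at some admissible lag, by a trailing
# window of outcomes whose gain proportion strictly exceeds the threshold.
check_reversal_rule <- function(trials, config) {
  W <- config$trigger_window
  flips <- which(trials$reversal_flag)
  ok <- TRUE
  for (t in flips) {
    lag_ok <- FALSE
    for (lag in config$reversal_lag_min:config$reversal_lag_max) {
      s <- t - lag
      if (s >= W &&
          mean(trials$outcome[(s - W + 1):s] == 1) > config$trigger_threshold)
        lag_ok <- TRUE
    }
    ok <- ok && lag_ok
  }
  ok && !any(flips < W + config$reversal_lag_min)
}

# Stick-breaking Dirichlet sampler (independent of the rgamma-based path in
# rfx_bms): p_k = b_k * prod_{j<k}(1 - b_j), b_k ~ Beta(alpha_k, sum_{j>k} alpha_j).
stickbreak_exceedance <- function(alpha, n_draws, seed) {
  set.seed(seed)
  K <- length(alpha)
  P <- matrix(0, n_draws, K)
  remaining <- rep(1, n_draws)
  for (k in seq_len(K - 1)) {
    b <- rbeta(n_draws, alpha[k], sum(alpha[(k + 1):K]))
    P[, k] <- remaining * b
    remaining <- remaining * (1 - b)
  }
  P[, K] <- remaining
  winners <- max.col(P, ties.method = "first")
  tabulate(winners, nbins = K) / n_draws
}
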