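test_that("feedback follows the configured reliability", {
  # deterministic limit
  cfg <- task_config(feedback_reliability = 1.0)
  s <- generate_session(cfg, fixed_policy("correct"), seed = 1)
  expect_true(all(s$outcome == 1))
  expect_equal(summarize_accuracy(s)$proportion_correct, 1.0)
  s_wrong <- generate_session(cfg, fixed_policy("wrong"), seed = 1)
  expect_equal(summarize_accuracy(s_wrong)$proportion_correct, 0.0)
  expect_true(all(s_wrong$outcome == 2))

  # stochastic feedback converges to the configured 0.85, for any policy
  cfg10k <- task_config(n_trials = 10000, n_sessions = 1)
  s <- generate_session(cfg10k, fixed_policy("correct"), seed = 2)
  expect_equal(mean(s$outcome == 1), 0.85, tolerance = 0.01)
  s_rand <- generate_session(cfg10k, fixed_policy("random"), seed = 3)
  correct <- s_rand$action == correct_action(s_rand$true_state, s_rand$cue)
  veridical <- (s_rand$outcome == 1) == correct
  expect_equal(mean(veridical), 0.85, tolerance = 0.01)
  # random policy is right about half the time
  expect_equal(summarize_accuracy(s_rand)$proportion_correct, 0.5, tolerance = 0.01)
})

test_that("reversals obey the performance trigger rule", {
  cfg <- task_config()
  for (seed in 1:30) {
    s <- generate_session(cfg, fixed_policy("correct"), seed = seed)
    expect_true(check_reversal_rule(s, cfg))
    flips <- which(s$reversal_flag)
    if (length(flips) > 0)
      expect_gte(min(flips), cfg$trigger_window + cfg$reversal_lag_min)
    # context actually flips exactly at the flagged trials
    changes <- which(diff(s$true_state) != 0) + 1L
    expect_equal(changes, setdiff(flips, 1), ignore_attr = TRUE)
  }
})

test_that("reversal lags are uniform on the configured range", {
  # with perfectly reliable feedback and a correct policy the trigger fires
  # exactly every trigger_window trials, so each lag is identifiable
  cfg <- task_config(n_trials = 4000, n_sessions = 1, feedback_reliability = 1.0)
  s <- generate_session(cfg, fixed_policy("correct"), seed = 4)
  flips <- which(s$reversal_flag)
  triggers <- seq(cfg$trigger_window, by = cfg$trigger_window,
                  length.out = length(flips))
  lags <- flips - triggers
  expect_true(all(lags %in% cfg$reversal_lag_min:cfg$reversal_lag_max))
  freq <- tabulate(lags, nbins = 3) / length(lags)
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / length(lags))))
})

test_that("cue schedules have the declared marginals", {
  cfg <- task_config(n_trials = 10000, n_sessions = 1)
  s <- generate_session(cfg, fixed_policy("correct"), seed = 5)
  expect_equal(mean(s$cue == 1), 0.5, tolerance = 0.015)
  cfg_bal <- task_config(cue_schedule = "balanced")
  s <- generate_session(cfg_bal, fixed_policy("correct"), seed = 6)
  counts <- tapply(s$cue == 1, s$session, sum)
  expect_true(all(counts == 16))  # 32 trials per session, exactly balanced
})

test_that("invalid configurations and policies are rejected", {
  expect_error(task_config(feedback_reliability = 0.3), class = "seqinfer_config_error")
  expect_error(task_config(trigger_threshold = 1), class = "seqinfer_config_error")
  expect_error(task_config(reversal_lag_min = 3, reversal_lag_max = 1),
               class = "seqinfer_config_error")
  expect_error(task_config(n_trials = 5, trigger_window = 10),
               class = "seqinfer_config_error")
  bad_policy <- function(cue, correct) 7L
  err <- tryCatch(generate_session(task_config(), bad_policy, seed = 1),
                  error = function(e) e)
  expect_s3_class(err, "seqinfer_data_error")
  expect_match(conditionMessage(err), "trial 1")
})

test_that("model agents behave sensibly in closed loop", {
  # zero precision: choice marginal near one half regardless of beliefs
  cfg <- task_config(n_trials = 4000, n_sessions = 1)
  s <- simulate_agent("S1", hmm_parameters(0.05, 0.8, 0), cfg, seed = 7)
  expect_equal(mean(s$action == 1), 0.5, tolerance = 0.025)

  # full-overwrite learning: Q(y, a) equals the reward just observed there
  cfg_det <- task_config(n_trials = 40, feedback_reliability = 1.0)
  agent <- model_agent("Q1", q_parameters(phi = 1, gamma = 2))
  s <- generate_session(cfg_det, agent, seed = 8)
  qr <- run_q_inference("Q1", q_parameters(phi = 1, gamma = 2), s,
                        keep_values = TRUE)
  for (t in seq_len(nrow(s))) {
    col <- (s$cue[t] - 1) * 2 + s$action[t]
    expect_equal(unname(qr$values[t, col]), as.numeric(s$outcome[t] == 1))
  }

  # agent trace is retained and matches an offline replay of the same log
  s2 <- simulate_agent("S2", hmm_parameters(0.05, 0.8, 3), task_config(), seed = 9)
  trace <- attr(s2, "trace")
  replay <- run_inference("S2", hmm_parameters(0.05, 0.8, 3), s2)
  expect_equal(trace$pred_p1, replay$trace$pred_p1, tolerance = 1e-10)
  expect_equal(trace$post_p1, replay$trace$post_p1, tolerance = 1e-10)
})

test_that("cohort generation is deterministic and bookkept", {
  spec <- cohort_spec(5, "S2", hmm_parameters(0.05, 0.8, 3), master_seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$manifest, c2$manifest)
  expect_true(all(vapply(c1$manifest, function(m) m$model, character(1)) == "S2"))
  # one subject reduces to simulate_agent under the derived seed
  spec1 <- cohort_spec(1, "S2", hmm_parameters(0.05, 0.8, 3), master_seed = 42)
  c3 <- generate_cohort(spec1)
  direct <- simulate_agent("S2", hmm_parameters(0.05, 0.8, 3), task_config(),
                           seed = c3$manifest[[1]]$seed)
  expect_equal(c3$trials$action, direct$action)
  expect_error(cohort_spec(2, "S1", hmm_parameters(0.1, 0.8, 1), 1,
                           ids = c("a", "a")),
               class = "seqinfer_config_error")
})

test_that("accuracy summaries require ground truth and support both units", {
  cohort <- generate_cohort(cohort_spec(4, "S1", hmm_parameters(0.05, 0.8, 5),
                                        master_seed = 11))
  acc_t <- summarize_accuracy(cohort$trials, by = "trial")
  acc_s <- summarize_accuracy(cohort$trials, by = "subject")
  expect_equal(acc_t$proportion_correct, acc_s$proportion_correct, tolerance = 1e-12)
  expect_equal(acc_t$n, 4 * 128)
  expect_equal(acc_s$n, 4)
  no_truth <- cohort$trials
  no_truth$true_state <- NA
  expect_error(summarize_accuracy(no_truth), class = "seqinfer_data_error")
})
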