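test_that("single-trial updates reproduce hand-computed beliefs", {
  p <- hmm_parameters(r = 0.05, v = 0.8, gamma = 3)

  # transition propagation of an informative boundary
  b <- init_belief(1)
  b$boundary <- c(0.8, 0.2)
  b <- advance_window(b, p)
  expect_equal(b$joint, c(0.77, 0.23), tolerance = 1e-12)

  # maximal-entropy transition forgets history
  b <- init_belief(1)
  b$boundary <- c(0.95, 0.05)
  b <- advance_window(b, hmm_parameters(0.5, 0.8, 3))
  expect_equal(b$joint, c(0.5, 0.5), tolerance = 1e-12)

  # first-trial posterior: uniform prior times likelihood
  b <- init_belief(3)
  b <- advance_window(b, p)
  b <- incorporate_outcome(b, 1, 1, 1, p)
  expect_equal(marginal_current_state(b), c(0.8, 0.2), tolerance = 1e-12)

  # uninformative feedback leaves the joint unchanged
  p_flat <- hmm_parameters(0.05, 0.5, 3)
  b <- init_belief(2)
  b <- advance_window(b, p_flat)
  before <- b$joint
  b <- incorporate_outcome(b, 2, 1, 2, p_flat)
  expect_equal(b$joint, before, tolerance = 1e-12)
})

test_that("two concordant trials give the expected order-2 joint and boundary", {
  p <- hmm_parameters(r = 0.05, v = 0.8, gamma = 3)
  b <- init_belief(2)
  for (t in 1:2) {
    b <- advance_window(b, p)
    b <- incorporate_outcome(b, 1, 1, 1, p)
  }
  expect_equal(b$joint, c(0.608, 0.008, 0.008, 0.038) / 0.662, tolerance = 1e-10)
  expect_equal(marginal_current_state(b)[1], 0.608 / 0.662 + 0.008 / 0.662,
               tolerance = 1e-10)
  b3 <- advance_window(b, p)
  expect_equal(b3$boundary, c(0.616, 0.046) / 0.662, tolerance = 1e-10)
})

test_that("marginal over the current state behaves as a marginal", {
  b <- init_belief(2)
  p <- hmm_parameters(0.1, 0.7, 1)
  b <- advance_window(b, p)
  b <- advance_window(b, p)
  b$joint <- rep(0.25, 4)
  expect_equal(marginal_current_state(b), c(0.5, 0.5))
  # order 1: the marginal is the joint itself
  b1 <- init_belief(1)
  b1 <- advance_window(b1, p)
  b1 <- incorporate_outcome(b1, 1, 1, 1, p)
  expect_equal(marginal_current_state(b1), b1$joint)
  expect_error(marginal_current_state(init_belief(2)), class = "seqinfer_state_error")
})

test_that("softmax action rule matches direct evaluation", {
  expect_equal(predict_action_prob(c(0.8, 0.2), 1, 3), 1 / (1 + exp(-1.8)),
               tolerance = 1e-12)
  expect_equal(predict_action_prob(c(0.8, 0.2), 2, 3), 1 - 1 / (1 + exp(-1.8)),
               tolerance = 1e-12)
  expect_equal(predict_action_prob(c(0.9, 0.1), 1, 0), 0.5)
  expect_equal(predict_action_prob(c(0.5, 0.5), 1, 12.3), 0.5)
  expect_error(predict_action_prob(c(0.5, 0.5), 3, 1), class = "seqinfer_data_error")
})

test_that("belief initialisation and code validation", {
  for (ord in c(1, 5)) {
    b <- init_belief(ord)
    expect_identical(b$window_length, 0L)
    expect_equal(b$boundary, c(0.5, 0.5))
    expect_length(b$joint, 0)
  }
  expect_identical(init_belief(3), init_belief(3))
  expect_error(init_belief(0), class = "seqinfer_config_error")
  expect_error(init_belief(6), class = "seqinfer_config_error")
  b <- advance_window(init_belief(2), hmm_parameters(0.1, 0.8, 1))
  expect_error(incorporate_outcome(b, 3, 1, 1, hmm_parameters(0.1, 0.8, 1)),
               class = "seqinfer_data_error")
})

test_that("joint and boundary stay normalised through random histories", {
  set.seed(401)
  for (rep in 1:10) {
    ord <- sample(1:5, 1)
    p <- random_hmm_params(400 + rep)
    b <- init_belief(ord)
    tr <- random_trials(40, 500 + rep)
    for (t in seq_len(nrow(tr))) {
      b <- advance_window(b, p)
      expect_equal(sum(b$joint), 1, tolerance = 1e-12)
      b <- incorporate_outcome(b, tr$cue[t], tr$action[t], tr$outcome[t], p)
      expect_equal(sum(b$joint), 1, tolerance = 1e-12)
      expect_equal(sum(b$boundary), 1, tolerance = 1e-12)
      expect_true(all(b$joint >= 0) && all(b$boundary >= 0))
    }
  }
})

test_that("relabelling contexts together with cues leaves choice probabilities invariant", {
  for (rep in 1:5) {
    p <- random_hmm_params(600 + rep)
    tr <- random_trials(60, 700 + rep)
    tr_flip <- tr
    tr_flip$cue <- 3L - tr$cue
    for (ord in c(1, 2, 4)) {
      a <- run_inference(ord, p, tr)
      b <- run_inference(ord, p, tr_flip)
      expect_equal(b$trace$p_action1, a$trace$p_action1, tolerance = 1e-12)
      expect_equal(b$log_likelihood, a$log_likelihood, tolerance = 1e-10)
    }
  }
})

test_that("degenerate parameters give the closed-form log-likelihoods", {
  tr <- random_trials(128, 801)
  for (ord in 1:5) {
    res <- run_inference(ord, hmm_parameters(0.2, 0.7, 0), tr)
    expect_equal(res$log_likelihood, 128 * log(0.5), tolerance = 1e-10)
  }
  # fully uninformative model: every predictive marginal is flat
  res <- run_inference(3, hmm_parameters(0.5, 0.5, 4), tr)
  expect_true(all(abs(res$trace$pred_p1 - 0.5) < 1e-12))
})
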