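test_that("symmetric evidence yields symmetric group posteriors", {
  ev <- matrix(-50, nrow = 12, ncol = 3,
               dimnames = list(NULL, c("A", "B", "C")))
  res <- rfx_bms(ev, mc_samples = 2e5, seed = 1)
  expect_equal(unname(res$alpha), rep(res$alpha[[1]], 3), tolerance = 1e-8)
  expect_equal(unname(res$expected_prob), rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(unname(res$exceedance_prob), rep(1 / 3, 3), tolerance = 0.01)
})

test_that("Dirichlet counts are conserved and probabilities normalised", {
  set.seed(41)
  for (rep in 1:5) {
    n_sub <- sample(5:40, 1); n_mod <- sample(2:5, 1)
    ev <- matrix(rnorm(n_sub * n_mod, -60, 4), n_sub, n_mod,
                 dimnames = list(NULL, paste0("M", seq_len(n_mod))))
    res <- rfx_bms(ev, mc_samples = 1e5, seed = rep)
    expect_equal(sum(res$alpha - res$alpha0), n_sub, tolerance = 1e-6)
    expect_equal(sum(res$expected_prob), 1, tolerance = 1e-9)
    expect_equal(sum(res$exceedance_prob), 1, tolerance = 1e-3)
    expect_equal(unname(rowSums(res$responsibilities)), rep(1, n_sub),
                 tolerance = 1e-9)
  }
  expect_error(rfx_bms(matrix(c(1, NA, 2, 3), 2, 2)), class = "seqinfer_data_error")
})

test_that("a uniformly dominant model saturates the exceedance probability", {
  set.seed(42)
  base <- rnorm(20, -60, 3)
  ev <- cbind(M1 = base + 10, M2 = base, M3 = base - rnorm(20, 2, 1))
  res <- rfx_bms(ev, mc_samples = 2e5, seed = 2)
  expect_gt(res$exceedance_prob[["M1"]], 0.99)
  expect_equal(which.max(res$expected_prob), 1L, ignore_attr = TRUE)
})

test_that("exceedance agrees with analytic and independent Monte-Carlo oracles", {
  set.seed(43)
  # two models: the package uses the exact Beta CDF; check it against an
  # independent stick-breaking sampler within 3 Monte-Carlo standard errors
  ev2 <- cbind(M1 = rnorm(15, -60, 3), M2 = rnorm(15, -61, 3))
  res2 <- rfx_bms(ev2)
  n_draws <- 2e5
  mc <- stickbreak_exceedance(res2$alpha, n_draws, seed = 7)
  se <- sqrt(mc[1] * (1 - mc[1]) / n_draws)
  expect_lt(abs(res2$exceedance_prob[[1]] - mc[1]), 3 * max(se, 1e-4))
  # three models: package Monte-Carlo vs the independent sampler
  ev3 <- cbind(M1 = rnorm(15, -60, 3), M2 = rnorm(15, -61, 3),
               M3 = rnorm(15, -62, 3))
  res3 <- rfx_bms(ev3, mc_samples = 4e5, seed = 3)
  mc3 <- stickbreak_exceedance(res3$alpha, n_draws, seed = 8)
  for (k in 1:3) {
    se_k <- sqrt(mc3[k] * (1 - mc3[k]) / n_draws +
                 res3$exceedance_prob[[k]] * (1 - res3$exceedance_prob[[k]]) / 4e5)
    expect_lt(abs(res3$exceedance_prob[[k]] - mc3[k]), 3 * max(se_k, 1e-4))
  }
})

test_that("subject-level model posteriors are a softmax of log evidence", {
  expect_equal(subject_model_posteriors(c(-10, -10, -10)), rep(1 / 3, 3))
  expect_equal(subject_model_posteriors(c(-5 + log(9), -5)), c(0.9, 0.1),
               tolerance = 1e-12)
  expect_equal(subject_model_posteriors(c(0, -100)), c(1, 0), tolerance = 1e-12)
  expect_error(subject_model_posteriors(c(1, Inf)), class = "seqinfer_data_error")
})

test_that("parameter averaging is the posterior-weighted convex combination", {
  pm <- list(list(r = 0.9, v = 0.8), list(r = 0.8, v = 0.6))
  expect_equal(bayesian_parameter_average(pm, c(0.75, 0.25)),
               c(r = 0.875, v = 0.75))
  expect_equal(bayesian_parameter_average(pm, c(1, 0)), c(r = 0.9, v = 0.8))
  same <- list(list(r = 0.5), list(r = 0.5))
  expect_equal(bayesian_parameter_average(same, c(0.3, 0.7)), c(r = 0.5))
  incompatible <- list(list(r = 0.5), list(phi = 0.2))
  expect_error(bayesian_parameter_average(incompatible, c(0.5, 0.5),
                                          parameters = "r"),
               class = "seqinfer_config_error")
  # zero-weight models may lack the parameter
  expect_equal(bayesian_parameter_average(incompatible, c(1, 0), parameters = "r"),
               c(r = 0.5))
})
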