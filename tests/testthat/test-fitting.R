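test_that("fit statistics follow their defining formulas", {
  chance <- 128 * log(0.5)
  expect_equal(compute_bic(chance, 2, 128), 2 * chance - 2 * log(128),
               tolerance = 1e-9)
  expect_equal(compute_bic(chance, 2, 128), -187.1475, tolerance = 1e-3)
  expect_equal(compute_bic(-50, 0, 100), -100)
  # equal likelihood, one extra parameter: penalty gap is exactly ln(n)
  expect_equal(compute_bic(-60, 2, 128) - compute_bic(-60, 3, 128), log(128),
               tolerance = 1e-9)
  expect_equal(compute_pseudo_r2(chance, 128), 0, tolerance = 1e-9)
  expect_equal(compute_pseudo_r2(0, 128), 1)
  expect_equal(compute_pseudo_r2(-44.3614, 128), 0.5, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:20) {
    ll <- -runif(1, 1, 200); k <- sample(0:4, 1); n <- sample(20:500, 1)
    expect_equal(compute_bic(ll, k, n), 2 * ll - k * log(n), tolerance = 1e-9)
    expect_equal(compute_pseudo_r2(ll, n), 1 - ll / (n * log(0.5)), tolerance = 1e-9)
  }
})

test_that("log posterior combines likelihood and prior terms correctly", {
  tr <- random_trials(64, 3001)
  # flat-prior limit with fixed gamma: exactly the log-likelihood
  m_fixed <- model_spec("S1", gamma_mode = "fixed", fixed_gamma = 2)
  flat <- prior_spec(rate_shape1 = 1, rate_shape2 = 1)
  prm <- list(r = 0.2, v = 0.7)
  expect_equal(log_posterior(m_fixed, prm, tr, flat),
               run_inference(m_fixed, hmm_parameters(0.2, 0.7, 2), tr)$log_likelihood,
               tolerance = 1e-10)
  # support boundary: Beta(1.1, 1.1) density vanishes at 0 and 1
  expect_identical(log_posterior(m_fixed, list(r = 0, v = 0.7), tr), -Inf)
  expect_identical(log_posterior(m_fixed, list(r = 0.2, v = 1), tr), -Inf)
  # zero precision: likelihood term is the chance log-likelihood
  m0 <- model_spec("S2", gamma_mode = "fixed", fixed_gamma = 0)
  pri <- prior_spec()
  expect_equal(log_posterior(m0, list(r = 0.3, v = 0.6), tr, pri),
               64 * log(0.5) +
                 dbeta(0.3, 1.1, 1.1, log = TRUE) + dbeta(0.6, 1.1, 1.1, log = TRUE),
               tolerance = 1e-10)
  # free gamma adds the log-normal precision prior on ln(gamma)
  expect_equal(log_posterior("S1", list(r = 0.2, v = 0.7, gamma = 2), tr, pri) -
                 log_posterior(m_fixed, list(r = 0.2, v = 0.7), tr, pri),
               dnorm(log(2), 1, 0.5, log = TRUE), tolerance = 1e-10)
})

test_that("MAP fitting is deterministic and respects its reported statistics", {
  tr <- simulate_agent("S2", hmm_parameters(0.08, 0.8, 3), task_config(), seed = 32)
  f1 <- fit_map("S2", tr, n_starts = 4, seed = 5)
  f2 <- fit_map("S2", tr, n_starts = 4, seed = 5)
  expect_identical(f1$map_params, f2$map_params)
  expect_identical(f1$log_posterior, f2$log_posterior)
  expect_equal(f1$bic, compute_bic(f1$log_likelihood, f1$k, f1$n_trials),
               tolerance = 1e-9)
  expect_equal(f1$pseudo_r2, compute_pseudo_r2(f1$log_likelihood, f1$n_trials),
               tolerance = 1e-9)
  expect_true(f1$convergence)
  expect_error(fit_map("S1", tr[1:10, ]), class = "seqinfer_data_error")
})

test_that("a coarse grid never beats the simplex optimum", {
  for (seed in c(33, 34)) {
    tr <- simulate_agent("S1", hmm_parameters(0.1, 0.8, 4),
                         task_config(n_trials = 64, n_sessions = 1), seed = seed)
    m <- model_spec("S1", gamma_mode = "fixed", fixed_gamma = 4)
    f <- fit_map(m, tr, n_starts = 4, seed = 1)
    grid <- expand.grid(r = seq(0.02, 0.98, by = 0.04),
                        v = seq(0.02, 0.98, by = 0.04))
    lp_grid <- mapply(function(r, v) log_posterior(m, list(r = r, v = v), tr),
                      grid$r, grid$v)
    expect_gte(f$log_posterior + 1e-6, max(lp_grid))
  }
})

test_that("data from a zero-precision agent fit at the chance ceiling", {
  tr <- simulate_agent("S1", hmm_parameters(0.1, 0.8, 0),
                       task_config(n_trials = 256, n_sessions = 1), seed = 35)
  f <- fit_map("S1", tr, n_starts = 6, seed = 1)
  expect_equal(f$log_likelihood, 256 * log(0.5), tolerance = 3)
})

test_that("recovered parameters approach the truth as trials grow", {
  truth <- hmm_parameters(0.1, 0.85, 5)
  errs <- vapply(c(128, 512, 2048), function(n) {
    pr <- run_parameter_recovery(true_params = truth, n_trials = n,
                                 n_replicates = 4, n_starts = 3, seed = 36)
    mean(abs(c(pr$estimates$r_hat - truth$r, pr$estimates$v_hat - truth$v)))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.05)
})

test_that("the fixed-precision second pass drops one parameter and keeps fit", {
  cohort <- generate_cohort(cohort_spec(4, "S1", hmm_parameters(0.1, 0.8, 3),
                                        master_seed = 37))
  cf <- fit_cohort_fixed_gamma("S1", cohort, n_starts = 3, seed = 1)
  expect_equal(vapply(cf$pass1, function(f) f$k, numeric(1)),
               setNames(rep(3, 4), names(cf$pass1)))
  expect_equal(vapply(cf$pass2, function(f) f$k, numeric(1)),
               setNames(rep(2, 4), names(cf$pass2)))
  expect_equal(cf$fixed_gamma,
               mean(vapply(cf$pass1, function(f) f$map_params$gamma, numeric(1))),
               tolerance = 1e-12)
  # shared generating precision: clamping costs little likelihood, so the
  # BIC penalty saving favours the fixed-precision fit in every subject
  expect_true(all(cf$comparison$favours_fixed))
  # parameter counts across families (fixed-precision pass)
  tr <- split(cohort$trials, cohort$trials$subject_id)[[1]]
  for (spec in list(c("Q1", 1), c("Q2", 1), c("Q3", 2), c("S3", 2))) {
    m <- model_spec(spec[1], gamma_mode = "fixed", fixed_gamma = 2)
    f <- fit_map(m, tr, n_starts = 2, seed = 1)
    expect_equal(f$k, as.numeric(spec[2]))
  }
  # identical trial logs give identical per-subject results
  twins <- list(a = tr, b = tr)
  cft <- fit_cohort_fixed_gamma("S1", twins, n_starts = 2, seed = 1)
  expect_equal(cft$pass2$a$map_params, cft$pass2$b$map_params)
})
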