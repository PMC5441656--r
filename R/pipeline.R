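SEQ_MODELS <- paste0("S", 1:5)
PRELIM_MODELS <- c("S1", paste0("Q", 1:3))

#' Full behavioural analysis of a cohort
#'
#' Runs the complete modelling pipeline on a cohort of trial logs: two-pass
#' fixed-precision MAP fits of every model in the model space, the
#' preliminary comparison of filtering against the delta-rule baselines
#' (S1 vs Q1-Q3), the sequential comparison (S1-S5), random-effects Bayesian
#' model selection on each, Bayesian parameter averaging of r and v, the
#' per-subject sequential-inference measures (delta-LL and L), accuracy
#' summaries, and optional partial correlations of the measures with
#' covariate scores.
#'
#' @param cohort A `seqinfer_cohort`, long trial data frame with
#'   `subject_id`, or named list of per-subject trial data frames.
#' @param models Model space to fit (default S1-S5 and Q1-Q3).
#' @param priors A [prior_spec()].
#' @param n_starts Optimizer restarts per fit.
#' @param mc_samples Monte-Carlo draws for exceedance probabilities.
#' @param seed Master seed for fitting restarts and Monte-Carlo draws.
#' @param covariates Optional data frame with a `subject_id` column and
#'   numeric score columns (e.g. working-memory and reasoning scores).
#' @param controls Covariate columns to partial out in the correlations
#'   (default: whichever of `age_group`, `gender` are present).
#' @return A list of class `seq_analysis`: `fits`, `evidence_seq`,
#'   `evidence_prelim`, `bms_seq`, `bms_prelim`, `subject_measures`,
#'   `accuracy`, `model_table`, `correlations`, `seed`.
#' @export
run_full_analysis <- function(cohort, models = c(SEQ_MODELS, paste0("Q", 1:3)),
                              priors = prior_spec(), n_starts = 5,
                              mc_samples = 1e6, seed = 1,
                              covariates = NULL, controls = NULL) {
  subjects <- as_cohort_list(cohort)
  models <- unique(toupper(models))
  if (!all(SEQ_MODELS %in% models))
    stop_config("the model space must include S1..S5")
  seeds <- derive_seeds(seed, length(models) + 1L)

  fits <- list()
  for (i in seq_along(models)) {
    fits[[models[i]]] <- fit_cohort_fixed_gamma(models[i], subjects,
                                                priors = priors,
                                                n_starts = n_starts,
                                                seed = seeds[i])
  }

  evidence_for <- function(space) {
    ev <- vapply(space, function(m) {
      vapply(fits[[m]]$pass2, function(f) f$bic / 2, numeric(1))
    }, numeric(length(subjects)))
    rownames(ev) <- names(subjects)
    ev
  }
  evidence_seq <- evidence_for(SEQ_MODELS)
  bms_seq <- rfx_bms(evidence_seq, mc_samples = mc_samples,
                     seed = seeds[length(seeds)])
  evidence_prelim <- NULL
  bms_prelim <- NULL
  if (all(PRELIM_MODELS %in% models)) {
    evidence_prelim <- evidence_for(PRELIM_MODELS)
    bms_prelim <- rfx_bms(evidence_prelim, mc_samples = mc_samples,
                          seed = seeds[length(seeds)])
  }

  # Per-subject measures over the sequential model space.
  subject_measures <- do.call(rbind, lapply(seq_along(subjects), function(s) {
    sfits <- lapply(SEQ_MODELS, function(m) fits[[m]]$pass2[[s]])
    names(sfits) <- SEQ_MODELS
    post <- subject_model_posteriors(evidence_seq[s, ])
    bpa <- bayesian_parameter_average(
      lapply(sfits, function(f) f$map_params), post, parameters = c("r", "v"))
    data.frame(subject_id = names(subjects)[s],
               delta_ll = compute_delta_ll(sfits),
               L = compute_sequence_length_L(sfits),
               bpa_r = bpa[["r"]], bpa_v = bpa[["v"]],
               mean_bic = mean(vapply(sfits, function(f) f$bic, numeric(1))),
               row.names = NULL)
  }))

  trials_all <- do.call(rbind, subjects)
  accuracy <- if ("true_state" %in% names(trials_all) &&
                  !all(is.na(trials_all$true_state))) {
    list(trial = summarize_accuracy(trials_all, "trial"),
         subject = if ("subject_id" %in% names(trials_all))
           summarize_accuracy(trials_all, "subject") else NULL)
  } else NULL

  model_table <- data.frame(
    model = SEQ_MODELS,
    summed_bic = vapply(SEQ_MODELS, function(m)
      sum(vapply(fits[[m]]$pass2, function(f) f$bic, numeric(1))), numeric(1)),
    posterior_prob = as.numeric(bms_seq$expected_prob[SEQ_MODELS]),
    exceedance_prob = as.numeric(bms_seq$exceedance_prob[SEQ_MODELS]),
    mean_pseudo_r2 = vapply(SEQ_MODELS, function(m)
      mean(vapply(fits[[m]]$pass2, function(f) f$pseudo_r2, numeric(1))),
      numeric(1)),
    row.names = NULL
  )
  model_table$bic_vs_worst <- model_table$summed_bic - min(model_table$summed_bic)
  model_table <- model_table[, c("model", "summed_bic", "bic_vs_worst",
                                 "posterior_prob", "exceedance_prob",
                                 "mean_pseudo_r2")]

  correlations <- NULL
  if (!is.null(covariates)) {
    if (!"subject_id" %in% names(covariates))
      stop_data("`covariates` must contain a `subject_id` column")
    cov <- merge(subject_measures, covariates, by = "subject_id", sort = FALSE)
    if (is.null(controls))
      controls <- intersect(c("age_group", "gender"), names(covariates))
    scores <- setdiff(names(covariates), c("subject_id", controls))
    ctrl <- if (length(controls) > 0) cov[, controls, drop = FALSE] else NULL
    correlations <- do.call(rbind, lapply(scores, function(sc) {
      do.call(rbind, lapply(c("L", "delta_ll"), function(ms) {
        pc <- partial_correlation(cov[[sc]], cov[[ms]], ctrl)
        data.frame(score = sc, measure = ms, R = pc$estimate,
                   p = pc$p.value, n = pc$n, row.names = NULL)
      }))
    }))
  }

  structure(list(fits = fits, evidence_seq = evidence_seq,
                 evidence_prelim = evidence_prelim,
                 bms_seq = bms_seq, bms_prelim = bms_prelim,
                 subject_measures = subject_measures,
                 accuracy = accuracy, model_table = model_table,
                 correlations = correlations, seed = seed),
            class = "seq_analysis")
}

#' @export
print.seq_analysis <- function(x, ...) {
  cat("Sequential-inference analysis\n")
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy: %.1f%% correct\n",
                100 * x$accuracy$trial$proportion_correct))
  cat("  sequential model comparison:\n")
  tab <- x$model_table
  tab[, -1] <- round(tab[, -1], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate subjects from a known model and refits them (precision
#' free), summarising the recovery error of the subjective reversal
#' probability r and cue validity v.
#'
#' @param model Generating (and fitted) model, default `"S1"`.
#' @param true_params Generating `hmm_parameters`.
#' @param n_trials Trials per replicate.
#' @param n_replicates Number of simulated subjects.
#' @param n_starts Optimizer restarts per fit.
#' @param seed Master seed.
#' @param config Base [task_config()]; its trial/session counts are overridden
#'   by `n_trials`.
#' @return A list with `estimates` (per-replicate data frame) and `summary`
#'   (median absolute error, bias and RMSE for r and v).
#' @export
run_parameter_recovery <- function(model = "S1",
                                   true_params = hmm_parameters(0.1, 0.85, 5),
                                   n_trials = 512, n_replicates = 20,
                                   n_starts = 5, seed = 1,
                                   config = task_config()) {
  if (!is_count(n_replicates)) stop_config("`n_replicates` must be a positive integer")
  model <- as_model_spec(model)
  config$n_trials <- as.integer(n_trials)
  config$n_sessions <- 1L
  seeds <- derive_seeds(seed, 2L * n_replicates)
  est <- do.call(rbind, lapply(seq_len(n_replicates), function(i) {
    tr <- simulate_agent(model, true_params, config, seed = seeds[i])
    fit <- fit_map(model, tr, n_starts = n_starts, seed = seeds[n_replicates + i])
    data.frame(replicate = i, r_hat = fit$map_params$r, v_hat = fit$map_params$v,
               gamma_hat = fit$map_params$gamma, log_likelihood = fit$log_likelihood,
               row.names = NULL)
  }))
  err_r <- est$r_hat - true_params$r
  err_v <- est$v_hat - true_params$v
  summary <- data.frame(
    parameter = c("r", "v"),
    truth = c(true_params$r, true_params$v),
    median_abs_error = c(median(abs(err_r)), median(abs(err_v))),
    bias = c(mean(err_r), mean(err_v)),
    rmse = c(sqrt(mean(err_r^2)), sqrt(mean(err_v^2))),
    row.names = NULL
  )
  list(estimates = est, summary = summary, model = model$name,
       n_trials = n_trials, seed = seed)
}

#' Model-recovery experiment
#'
#' For each generating model, simulates replicate cohorts, runs the two-pass
#' fitting and random-effects model selection over the sequential model
#' space, and records which model attains the highest exceedance probability.
#'
#' @param generators Generating model names.
#' @param n_subjects Subjects per cohort.
#' @param n_trials Trials per subject.
#' @param n_replicates Cohort replicates per generator.
#' @param gen_params Generating `hmm_parameters` shared by all subjects.
#' @param model_space Models fitted and compared (default S1-S5).
#' @param n_starts Optimizer restarts per fit.
#' @param mc_samples Monte-Carlo draws for exceedance probabilities.
#' @param seed Master seed.
#' @param config Base [task_config()].
#' @return A list with `results` (per generator x replicate: selected model
#'   and the generating model's exceedance probability) and `confusion`
#'   (generators x selected-model count matrix).
#' @export
run_model_recovery <- function(generators = c("S1", "S2", "S3"),
                               n_subjects = 30, n_trials = 128,
                               n_replicates = 10,
                               gen_params = hmm_parameters(0.05, 0.8, exp(1)),
                               model_space = SEQ_MODELS,
                               n_starts = 3, mc_samples = 1e5, seed = 1,
                               config = task_config()) {
  if (!is_count(n_replicates)) stop_config("`n_replicates` must be a positive integer")
  config$n_trials <- as.integer(n_trials)
  seeds <- derive_seeds(seed, length(generators) * n_replicates)
  rows <- list()
  k <- 0L
  for (g in generators) {
    for (rep in seq_len(n_replicates)) {
      k <- k + 1L
      cohort <- generate_cohort(
        cohort_spec(n_subjects, g, gen_params, master_seed = seeds[k]),
        config)
      subjects <- split_cohort(cohort$trials)
      ev <- vapply(model_space, function(m) {
        cf <- fit_cohort_fixed_gamma(m, subjects, n_starts = n_starts,
                                     seed = seeds[k])
        vapply(cf$pass2, function(f) f$bic / 2, numeric(1))
      }, numeric(n_subjects))
      bms <- rfx_bms(ev, mc_samples = mc_samples, seed = seeds[k])
      rows[[k]] <- data.frame(
        generator = g, replicate = rep,
        selected = model_space[which.max(bms$exceedance_prob)],
        xp_generating = as.numeric(bms$exceedance_prob[g]),
        row.names = NULL)
    }
  }
  results <- do.call(rbind, rows)
  confusion <- table(factor(results$generator, levels = generators),
                     factor(results$selected, levels = model_space))
  list(results = results, confusion = confusion, n_trials = n_trials,
       n_subjects = n_subjects, gen_params = gen_params, seed = seed)
}

#' Combined recovery report
#'
#' Runs the model-recovery and parameter-recovery experiments and returns a
#' single report: the generating-vs-selected confusion matrix and the
#' bias/RMSE table for the recovered r and v.
#'
#' @param model_recovery,parameter_recovery Named lists of arguments passed
#'   to [run_model_recovery()] and [run_parameter_recovery()].
#' @param seed Master seed (used where the sub-experiments do not set one).
#' @return A list of class `recovery_report` with `model_recovery` and
#'   `parameter_recovery`.
#' @export
run_recovery_suite <- function(model_recovery = list(),
                               parameter_recovery = list(), seed = 1) {
  seeds <- derive_seeds(seed, 2L)
  mr <- do.call(run_model_recovery,
                utils::modifyList(list(seed = seeds[1]), model_recovery))
  pr <- do.call(run_parameter_recovery,
                utils::modifyList(list(seed = seeds[2]), parameter_recovery))
  structure(list(model_recovery = mr, parameter_recovery = pr, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Model recovery (generator x selected):\n")
  print(x$model_recovery$confusion)
  cat("\nParameter recovery:\n")
  print(x$parameter_recovery$summary, row.names = FALSE)
  invisible(x)
}
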