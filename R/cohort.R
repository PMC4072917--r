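#' Cohort configuration
#'
#' Defines an age-stratified synthetic cohort: ages are drawn uniformly over
#' a range and each subject's true learning rate, inverse temperature,
#' PE-to-BOLD coupling and outcome-response amplitude come from linear age
#' models plus individual Gaussian scatter. The shipped defaults encode the
#' hypothesis under study: the prediction-error coupling declines linearly
#' with age while the outcome response does not, and (for the imaging arm)
#' the learning rate itself is age-stable.
#'
#' @param n_subjects number of subjects (default 39, the learning arm size).
#' @param age_range two-vector of ages in years (default 22-85, uniform).
#' @param alpha_model list `(intercept, slope, sd)`: learning rate at the
#'   reference age 53, change per year, and individual SD; clipped to
#'   `[0, 1]`.
#' @param beta_model list `(meanlog, sdlog)`: lognormal inverse temperature.
#' @param coupling_model list `(intercept, slope, sd)`: PE coupling in PSC
#'   units per PE unit at age 53 and its change per year.
#' @param outcome_model list `(intercept, slope, sd)`: outcome-response
#'   amplitude (PSC) for the non-learning task.
#' @param noise list `(sd, ar1)`: BOLD noise marginal SD (PSC) and lag-1
#'   autocorrelation.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 39, age_range = c(22, 85),
                          alpha_model = list(intercept = 0.35, slope = 0,
                                             sd = 0.08),
                          beta_model = list(meanlog = log(4), sdlog = 0.3),
                          coupling_model = list(intercept = 0.8,
                                                slope = -0.010, sd = 0.08),
                          outcome_model = list(intercept = 0.6, slope = 0,
                                               sd = 0.08),
                          noise = list(sd = 0.5, ar1 = 0.3)) {
  stopifnot(n_subjects >= 2, diff(age_range) > 0)
  structure(
    list(n_subjects = n_subjects, age_range = age_range,
         alpha_model = alpha_model, beta_model = beta_model,
         coupling_model = coupling_model, outcome_model = outcome_model,
         noise = noise, reference_age = 53),
    class = "cohort_config"
  )
}

#' Generate a synthetic age-stratified cohort
#'
#' @param config a `cohort_config`.
#' @param seed integer seed.
#' @return data.frame: subject_id, age, group (young/middle/older bins),
#'   alpha, beta, pe_coupling, outcome_amplitude.
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  d_age <- age - config$reference_age
  lin <- function(m) m$intercept + m$slope * d_age + stats::rnorm(n, 0, m$sd)
  alpha <- pmin(pmax(lin(config$alpha_model), 0), 1)
  beta <- stats::rlnorm(n, config$beta_model$meanlog,
                        config$beta_model$sdlog)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)), age = age,
    group = age_group(age), alpha = alpha, beta = beta,
    pe_coupling = lin(config$coupling_model),
    outcome_amplitude = lin(config$outcome_model),
    stringsAsFactors = FALSE
  )
}

subject_seeds <- function(seed, n, k = 6L) {
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max - 1L, n * k), nrow = n)
}

#' Run the learning-task (MIL) imaging arm for one cohort
#'
#' For every subject: build an individually randomized MIL schedule, simulate
#' an RW/softmax learner with the subject's true parameters, fit the learning
#' model by maximum likelihood, synthesize a ROI series whose feedback
#' responses are modulated by the fitted signed PE scaled by the subject's
#' true coupling, invert with the parametric first-level GLM, and extract the
#' positive-vs-negative PE feedback-window time-course contrast. Then
#' regress the first-level PE coefficient on mean-centered age (linear +
#' quadratic) and t-test the time-course contrast against zero.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param seed integer master seed (per-subject streams derive from it).
#' @param noise list `(sd, ar1)` for the BOLD noise.
#' @return list with `subjects` (per-subject table), `age_regression`
#'   (on the PE coefficient), `timecourse_t`, `excluded`.
#' @export
run_study1_mil <- function(cohort, seed = 1, noise = list(sd = 0.5,
                                                          ar1 = 0.3)) {
  n <- nrow(cohort)
  seeds <- subject_seeds(seed, n)
  rows <- vector("list", n)
  tc_diff <- rep(NA_real_, n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sched <- build_schedule("mil", seed = seeds[i, 1])
      log <- simulate_choices(
        sched, agent_params(cohort$alpha[i], cohort$beta[i], "rw_softmax"),
        seed = seeds[i, 2])
      fit <- fit_rw(log)
      pe_full <- rep(NA_real_, nrow(sched$trials))
      pe_full[match(fit$pe$trial, sched$trials$trial)] <- fit$pe$pe
      cp <- coupling_spec(event_amplitude = 0.5,
                          pe_coupling = cohort$pe_coupling[i],
                          noise_sd = noise$sd, ar1 = noise$ar1)
      series <- synthesize_roi_timeseries(sched, pe_full, cp,
                                          roi_label = "MPFC",
                                          seed = seeds[i, 3])
      design <- build_design_matrix(sched, pe_full, "mil-parametric")
      glm <- fit_glm(series, design)
      gain_idx <- sched$trials$condition == "gain"
      labels <- classify_pe_sign(pe_full[gain_idx])
      tcd <- tryCatch({
        keep <- labels != "excluded"
        mat <- extract_peristimulus(series,
                                    sched$trials$onset_s[gain_idx][keep])
        lab <- labels[keep][attr(mat, "kept")]
        condition_contrast_curves(mat, lab,
                                  contrast = c("positive",
                                               "negative"))$difference
      }, error = function(e) NA_real_)
      list(row = data.frame(
        subject_id = cohort$subject_id[i], age = cohort$age[i],
        alpha_true = cohort$alpha[i], alpha_hat = coef(fit)[["alpha"]],
        beta_hat = coef(fit)[["beta"]],
        coupling_true = cohort$pe_coupling[i],
        pe_coef = glm_stat(glm, "pe_gain"),
        pe_z = glm_stat(glm, "pe_gain", "z"),
        performance = performance_metrics(log, "MIL"),
        stringsAsFactors = FALSE), tc = tcd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, sprintf("%s: %s", cohort$subject_id[i],
                                      conditionMessage(res)))
    } else {
      rows[[i]] <- res$row
      tc_diff[i] <- res$tc
    }
  }
  subjects <- do.call(rbind, rows)
  list(
    subjects = subjects,
    age_regression = age_effect_regression(
      data.frame(age = subjects$age, value = subjects$pe_coef)),
    timecourse_t = within_sample_t(tc_diff[is.finite(tc_diff)]),
    excluded = excluded
  )
}

#' Run the non-learning (MID) imaging arm for one cohort
#'
#' For every subject: build a MID schedule, simulate speeded responding under
#' the per-cue-type adaptive timing algorithm, synthesize a ROI series whose
#' at-stake feedback responses differ between hits and misses by the
#' subject's true (age-stable) outcome amplitude, invert with the MID
#' contrast GLM, and regress the gain-vs-nongain outcome coefficient on age.
#'
#' @inheritParams run_study1_mil
#' @return list with `subjects`, `age_regression` (on the outcome
#'   coefficient), `excluded`.
#' @export
run_study1_mid <- function(cohort, seed = 1, noise = list(sd = 0.5,
                                                          ar1 = 0.3)) {
  n <- nrow(cohort)
  seeds <- subject_seeds(seed + 1L, n)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      sched <- build_schedule("mid", seed = seeds[i, 1])
      perf <- simulate_mid_performance(sched, seed = seeds[i, 2])
      stake <- perf$magnitude > 0
      code <- ifelse(stake, ifelse(perf$hit, 1, -1), 0)
      cp <- coupling_spec(event_amplitude = 0.5,
                          pe_coupling = cohort$outcome_amplitude[i],
                          noise_sd = noise$sd, ar1 = noise$ar1)
      series <- synthesize_roi_timeseries(sched, code, cp,
                                          roi_label = "MPFC",
                                          seed = seeds[i, 3])
      design <- build_design_matrix(sched, perf, "mid")
      glm <- fit_glm(series, design)
      data.frame(
        subject_id = cohort$subject_id[i], age = cohort$age[i],
        outcome_true = cohort$outcome_amplitude[i],
        outcome_coef = glm_stat(glm, "out_gain"),
        outcome_z = glm_stat(glm, "out_gain", "z"),
        hit_rate = mean(perf$hit), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, sprintf("%s: %s", cohort$subject_id[i],
                                      conditionMessage(res)))
    } else {
      rows[[i]] <- res
    }
  }
  subjects <- do.call(rbind, rows)
  list(
    subjects = subjects,
    age_regression = age_effect_regression(
      data.frame(age = subjects$age, value = subjects$outcome_coef)),
    excluded = excluded
  )
}

#' Study 2 cohort: younger and older behavioral groups
#'
#' Two age bands (defaults 19-33 and 67-86, 18 and 30 subjects) with a
#' group-level learning-rate deficit: younger adults learn fast enough to
#' approach asymptote within a short 25-trial block while older adults learn
#' slowly enough that only the long 75-trial block gives them time to catch
#' up; inverse temperatures are age-stable. The deficit is modeled at the
#' group level (rather than as a within-band age gradient) so the block
#' length x age group manipulation stays clean.
#'
#' @param n_young,n_older group sizes.
#' @param young_range,older_range age bands in years.
#' @param alpha_model list `(young_mean, older_mean, young_sd, older_sd)`
#'   of group learning-rate distributions; draws are clipped to
#'   `[0.01, 1]`.
#' @param beta_model lognormal inverse-temperature model
#'   (`meanlog`, `sdlog`).
#' @param seed integer seed.
#' @return data.frame: subject_id, age, group (`"young"`/`"older"`), alpha,
#'   beta.
#' @export
study2_cohort <- function(n_young = 18, n_older = 30,
                          young_range = c(19, 33), older_range = c(67, 86),
                          alpha_model = list(young_mean = 0.60,
                                             older_mean = 0.055,
                                             young_sd = 0.04,
                                             older_sd = 0.012),
                          beta_model = list(meanlog = log(8), sdlog = 0.1),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_young + n_older
  age <- c(stats::runif(n_young, young_range[1], young_range[2]),
           stats::runif(n_older, older_range[1], older_range[2]))
  alpha <- pmin(pmax(
    c(stats::rnorm(n_young, alpha_model$young_mean, alpha_model$young_sd),
      stats::rnorm(n_older, alpha_model$older_mean, alpha_model$older_sd)),
    0.01), 1)
  data.frame(
    subject_id = sprintf("b%03d", seq_len(n)), age = age,
    group = rep(c("young", "older"), c(n_young, n_older)),
    alpha = alpha,
    beta = stats::rlnorm(n, beta_model$meanlog, beta_model$sdlog),
    stringsAsFactors = FALSE
  )
}

#' Run the Study 2 behavioral learning-limits arm
#'
#' Every subject plays the expanded four-cue task (blocks of 25, 75, 25, 75
#' trials in the fixed order short-long-short-long, fresh cues per block).
#' Performance is the proportion of choices allocated to the two
#' highest-probability cues, averaged over the two rounds of each block
#' length. Subjects adhering to win-stay/lose-shift on every single trial
#' are excluded, as are those from the mixed-design ANOVA and follow-up
#' tests.
#'
#' @param cohort data.frame from [study2_cohort()].
#' @param seed integer master seed.
#' @return list with `scores` (long format: subject, group, length, score),
#'   `anova` ([mixed_anova_2x2()] output), `followup`
#'   ([group_comparison_tests()] output), `excluded`.
#' @export
run_study2 <- function(cohort, seed = 1) {
  n <- nrow(cohort)
  seeds <- subject_seeds(seed + 2L, n)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    sched <- build_schedule("expanded", seed = seeds[i, 1])
    log <- simulate_choices(
      sched, agent_params(cohort$alpha[i], cohort$beta[i], "rw_softmax"),
      seed = seeds[i, 2])
    wsls <- wsls_adherence(log)
    if (wsls$exclude) {
      excluded <- c(excluded,
                    sprintf("%s: win-stay/lose-shift on every trial",
                            cohort$subject_id[i]))
      next
    }
    perf <- performance_metrics(log, "EXPANDED")$per_block
    lens <- sched$block_structure$length[perf$block]
    short <- mean(perf$proportion[lens == min(lens)])
    long <- mean(perf$proportion[lens == max(lens)])
    rows[[i]] <- data.frame(
      subject = cohort$subject_id[i], group = cohort$group[i],
      length = c("short", "long"), score = c(short, long),
      stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  scores$length <- factor(scores$length, levels = c("short", "long"))
  list(scores = scores, anova = mixed_anova_2x2(scores),
       followup = group_comparison_tests(scores), excluded = excluded)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates both imaging arms on an age-stratified cohort and the
#' behavioral learning-limits arm on its own two-group cohort, mirroring the
#' study structure (39 learning-arm subjects, the first 37 of them in the
#' non-learning arm, and 18 + 30 behavioral subjects).
#'
#' @param config a `cohort_config` for the imaging cohort.
#' @param seed integer master seed.
#' @param n_mid number of subjects in the non-learning arm (default 37).
#' @return an object of class `group_result` with components `cohort`, `mil`,
#'   `mid`, `study2` and a `manifest` of seeds and sizes.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, n_mid = 37) {
  cohort <- generate_cohort(config, seed = seed)
  mil <- run_study1_mil(cohort, seed = seed, noise = config$noise)
  mid <- run_study1_mid(cohort[seq_len(min(n_mid, nrow(cohort))), ],
                        seed = seed, noise = config$noise)
  s2_cohort <- study2_cohort(seed = seed + 10L)
  s2 <- run_study2(s2_cohort, seed = seed)
  structure(
    list(cohort = cohort, mil = mil, mid = mid, study2 = s2,
         manifest = list(seed = seed, n_mil = nrow(cohort),
                         n_mid = min(n_mid, nrow(cohort)),
                         n_study2 = nrow(s2_cohort),
                         date = as.character(Sys.Date()))),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat("Synthetic prediction-error pipeline result\n")
  cat(sprintf("Learning arm (n = %d): age beta on PE coefficient = %.2f (p = %.3g)\n",
              x$manifest$n_mil, x$mil$age_regression$std_beta,
              x$mil$age_regression$linear["Pr(>|t|)"]))
  cat(sprintf("Non-learning arm (n = %d): age beta on outcome coefficient = %.2f (p = %.3g)\n",
              x$manifest$n_mid, x$mid$age_regression$std_beta,
              x$mid$age_regression$linear["Pr(>|t|)"]))
  cat(sprintf("Time-course contrast (pos vs neg PE): t(%d) = %.2f\n",
              x$mil$timecourse_t$df, x$mil$timecourse_t$t))
  a <- x$study2$anova
  cat(sprintf("Study 2 ANOVA: length F(1,%d) = %.2f; interaction F(1,%d) = %.2f\n",
              a$length$df2, a$length$F, a$interaction$df2, a$interaction$F))
  invisible(x)
}
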