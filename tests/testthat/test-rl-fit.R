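test_that("the delta rule produces the forced arithmetic", {
  u <- rw_update(0, 1, 0.3)
  expect_equal(u$pe, 1.0)
  expect_equal(u$value, 0.3)
  expect_equal(rw_update(0.7, 5, 0)$value, 0.7)   # frozen learner
  u2 <- rw_update(1, 1, 0.5)                      # fully predicted reward
  expect_equal(u2$pe, 0)
  expect_equal(u2$value, 1)
  expect_error(rw_update(0, 1, 1.2), "alpha")
})

test_that("likelihood matches a pencil-and-paper 3-trial oracle", {
  # choices A(+1), A(+0), B(+1) on a two-cue pair; alpha 0.5, beta 2, V0 = 0
  log <- make_choice_log(
    condition = rep("gain", 3), cue_ids = rep("A;B", 3),
    chosen = c("A", "A", "B"), outcome = c(1, 0, 1),
    cues = two_cue_table
  )
  # trial 1: V = (0, 0)        -> P(A) = 1/2
  # trial 2: V = (0.5, 0)      -> P(A) = e^1 / (e^1 + e^0)
  # trial 3: V = (0.25, 0)     -> P(B) = 1 / (1 + e^0.5)
  oracle <- -(log(0.5) + log(exp(1) / (exp(1) + 1)) +
                log(1 / (1 + exp(0.5))))
  expect_equal(
    negative_log_likelihood(list(alpha = 0.5, beta = 2), log), oracle
  )
})

test_that("beta = 0 forces NLL = T log 2 on two-cue trials", {
  sched <- build_schedule("mil", seed = 21)
  log <- simulate_choices(sched, agent_params(0.3, 4), seed = 22)
  n_learning <- sum(log$condition != "neutral")
  expect_equal(
    negative_log_likelihood(list(alpha = 0.4, beta = 0), log),
    n_learning * log(2)
  )
})

test_that("compiled likelihood agrees with the plain R recursion", {
  set.seed(23)
  for (i in 1:8) {
    sched <- build_schedule("mil", config = list(n_per_condition = 10),
                            seed = 100 + i)
    log <- simulate_choices(sched, agent_params(runif(1), runif(1, 0, 8)),
                            seed = 200 + i)
    a <- runif(1)
    b <- runif(1, 0, 20)
    expect_equal(negative_log_likelihood(list(alpha = a, beta = b), log),
                 reference_nll(a, b, log))
  }
})

test_that("likelihood stays finite across the parameter box", {
  sched <- build_schedule("mil", config = list(n_per_condition = 20),
                          seed = 30)
  log <- simulate_choices(sched, agent_params(0.5, 6), seed = 31)
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    for (b in c(0, 1, 5, 10, 20)) {
      nll <- negative_log_likelihood(list(alpha = a, beta = b), log)
      expect_true(is.finite(nll))
      expect_gte(nll, 0)
    }
  }
  expect_error(negative_log_likelihood(
    list(alpha = 0.5, beta = 1),
    make_choice_log("neutral", "n1;n2", "n1", 0,
                    data.frame(cue_id = c("n1", "n2"), win_prob = 1,
                               valence = "neutral"))),
    "learning trials")
})

test_that("fitting a random agent finds an unstructured-choice solution", {
  sched <- build_schedule("mil", config = list(n_per_condition = 200),
                          seed = 41)
  log <- simulate_choices(sched, agent_params(strategy = "random"),
                          seed = 42)
  fit <- fit_rw(log)
  expect_lt(coef(fit)[["beta"]], 0.5)
  expect_lt(abs(fit$nll / fit$n_trials_used - log(2)), 0.01)
})

test_that("fit results are internally consistent and regenerate their PEs", {
  sched <- build_schedule("mil", seed = 51)
  log <- simulate_choices(sched, agent_params(0.4, 4), seed = 52)
  fit <- fit_rw(log)
  expect_true(fit$convergence)
  expect_gte(coef(fit)[["alpha"]], 0)
  expect_lte(coef(fit)[["alpha"]], 1)
  expect_lte(fit$log_likelihood, 0)
  expect_equal(nrow(fit$pe), fit$n_trials_used)
  expect_equal(fit$bic,
               2 * fit$nll + 2 * log(fit$n_trials_used))
  expect_equal(unname(BIC(fit)), fit$bic)

  # regenerate the PE series from (alpha_hat, log) with plain arithmetic:
  # must be bit-identical
  v <- list()
  a_hat <- coef(fit)[["alpha"]]
  pe_ref <- numeric(0)
  keep <- log$condition != "neutral"
  sub <- log[keep, ]
  for (i in seq_len(nrow(sub))) {
    ch <- sub$chosen[i]
    if (is.null(v[[ch]])) v[[ch]] <- 0
    pe_ref <- c(pe_ref, sub$outcome[i] - v[[ch]])
    v[[ch]] <- v[[ch]] + a_hat * (sub$outcome[i] - v[[ch]])
  }
  expect_identical(fit$pe$pe, pe_ref)

  # fitted optimum is at least as good as the generating parameters
  gen_nll <- negative_log_likelihood(list(alpha = 0.4, beta = 4), log)
  expect_lte(fit$nll, gen_nll + 1e-6)
})

test_that("recovery bias shrinks as the trial count grows", {
  err <- vapply(c(100, 1000), function(n_trials) {
    errs <- vapply(1:5, function(s) {
      sched <- build_schedule(
        "mil", config = list(n_per_condition = ceiling(n_trials / 2)),
        seed = 600 + s)
      log <- simulate_choices(sched, agent_params(0.3, 3), seed = 700 + s)
      abs(coef(fit_rw(log))[["alpha"]] - 0.3)
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("per-valence learning rates can be fit when requested", {
  sched <- build_schedule("mil", config = list(n_per_condition = 150),
                          seed = 61)
  log <- simulate_choices(sched, agent_params(0.35, 4), seed = 62)
  fit <- fit_rw(log, per_valence_alpha = TRUE)
  expect_named(coef(fit), c("alpha_gain", "alpha_loss", "beta"))
  expect_equal(fit$bic, 2 * fit$nll + 3 * log(fit$n_trials_used))
})

test_that("prediction errors are labeled by sign with zeros excluded", {
  expect_equal(classify_pe_sign(c(1.0, -0.3, 0.0)),
               c("positive", "negative", "excluded"))
  expect_equal(classify_pe_sign(numeric(0)), character(0))
  # first gain trial from V0 = 0 paying $1 is necessarily positive
  log <- make_choice_log("gain", "A;B", "A", 1, two_cue_table)
  fit_pe <- 1 - 0
  expect_equal(classify_pe_sign(fit_pe), "positive")
})

test_that("model methods expose the fit the standard way", {
  sched <- build_schedule("mil", config = list(n_per_condition = 30),
                          seed = 71)
  log <- simulate_choices(sched, agent_params(0.4, 5), seed = 72)
  fit <- fit_rw(log)
  expect_s3_class(fit, "rwfit")
  expect_length(residuals(fit), fit$n_trials_used)
  expect_equal(unname(residuals(fit)), fit$pe$pe)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2)
  expect_equal(as.numeric(ll), fit$log_likelihood)
  pr <- predict(fit)
  expect_true(all(pr$p_chosen > 0 & pr$p_chosen < 1))
  expect_equal(fitted(fit), pr$p_chosen)
  sim <- simulate(fit, seed = 73, schedule = sched)
  expect_s3_class(sim, "choice_log")
  expect_equal(nrow(sim), nrow(sched$trials))
  expect_output(print(summary(fit)), "maximum-likelihood")
})
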