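test_that("age regression centers predictors and standardizes the slope", {
  set.seed(130)
  age <- runif(40, 22, 85)
  # exact linear dependence: standardized beta must be -1
  exact <- suppressWarnings(
    age_effect_regression(data.frame(age = age, value = -0.2 * age)))
  expect_equal(exact$std_beta, -1)

  value <- 1.5 - 0.01 * age + rnorm(40, 0, 0.2)
  ar <- age_effect_regression(data.frame(age = age, value = value))
  # intercept equals the sample mean when predictors are mean-centered
  expect_equal(unname(ar$intercept["Estimate"]), mean(value))
  # slopes invariant to age centering
  ar2 <- age_effect_regression(data.frame(age = age - 50, value = value))
  expect_equal(ar$linear[["Estimate"]], ar2$linear[["Estimate"]])
  expect_equal(ar$std_beta, ar2$std_beta)
  # linear-only variant drops the quadratic row
  expect_null(age_effect_regression(data.frame(age = age, value = value),
                                    include_quadratic = FALSE)$quadratic)
  expect_error(age_effect_regression(data.frame(age = rep(50, 10),
                                                value = rnorm(10))),
               "zero variance")
})

test_that("age regression rejects at the nominal rate under the null", {
  set.seed(131)
  rej <- vapply(1:400, function(i) {
    age <- runif(39, 22, 85)
    ar <- age_effect_regression(data.frame(age = age, value = rnorm(39)))
    ar$linear[["Pr(>|t|)"]] < 0.05
  }, logical(1))
  expect_true(binom_ci_contains(sum(rej), 400, 0.05))
})

test_that("learning performance counts choices of the better cues", {
  # hand-built 4-trial log with 3 optimal choices
  log <- make_choice_log(
    condition = rep("gain", 4), cue_ids = rep("A;B", 4),
    chosen = c("A", "A", "B", "A"), outcome = c(1, 0, 1, 1),
    cues = two_cue_table
  )
  expect_equal(performance_metrics(log, "MIL"), 0.75)
  # always-optimal play scores 1.0
  opt <- make_choice_log(rep("gain", 6), rep("A;B", 6), rep("A", 6),
                         rep(1, 6), two_cue_table)
  expect_equal(performance_metrics(opt, "MIL"), 1.0)
  # neutral trials are excluded from scoring
  neutral_cues <- rbind(two_cue_table,
                        data.frame(cue_id = c("n1", "n2"), win_prob = 1,
                                   valence = "neutral"))
  mixed <- make_choice_log(c("gain", "neutral"), c("A;B", "n1;n2"),
                           c("B", "n1"), c(0, 0), neutral_cues)
  expect_equal(performance_metrics(mixed, "MIL"), 0)
  expect_error(performance_metrics(
    make_choice_log("neutral", "n1;n2", "n1", 0, neutral_cues), "MIL"),
    "no scoreable")
})

test_that("expanded-task top-2 metric is chance-calibrated for random play", {
  sched <- build_schedule("expanded",
                          config = list(block_lengths = c(2500, 2500)),
                          seed = 132)
  log <- simulate_choices(sched, agent_params(strategy = "random"),
                          seed = 133)
  pm <- performance_metrics(log, "EXPANDED")
  expect_true(binom_ci_contains(round(pm$overall * 5000), 5000, 0.5))
  expect_equal(nrow(pm$per_block), 2L)
})

test_that("WSLS adherence scores prescriptions and flags full adherence", {
  # 2-trial log matching WSLS once: flagged despite the tiny sample
  log2 <- make_choice_log(rep("gain", 2), rep("A;B", 2), c("A", "A"),
                          c(1, 1), two_cue_table)
  w2 <- wsls_adherence(log2)
  expect_equal(w2$proportion, 1.0)
  expect_true(w2$exclude)

  # an agent that always repeats its choice: adherence equals the win rate
  # of the preceding trials, and full adherence is not reached
  set.seed(134)
  outcomes <- rbinom(60, 1, 2 / 3)
  rep_log <- make_choice_log(rep("gain", 60), rep("A;B", 60),
                             rep("A", 60), outcomes, two_cue_table)
  w <- wsls_adherence(rep_log)
  expect_equal(w$proportion, mean(outcomes[-60] > 0))
  expect_false(w$exclude)
  expect_error(wsls_adherence(log2[1, ]), "at least 2")
})

test_that("mixed ANOVA matches a hand-computed sums-of-squares oracle", {
  set.seed(135)
  n1 <- 18
  n2 <- 30
  scores <- data.frame(
    subject = rep(sprintf("s%02d", 1:(n1 + n2)), each = 2),
    group = rep(rep(c("young", "older"), c(n1, n2)), each = 2),
    length = rep(c("short", "long"), n1 + n2),
    score = runif(2 * (n1 + n2))
  )
  out <- mixed_anova_2x2(scores)

  # transparent cell-mean sums of squares for the balanced-within design
  wide <- reshape(scores, idvar = c("subject", "group"),
                  timevar = "length", direction = "wide")
  y <- as.matrix(wide[, c("score.short", "score.long")])
  g <- wide$group
  n_g <- table(g)
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, g, mean)
  ss_group <- 2 * sum(n_g * (grp_mean - grand)^2)
  ss_subj <- 2 * sum((subj_mean - grp_mean[g])^2)
  len_mean <- colMeans(y)
  ss_len <- sum(n_g) * sum((len_mean - grand)^2)
  cell <- rbind(tapply(y[, 1], g, mean), tapply(y[, 2], g, mean))
  ss_cells <- sum(t(outer(n_g, c(1, 1))) * (cell - grand)^2)
  ss_int <- ss_cells - ss_group - ss_len
  # within residual: total SS minus all modeled strata
  ss_total <- sum((y - grand)^2)
  ss_wres <- ss_total - ss_group - ss_subj - ss_len - ss_int
  n <- sum(n_g)
  f_group <- (ss_group / 1) / (ss_subj / (n - 2))
  f_len <- (ss_len / 1) / (ss_wres / (n - 2))
  f_int <- (ss_int / 1) / (ss_wres / (n - 2))
  expect_equal(out$group$F, f_group, tolerance = 1e-10)
  expect_equal(out$length$F, f_len, tolerance = 1e-10)
  expect_equal(out$interaction$F, f_int, tolerance = 1e-10)
  expect_equal(out$length$df2, n - 2)
  expect_equal(out$interaction$df1, 1)
})

test_that("mixed ANOVA degenerate profiles give the forced F values", {
  subj <- sprintf("s%02d", 1:12)
  base <- data.frame(
    subject = rep(subj, each = 2),
    group = rep(rep(c("a", "b"), each = 6), each = 2),
    length = rep(c("short", "long"), 12)
  )
  # constant data: no variance anywhere, all F = 0
  const <- transform(base, score = 0.5)
  out0 <- mixed_anova_2x2(const)
  expect_equal(out0$length$F, 0)
  expect_equal(out0$group$F, 0)
  expect_equal(out0$interaction$F, 0)
  # parallel profiles: identical improvement in both groups
  set.seed(136)
  subj_base <- rnorm(12)
  par <- base
  par$score <- subj_base[match(par$subject, subj)] +
    ifelse(par$length == "long", 0.3, 0)
  outp <- mixed_anova_2x2(par)
  expect_equal(outp$interaction$F, 0)
  expect_gt(outp$length$F, 0)
  expect_error(mixed_anova_2x2(const[-1, ]), "exactly one score")
})

test_that("mixed ANOVA rejects at the nominal rate under the null", {
  set.seed(137)
  ps <- t(vapply(1:400, function(i) {
    scores <- data.frame(
      subject = rep(sprintf("s%02d", 1:48), each = 2),
      group = rep(rep(c("young", "older"), c(18, 30)), each = 2),
      length = rep(c("short", "long"), 48),
      score = rnorm(96)
    )
    out <- mixed_anova_2x2(scores)
    c(out$length$p, out$group$p, out$interaction$p)
  }, numeric(3)))
  for (j in 1:3) {
    expect_true(binom_ci_contains(sum(ps[, j] < 0.05), 400, 0.05))
  }
})

test_that("follow-up t tests use the study's df conventions", {
  set.seed(138)
  scores <- data.frame(
    subject = rep(sprintf("s%02d", 1:48), each = 2),
    group = rep(rep(c("young", "older"), c(18, 30)), each = 2),
    length = rep(c("short", "long"), 48),
    score = runif(96)
  )
  ft <- group_comparison_tests(scores)
  expect_equal(nrow(ft), 4L)
  paired <- ft[grep("within (young|older)$", ft$comparison), ]
  expect_setequal(paired$df, c(17, 29))
  indep <- ft[grep("block$", ft$comparison), ]
  expect_equal(indep$df, c(46, 46))   # pooled: n1 + n2 - 2

  # identical short/long scores within a group: paired t = 0
  flat <- scores
  flat$score <- rep(runif(48), each = 2)
  ft0 <- group_comparison_tests(flat)
  expect_equal(ft0$t[grep("within young$", ft0$comparison)], 0)
})
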