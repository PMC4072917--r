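# rlbold

Forward simulation and model-based analysis of probabilistic
reward-learning experiments, built for validating the analysis chain used
to study how the neural coding of reward *prediction errors* changes across
the adult lifespan.

## The problem

A recurring finding in the cognitive neuroscience of aging is a
dissociation: frontostriatal responses to reward *outcomes* stay intact in
older adults, while the trial-by-trial coupling of those regions to reward
*prediction errors* — the teaching signal that drives learning — declines
with age. Establishing that dissociation requires a long analysis chain:

1. a probabilistic choice task (and a non-learning control task),
2. a Rescorla–Wagner learner fit to each subject's choices by maximum
   likelihood, `V ← V + α (r − V)` with softmax choice
   `P(i) ∝ exp(β V_i)`, yielding a signed prediction-error (PE) series
   `δ_t = r_t − V_t`,
3. a first-level GLM in which the PE series parametrically modulates the
   feedback response (gamma-variate HRF, drift nuisance, t→z conversion),
4. second-level regressions of the subject-level coefficients on age, and
5. a behavioral "learning-limits" experiment analyzed with a mixed-design
   block-length × age-group ANOVA.

Every link in that chain can hide a bug that masquerades as (or masks) an
age effect. `rlbold` implements the whole chain on synthetic data whose
ground truth is known — age-declining PE coupling, age-stable outcome
response, group-level learning-rate deficits — so each inferential step can
be validated against the generative model: noise-free round trips recover
coupling parameters to machine precision, null simulations hit nominal
type-I rates, and cohorts built with the hypothesized structure yield the
expected dissociation and block-length patterns.

It is aimed at researchers who build or teach model-based fMRI pipelines
and want a fully inspectable, deterministic testbed rather than real (and
undepositable) BOLD data.

## What's in the box

| Stage | Functions |
|---|---|
| Task designs | `build_schedule()` (MIL 3×24, MID 6×15, expanded 4-cue 25/75/25/75), `sample_outcome()`, `adaptive_target_duration()` |
| Agents | `simulate_choices()` (RW/softmax, WSLS, random), `simulate_mid_performance()`, `simulate_staircase_run()` |
| Model fitting | `fit_rw()` → classed `rwfit` (`coef`, `logLik`, `residuals` = PE series, `predict`, `simulate`), `negative_log_likelihood()`, `classify_pe_sign()` |
| BOLD synthesis | `gamma_hrf()`, `build_event_regressor()`, `synthesize_roi_timeseries()`, `coupling_spec()` |
| First level | `build_design_matrix()` (parametric-PE, binary-contrast, MID modes), `fit_glm()`, `t_to_z()` |
| Time courses | `extract_peristimulus()`, `condition_contrast_curves()`, `within_sample_t()` |
| Group level | `age_effect_regression()`, `performance_metrics()`, `wsls_adherence()`, `mixed_anova_2x2()`, `group_comparison_tests()` |
| Cohorts & orchestration | `cohort_config()`, `generate_cohort()`, `study2_cohort()`, `run_study1_mil()`, `run_study1_mid()`, `run_study2()`, `run_pipeline()` |

Schedules, choice logs and ROI series serialize to TSV and fits to JSON
(`write_schedule_tsv()` and friends).

## Worked example

Simulate one subject on the learning task, fit the model, and invert a
synthetic ROI series:

```r
library(rlbold)

sched <- build_schedule("mil", seed = 1)                 # 72 trials
log   <- simulate_choices(sched, agent_params(alpha = 0.3, beta = 5), seed = 2)
performance_metrics(log, "MIL")
#> [1] 0.75                       # fraction of better-cue choices

fit <- fit_rw(log)
summary(fit)
#> RW/softmax maximum-likelihood fit
#>
#> Coefficients:
#> alpha  beta
#> 0.319 3.426
#>
#> logLik -21.952  BIC 51.65  (n = 48 learning trials, converged)
#> Mean NLL/trial 0.4573 (chance for 2 cues: 0.6931)
#>
#> Prediction errors:
#> positive negative excluded
#>       25       21        2
#> range [-1.000, 1.000]
```

The recovered learning rate (0.319) and inverse temperature (3.43) sit near
the generating values (0.3, 5 — β is weakly identified at 48 trials), and
the per-trial NLL is well below the 2-cue chance level ln 2 ≈ 0.693. Now
couple the fitted PE series into a BOLD series at 0.8 percent signal change
per PE unit, with AR(1) noise, and recover it with the parametric GLM:

```r
pe <- rep(NA_real_, 72)
pe[match(fit$pe$trial, sched$trials$trial)] <- fit$pe$pe
ts  <- synthesize_roi_timeseries(sched, pe,
         coupling_spec(pe_coupling = 0.8, noise_sd = 0.5),
         roi_label = "MPFC", seed = 3)
glm <- fit_glm(ts, build_design_matrix(sched, pe, "mil-parametric"))
glm_stat(glm, "pe_gain")      # 1.101  (true coupling 0.8, noise sd 0.5)
glm_stat(glm, "pe_gain", "z") # 6.56   (the PE regressor is detected)
```

A full synthetic study — 39 learning-arm subjects, 37 non-learning-arm
subjects, and the 18 + 30 behavioral arm — runs with one call:

```r
res <- run_pipeline(cohort_config(), seed = 1)
print(res)   # second-level age betas, time-course t, Study-2 ANOVA
```

## Design notes

The methods vignette (`vignettes/prediction-error-pipeline.Rmd`) documents
the model assumptions, every tunable default (HRF shape, feedback timing,
staircase rule, cohort effect sizes) with its rationale, the numerical
choices, and what passing simulations do and do not establish about real
data.
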