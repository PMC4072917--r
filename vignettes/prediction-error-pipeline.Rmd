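---
title: "Simulating and recovering prediction-error signals in reward tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and recovering prediction-error signals in reward tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(rlbold)
```

## What the package models

Model-based imaging studies of reward learning tie a trial-level learning
model to a voxel- or ROI-level regression model. A subject repeatedly
chooses between probabilistic reward cues; a Rescorla–Wagner learner tracks
each cue's value $V$ and updates it by the delta rule

$$V \leftarrow V + \alpha\,(r - V),$$

where $r$ is the received outcome, $\alpha \in [0,1]$ the learning rate, and
$\delta = r - V$ the signed *prediction error* (PE). Choices follow a
softmax with inverse temperature $\beta \ge 0$:
$P(i) \propto \exp(\beta V_i)$. The fitted trial-wise PE series then enters
a first-level GLM as a parametric modulator of the feedback response, and
the subject-level PE coefficients are regressed on age at the second level.

`rlbold` implements that full loop on synthetic data: task generation,
behaving agents, maximum-likelihood model fitting, BOLD forward simulation,
GLM inversion, time-course contrasts, and group inference. Because every
stage of the generative model is explicit, the pipeline's inferential
machinery can be validated against known ground truth — which is the
package's purpose. No real subject data are involved anywhere.

## Task designs

Three designs are built by `build_schedule()`:

* **MIL** (monetary incentive learning): three interleaved cue-pair
  conditions — gain, loss, neutral — each presented 24 times (72 trials).
  The better gain cue pays +\$1 with probability 2/3 and \$0 otherwise; the
  worse cue reverses the odds. The loss pair mirrors this with outcomes
  {−\$1, \$0}, and neutral cues always pay \$0. Trials last 10 s with ITIs
  drawn uniformly from {2, 4, 6} s, and the better cue appears equally often
  left and right (so odd per-condition counts are rejected).
* **MID** (monetary incentive delay): six cue types crossing valence with
  stake (\$0, \$0.50, \$5), 15 repetitions each (90 trials), 8-s trials. No
  learning is required: a speeded buttonpress to a target determines the
  outcome, and an adaptive timing algorithm holds each cue type's hit rate
  near 66%.
* **Expanded** four-cue task: a gain-only behavioral task with win
  probabilities 40/50/60/70% (adjacent expected values exactly 10 cents
  apart), played as four blocks of 25, 75, 25, 75 trials in the fixed order
  short–long–short–long, fresh cues per block. It is self-paced, so the
  schedule carries a nominal 3-s trial duration and no ITI.

Schedule randomization and outcome draws use separately seeded RNG streams,
so a schedule can be regenerated without consuming outcome randomness.

### The adaptive timing rule

The staircase that sets the MID target duration is specified here as a
percentile tracker: the duration is $m + z_{0.66}\,s$ with $m$ and $s$ the
mean and SD of the last 20 reaction times and $z_{0.66} = \Phi^{-1}(0.66)
\approx 0.412$, seeded before any history exists with the practice mean RT
plus the same offset at a nominal practice SD of 50 ms, and floored at
50 ms. For approximately Gaussian RTs this targets a 66% hit rate. With the
package's lognormal RT model (median 300 ms, $\sigma = 0.2$) the achieved
long-run rate is slightly above target (≈68%) because the right-skewed
distribution puts more mass below $m + z s$ than a Gaussian would; this
bias is inherent to the mean+SD form of the tracker and is well inside the
±3-point band the design aims for. A degenerate zero-variance responder
drives the duration to exactly its constant RT, hence a hit rate of 1 —
flagged in the tests as the known edge case.

## Agents

`simulate_choices()` plays RW/softmax, win–stay/lose–shift (WSLS), and
random agents. Design choices:

* Initial values are 0 for every cue, gain and loss alike — symmetric
  around the \$0 reference outcome.
* Only the chosen cue updates: agents observe only the outcome of their own
  choice.
* The WSLS "win" is valence-aware: a gain-trial win is a strictly positive
  outcome; a loss-trial "win" is avoiding the loss (outcome \$0). After a
  win the agent repeats its previous choice *of the same condition stream*
  (same block and cue set); otherwise it switches uniformly among the other
  cues.
* MID reaction times are lognormal (positive, right-skewed), with
  configurable median and log-scale scatter.

## Model fitting

`fit_rw()` maximizes the choice likelihood over $\alpha \in [0,1]$ and
$\beta \in [0, 20]$ with L-BFGS-B from a 3×3 grid of starts (objective
tolerance well below 1e−6), excluding neutral trials, and returns a classed
`rwfit` with `coef()`, `logLik()`, `residuals()` (the signed PE series),
`predict()`, and `simulate()` methods. BIC is $2\,\mathrm{NLL} + k \ln n$
with $k = 2$ parameters ($k = 3$ when the optional per-valence learning
rates are fit). One $(\alpha, \beta)$ pair is shared across gain and loss
pairs by default: the analysis splits PE by valence at the GLM stage, not
inside the learner. The likelihood recursion is compiled (Rcpp) because
parameter-recovery studies evaluate it tens of thousands of times; a plain
R reference implementation lives in the test suite and the two are checked
against each other.

Ties at PE = 0 belong to neither sign class: `classify_pe_sign()` labels
them `excluded`, mirroring the binary gain/nongain contrast in which \$1
from $V < 1$ is positive and \$0 from $V > 0$ is negative.

```{r fit-example}
sched <- build_schedule("mil", seed = 1)
log <- simulate_choices(sched, agent_params(alpha = 0.3, beta = 5), seed = 2)
fit <- fit_rw(log)
summary(fit)
```

## BOLD synthesis and inversion

`synthesize_roi_timeseries()` is the forward model whose inversion is the
GLM. The hemodynamic kernel is the gamma-variate
$h(t) = (t/(pw))^p e^{p - t/w}$ with defaults $p = 8.6$, $w = 0.547$ —
zero at $t=0$, unit peak at $t = pw \approx 4.7$ s. Per-condition unit
responses and a parametric PE term (coupling × mean-centered PE, the
standard parametric-modulation construction that decorrelates the modulator
from the event regressor) are placed at feedback onsets — 6 s into the
10-s MIL trial and 6 s into the 8-s MID trial by default, a declared
assumption since intra-trial event timing is configurable. Drift is a
baseline/linear/quadratic polynomial on the volume index normalized to
$[-1, 1]$; noise is AR(1) Gaussian (coefficient 0.3) with a marginal SD in
percent-signal-change (PSC) units.

The percent component is embedded multiplicatively around a raw baseline of
100 and converted back to PSC relative to the run mean. Centering the
signal before embedding makes the noise-free run mean equal the baseline
exactly, so the generative→inferential round trip recovers the coupling to
machine precision — a property the tests assert — while PSC output remains
mean-zero and invariant to rescaling the raw series.

First-level designs (`build_design_matrix()`) come in three modes — the
parametric-PE MIL model (2 regressors of interest: signed PE on gain and on
loss trials), the model-free binary gain/nongain MIL variant, and the MID
contrast model (4 regressors of interest: gain and loss anticipation
contrasts, gain-vs-nongain and nonloss-vs-loss outcome contrasts) — always
completed by the trend columns and optional motion nuisance. `fit_glm()` is
ordinary least squares with homoskedastic errors; the AR(1) noise is
deliberately *not* prewhitened, accepted as model mismatch as in the
era's single-subject practice, and absorbed into the calibration tests'
tolerances. t statistics convert to z through the t CDF via
log-probabilities so large |t| stay finite.

## Time courses and group inference

`extract_peristimulus()` cuts TR-gridded trial-locked windows (16 s → 8
timepoints at TR = 2 s); `condition_contrast_curves()` averages them by
condition and takes the scalar contrast over the hemodynamic-lag-adjusted
feedback window, by default 10–14 s after trial onset (feedback at 6 s plus
a 4–8-s lag bracketing the ≈4.7-s HRF peak; configurable, since the
interval is defined graphically in this literature). `within_sample_t()` is
a one-sample t across subjects that reports the zero-variance case as an
infinite t rather than an error. Plot-style age binning uses young 22–44,
middle 45–60, older 61+.

Second-level `age_effect_regression()` regresses a per-subject statistic on
mean-centered age and squared age, so the intercept is the sample mean
effect controlling for age; it reports the standardized linear coefficient
$\beta = b\,\mathrm{SD(age)}/\mathrm{SD(value)}$. The Study 2 analysis is a
2×2 mixed-design ANOVA (between: age group; within: block length; all F
tests on df (1, n−2)) with follow-up paired t tests within group and
pooled-variance independent t tests between groups (df $n_1+n_2-2 = 46$ at
the default sample sizes — the pooled form is chosen to reproduce that df
convention). No multiple-testing correction is applied to the behavioral
follow-ups. Subjects who follow WSLS on every single scoreable trial are
excluded before analysis.

## The synthetic cohorts

The generators encode the hypothesis under study — PE coupling declines
with age while outcome responses do not — as ground truth, with effect
sizes chosen once for comfortable power at the study's own sample sizes
(true effect sizes are unknowable from the published statistics, which came
from real BOLD data):

* **Imaging cohort** (`cohort_config()`, n = 39, ages uniform 22–85, the
  first 37 also serving the non-learning arm): learning rate age-stable at
  0.35 (SD 0.08, clipped to [0, 1]); $\beta$ lognormal (median 4);
  PE coupling $0.8 - 0.010\,(\mathrm{age}-53)$ PSC per PE unit (SD 0.08);
  outcome amplitude age-stable at 0.6 PSC (SD 0.08); BOLD noise SD 0.5 PSC,
  AR(1) 0.3. An age-stable learning rate matches the observation that
  learning performance in a scanned sample of this size need not correlate
  with age even when the neural coupling does.
* **Behavioral cohort** (`study2_cohort()`, 18 younger aged 19–33, 30 older
  aged 67–86): the learning-rate deficit is modeled at the group level —
  young $\alpha \sim N(0.60, 0.04)$, older $\alpha \sim N(0.055, 0.012)$,
  both with $\beta$ lognormal (median 8). Young learners approach asymptote
  within a 25-trial block; older learners need the 75-trial block. A
  within-band age gradient was deliberately dropped: it inflates
  within-group heterogeneity and blurs the block-length × group contrast
  that the design exists to probe.

`run_pipeline()` chains everything: per subject, simulate → fit → PE series
→ BOLD → GLM → time courses, then pools into the second-level age
regressions and the behavioral ANOVA, collecting per-subject failures and
WSLS exclusions rather than aborting. All per-subject RNG streams derive
from one master seed, so a full run is bit-reproducible.

```{r pipeline, eval = FALSE}
res <- run_pipeline(cohort_config(), seed = 1)
print(res)
```

## What the simulations do and do not show

The synthetic data reproduce the *statistical structure* the analysis
assumes: trial schedules with the printed counts and payoff probabilities,
PE-modulated event responses with drift and autocorrelated noise, and
cohorts with (or without) age-linked coupling. They omit much of what makes
real BOLD data hard — spatial structure and smoothing, motion and
physiological artifacts, HRF variability across subjects and regions,
model misspecification of the learner itself. Green tests therefore certify
that the pipeline's inference is correct *when its assumptions hold*, not
that those assumptions hold in any real dataset. Published group statistics
from real cohorts (specific t, F and β values) are estimates from data that
were never deposited and are not reproducible from simulation; what is
reproducible — and what the acceptance checks assert — are the task-design
quantities the simulators embody and the qualitative dissociation and
block-length patterns.

## Numerical choices and problem sizes

* Optimizer: L-BFGS-B, 9 starts, bounds $\alpha \in [0,1]$,
  $\beta \in [0,20]$; non-convergence from every start is an error, partial
  convergence a warning.
* Zero-variance and degenerate inputs are defined, not errors, wherever the
  analysis can meet them: F = 0 for null ANOVA effects, t = 0 / ±∞ for
  constant difference samples, PE = 0 trials excluded from sign classes,
  empty schedules allowed.
* The validation suites run at deliberately modest sizes — e.g. 50
  simulated experiments for the imaging dissociation, 40 for the behavioral
  pattern, 20 recovery fits at 10,000 trials, 1,000-replicate calibration
  nulls — sized so the whole suite completes on a laptop-class single CPU
  in minutes while leaving the Monte Carlo error far smaller than the
  effects being checked.

## Known limitations

* The RW/softmax learner is the simplest member of its family; actor–critic
  and dual-learning-rate variants are out of scope (a per-valence learning
  rate is available as a sensitivity flag).
* OLS standard errors ignore the AR(1) noise; single-subject t statistics
  are mildly anticonservative under autocorrelation, which the calibration
  tolerances absorb.
* The adaptive-timing tracker holds ≈68% rather than exactly 66% for
  skewed RTs, as discussed above.
* The expanded-task agents cannot reproduce a perfectly flat young
  length-effect: even fast learners pay an exploration cost in the first
  trials of every fresh block, so the young group gains a little from
  longer blocks too. The group contrast remains directionally faithful.
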