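test_that("gamma-variate HRF has the closed-form shape", {
  p <- 8.6
  w <- 0.547
  tt <- seq(0, 20, by = 0.01)
  h <- gamma_hrf(tt, p, w)
  expect_equal(h[1], 0)                      # h(0) = 0
  expect_equal(gamma_hrf(c(0, p * w), p, w)[2], 1)  # unit peak at p*w
  expect_lt(abs(tt[which.max(h)] - 4.70), 0.011)    # peak near 4.70 s
  expect_true(all(h >= 0))
  expect_error(gamma_hrf(tt, p = -1), "positive")
  expect_error(gamma_hrf(c(1, 0.5)), "increasing")
})

test_that("event regressors convolve impulses with the kernel", {
  k <- hrf_kernel(tr = 2, length_s = 20)
  z <- build_event_regressor(c(10, 30), c(0, 0), n_volumes = 40, tr = 2,
                             kernel = k)
  expect_equal(z, numeric(40))
  # unit impulse reproduces the shifted kernel
  r <- build_event_regressor(10, 1, n_volumes = 40, tr = 2, kernel = k)
  expect_equal(r[6:16], k)
  expect_equal(r[1:5], numeric(5))
  # superposition: two overlapping events equal the sum of shifted kernels
  r2 <- build_event_regressor(c(10, 14), c(1, 2), n_volumes = 40, tr = 2,
                              kernel = k)
  single <- function(onset, amp) {
    build_event_regressor(onset, amp, n_volumes = 40, tr = 2, kernel = k)
  }
  expect_equal(r2, single(10, 1) + single(14, 2))
  expect_error(build_event_regressor(100, 1, n_volumes = 40, tr = 2,
                                     kernel = k), "beyond")
})

test_that("null coupling with no drift or noise gives an all-zero series", {
  sched <- build_schedule("mil", config = list(n_per_condition = 4),
                          seed = 81)
  cp <- coupling_spec(event_amplitude = 0, pe_coupling = 0, noise_sd = 0,
                      drift = c(0, 0, 0))
  ts <- synthesize_roi_timeseries(sched, rep(0, 12), cp, seed = 82)
  expect_equal(ts$values, numeric(ts$n_volumes))
})

test_that("PSC conversion is mean-zero and scale invariant", {
  set.seed(83)
  raw <- 100 + rnorm(50)
  psc <- psc_convert(raw)
  expect_equal(mean(psc), 0)
  expect_equal(psc_convert(3.7 * raw), psc)
  expect_error(psc_convert(raw - 200), "positive")
})

test_that("the GLM inverts the noise-free forward model exactly", {
  sched <- build_schedule("mil", seed = 84)
  log <- simulate_choices(sched, agent_params(0.35, 4), seed = 85)
  fit <- fit_rw(log)
  pe <- rep(NA_real_, 72)
  pe[match(fit$pe$trial, sched$trials$trial)] <- fit$pe$pe
  cp <- coupling_spec(event_amplitude = 0.4, pe_coupling = 0.75,
                      noise_sd = 0, drift = c(0.3, 0.5, 0.2))
  ts <- synthesize_roi_timeseries(sched, pe, cp, seed = 86)
  glm <- fit_glm(ts, build_design_matrix(sched, pe, "mil-parametric"))
  expect_equal(glm_stat(glm, "pe_gain"), 0.75, tolerance = 1e-10)
  expect_equal(glm_stat(glm, "pe_loss"), 0.75, tolerance = 1e-10)
  expect_equal(glm_stat(glm, "ev_gain"), 0.4, tolerance = 1e-10)

  # linearity: doubling the coupling doubles the recovered coefficient
  cp2 <- coupling_spec(event_amplitude = 0.4, pe_coupling = 1.5,
                       noise_sd = 0, drift = c(0.3, 0.5, 0.2))
  ts2 <- synthesize_roi_timeseries(sched, pe, cp2, seed = 86)
  glm2 <- fit_glm(ts2, build_design_matrix(sched, pe, "mil-parametric"))
  expect_equal(glm_stat(glm2, "pe_gain"), 2 * glm_stat(glm, "pe_gain"),
               tolerance = 1e-8)
})

test_that("coupling recovery is unbiased under AR(1) noise", {
  sched <- build_schedule("mil", seed = 87)
  log <- simulate_choices(sched, agent_params(0.35, 4), seed = 88)
  fit <- fit_rw(log)
  pe <- rep(NA_real_, 72)
  pe[match(fit$pe$trial, sched$trials$trial)] <- fit$pe$pe
  design <- build_design_matrix(sched, pe, "mil-parametric")
  est <- vapply(1:40, function(s) {
    cp <- coupling_spec(pe_coupling = 0.6, noise_sd = 0.5, ar1 = 0.3)
    ts <- synthesize_roi_timeseries(sched, pe, cp, seed = 900 + s)
    glm_stat(fit_glm(ts, design), "pe_gain")
  }, 0)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.6), 3 * se + 0.02)
})

test_that("synthetic series are reproducible and carry the TR grid", {
  sched <- build_schedule("mil", config = list(n_per_condition = 4),
                          seed = 89)
  cp <- coupling_spec()
  a <- synthesize_roi_timeseries(sched, rep(0.5, 12), cp, seed = 90)
  b <- synthesize_roi_timeseries(sched, rep(0.5, 12), cp, seed = 90)
  expect_identical(a$values, b$values)
  expect_equal(a$tr_s, 2)
  expect_equal(length(a$values), a$n_volumes)
  expect_equal(a$n_volumes, ceiling(schedule_run_length(sched) / 2))
  expect_equal(mean(a$values), 0)
})
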