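#' Rescorla-Wagner delta-rule update
#'
#' The prediction error is the difference between the received and expected
#' reward, `pe = outcome - value`; the value moves toward the outcome by a
#' fraction `alpha` of that error.
#'
#' @param value current value estimate (dollars).
#' @param outcome received outcome (dollars).
#' @param alpha learning rate in `[0, 1]`.
#' @return list with `value` (updated estimate) and `pe` (signed error).
#' @export
rw_update <- function(value, outcome, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  pe <- outcome - value
  list(value = value + alpha * pe, pe = pe)
}

# Compile a choice_log into index vectors for the likelihood loop.
# Neutral-condition trials carry no choice information and are excluded.
prepare_learning_data <- function(log) {
  stopifnot(inherits(log, "choice_log") || is.data.frame(log))
  cues <- attr(log, "cues")
  keep <- log$condition != "neutral"
  log <- log[keep, , drop = FALSE]
  if (nrow(log) == 0L) stop("no learning trials after excluding neutral")
  avail <- split_cue_ids(log$cue_ids)
  ids <- unique(unlist(avail, use.names = FALSE))
  avail_idx <- lapply(avail, match, ids)
  chosen_idx <- match(log$chosen, ids)
  within_idx <- as.integer(
    mapply(function(a, ch) match(ch, a), avail_idx, chosen_idx))
  valence <- if (!is.null(cues)) {
    cues$valence[match(ids, cues$cue_id)]
  } else rep("gain", length(ids))
  list(trial = log$trial, condition = log$condition,
       chosen = log$chosen, outcome = log$outcome,
       ids = ids, avail_idx = avail_idx, chosen_idx = chosen_idx,
       within_idx = within_idx, cue_valence = valence,
       n = nrow(log))
}

# Core likelihood recursion (compiled): alpha is a per-cue vector
# (per-valence fitting maps each cue's valence to its own rate).
rw_nll_core <- function(alpha_by_cue, beta, d, return_pe = FALSE) {
  res <- .rw_nll_core_cpp(alpha_by_cue, beta, d$avail_idx, d$chosen_idx,
                          d$within_idx, d$outcome, length(d$ids), return_pe)
  if (return_pe) res else res$nll
}

#' Negative log-likelihood of a choice log under the RW/softmax model
#'
#' Values are propagated by the delta rule in trial order (only the chosen
#' cue updates, initial values 0) and each choice contributes
#' `-log P(chosen | values, beta)` under the softmax rule.
#' Neutral-condition trials are excluded.
#'
#' @param params an `agent_params` (alpha, beta) or a named list with
#'   `alpha` and `beta`.
#' @param log a `choice_log`.
#' @return scalar negative log-likelihood, `>= 0`.
#' @export
negative_log_likelihood <- function(params, log) {
  d <- prepare_learning_data(log)
  rw_nll_core(rep(params$alpha[1], length(d$ids)), params$beta, d)
}

#' Fit the RW/softmax learning model by maximum likelihood
#'
#' Maximizes the choice likelihood over `alpha` in `[0, 1]` and `beta` in
#' `[0, beta_max]` with L-BFGS-B from a 3 x 3 grid of starting points, then
#' reconstructs the trial-wise signed prediction-error series at the optimum.
#' One `(alpha, beta)` pair is shared across gain and loss conditions by
#' default; `per_valence_alpha = TRUE` fits separate gain and loss learning
#' rates for sensitivity analyses.
#'
#' @param log a `choice_log` from [simulate_choices()] (or read from disk).
#' @param beta_max upper bound for the inverse temperature (default 20).
#' @param per_valence_alpha fit separate learning rates per valence.
#' @return an object of class `rwfit` with components `coefficients`
#'   (alpha, beta), `log_likelihood`, `bic`, `n_trials_used`, `convergence`,
#'   and `pe` (data.frame: trial, condition, chosen, outcome, value_chosen,
#'   pe, pe_sign). Methods: `print`, `summary`, `coef`, `logLik`,
#'   `residuals` (the signed PE series), `fitted` (probability assigned to
#'   each observed choice), `predict`, `simulate`.
#' @export
fit_rw <- function(log, beta_max = 20, per_valence_alpha = FALSE) {
  d <- prepare_learning_data(log)
  k <- if (per_valence_alpha) 3L else 2L
  expand_alpha <- function(par) {
    if (per_valence_alpha) {
      ifelse(d$cue_valence == "loss", par[2], par[1])
    } else {
      rep(par[1], length(d$ids))
    }
  }
  obj <- function(par) {
    rw_nll_core(expand_alpha(par), par[k], d)
  }
  starts <- expand.grid(alpha = c(0.2, 0.5, 0.8), beta = c(0.5, 5, 15))
  lower <- c(rep(0, k - 1L), 0)
  upper <- c(rep(1, k - 1L), beta_max)
  best <- NULL
  any_converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    par0 <- c(rep(starts$alpha[s], k - 1L), starts$beta[s])
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed to converge from all starts")
  if (!any_converged) {
    warning("no optimizer start reported clean convergence; ",
            "returning the best point found")
  }
  at_opt <- rw_nll_core(expand_alpha(best$par), best$par[k], d,
                        return_pe = TRUE)
  pe <- data.frame(
    trial = d$trial, condition = d$condition, chosen = d$chosen,
    outcome = d$outcome, value_chosen = at_opt$value_chosen,
    pe = at_opt$pe, pe_sign = classify_pe_sign(at_opt$pe),
    stringsAsFactors = FALSE
  )
  coefs <- if (per_valence_alpha) {
    c(alpha_gain = best$par[1], alpha_loss = best$par[2], beta = best$par[3])
  } else {
    c(alpha = best$par[1], beta = best$par[2])
  }
  structure(
    list(coefficients = coefs, log_likelihood = -best$value,
         nll = best$value, n_trials_used = d$n,
         bic = 2 * best$value + k * base::log(d$n),
         convergence = any_converged, k = k, pe = pe,
         beta_max = beta_max, per_valence_alpha = per_valence_alpha,
         data = log, call = match.call()),
    class = "rwfit"
  )
}

#' Classify prediction errors by sign
#'
#' @param pe_series numeric vector of signed prediction errors.
#' @return character vector: `"positive"` (pe > 0), `"negative"` (pe < 0),
#'   `"excluded"` (pe exactly 0, which belongs to neither class).
#' @export
classify_pe_sign <- function(pe_series) {
  if (length(pe_series) == 0L) return(character(0))
  ifelse(pe_series > 0, "positive",
         ifelse(pe_series < 0, "negative", "excluded"))
}

#' @export
print.rwfit <- function(x, digits = 3, ...) {
  cat("Rescorla-Wagner/softmax fit by maximum likelihood\n")
  print(round(x$coefficients, digits))
  cat(sprintf("logLik %.3f on %d trials, BIC %.2f\n",
              x$log_likelihood, x$n_trials_used, x$bic))
  invisible(x)
}

#' @export
summary.rwfit <- function(object, ...) {
  sgn <- table(factor(object$pe$pe_sign,
                      levels = c("positive", "negative", "excluded")))
  out <- list(coefficients = object$coefficients,
              log_likelihood = object$log_likelihood,
              bic = object$bic, n_trials_used = object$n_trials_used,
              convergence = object$convergence,
              mean_nll_per_trial = object$nll / object$n_trials_used,
              pe_sign_counts = sgn,
              pe_range = range(object$pe$pe))
  class(out) <- "summary.rwfit"
  out
}

#' @export
print.summary.rwfit <- function(x, digits = 3, ...) {
  cat("RW/softmax maximum-likelihood fit\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nlogLik %.3f  BIC %.2f  (n = %d learning trials, %s)\n",
              x$log_likelihood, x$bic, x$n_trials_used,
              if (x$convergence) "converged" else "NOT converged"))
  cat(sprintf("Mean NLL/trial %.4f (chance for 2 cues: %.4f)\n",
              x$mean_nll_per_trial, log(2)))
  cat("\nPrediction errors:\n")
  print(x$pe_sign_counts)
  cat(sprintf("range [%.3f, %.3f]\n", x$pe_range[1], x$pe_range[2]))
  invisible(x)
}

#' @export
coef.rwfit <- function(object, ...) object$coefficients

#' @export
logLik.rwfit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k,
            nobs = object$n_trials_used, class = "logLik")
}

#' @describeIn fit_rw the signed prediction-error series at the optimum.
#' @param object,... method arguments.
#' @export
residuals.rwfit <- function(object, ...) {
  stats::setNames(object$pe$pe, object$pe$trial)
}

#' @export
fitted.rwfit <- function(object, ...) {
  predict(object)$p_chosen
}

#' @export
predict.rwfit <- function(object, newdata = NULL, ...) {
  log <- newdata %||% object$data
  d <- prepare_learning_data(log)
  cf <- object$coefficients
  alpha_by_cue <- if (object$per_valence_alpha) {
    ifelse(d$cue_valence == "loss", cf[["alpha_loss"]], cf[["alpha_gain"]])
  } else rep(cf[["alpha"]], length(d$ids))
  beta <- cf[["beta"]]
  v <- numeric(length(d$ids))
  p_chosen <- numeric(d$n)
  for (i in seq_len(d$n)) {
    ai <- d$avail_idx[[i]]
    p <- softmax_choice_probs(v[ai], beta)
    p_chosen[i] <- p[d$within_idx[i]]
    ci <- d$chosen_idx[i]
    v[ci] <- v[ci] + alpha_by_cue[ci] * (d$outcome[i] - v[ci])
  }
  data.frame(trial = d$trial, chosen = d$chosen, p_chosen = p_chosen,
             stringsAsFactors = FALSE)
}

#' @export
simulate.rwfit <- function(object, nsim = 1, seed = NULL, schedule, ...) {
  if (missing(schedule)) stop("supply the trial_schedule to simulate on")
  if (!is.null(seed)) set.seed(seed)
  cf <- object$coefficients
  alpha <- if (object$per_valence_alpha) cf[["alpha_gain"]] else cf[["alpha"]]
  params <- agent_params(alpha = alpha, beta = cf[["beta"]],
                         strategy = "rw_softmax")
  out <- lapply(seq_len(nsim), function(i) {
    simulate_choices(schedule, params)
  })
  if (nsim == 1) out[[1]] else out
}
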