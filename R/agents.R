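#' Agent parameters
#'
#' @param alpha learning rate in `[0, 1]` (RW agents).
#' @param beta softmax inverse temperature, `>= 0`.
#' @param strategy `"rw_softmax"`, `"wsls"` or `"random"`.
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.3, beta = 5,
                         strategy = c("rw_softmax", "wsls", "random")) {
  strategy <- match.arg(strategy)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  if (!is.numeric(beta) || beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, strategy = strategy),
            class = "agent_params")
}

#' Softmax choice probabilities
#'
#' P(i) proportional to exp(beta * value_i), computed stably by subtracting
#' the maximum of `beta * values` before exponentiating. Invariant to adding
#' a constant to all values; uniform at `beta = 0`.
#'
#' @param values finite numeric vector of value estimates.
#' @param beta inverse temperature `>= 0`.
#' @return probability vector summing to 1, same length as `values`.
#' @export
softmax_choice_probs <- function(values, beta) {
  if (length(values) == 0L) stop("empty value set")
  if (!all(is.finite(values))) stop("values must be finite")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("beta must be a single value >= 0")
  }
  b <- beta * values
  p <- exp(b - max(b))
  p / sum(p)
}

split_cue_ids <- function(x) strsplit(x, ";", fixed = TRUE)

# WSLS "win" reference depends on valence: gains/neutral win on a strictly
# positive outcome, losses "win" by avoiding the loss (outcome == 0).
wsls_win <- function(outcome, valence) {
  ifelse(valence == "loss", outcome == 0, outcome > 0)
}

#' Simulate choices on a learning-task schedule
#'
#' Plays one agent through a MIL or expanded schedule. RW/softmax agents keep
#' one value estimate per cue (initialized at 0), choose by softmax over the
#' available set, and update only the chosen cue by the delta rule. WSLS
#' agents repeat the previous choice of the same condition stream after a win
#' and switch uniformly among the other cues otherwise. Random agents choose
#' uniformly. Agents see only the chosen cue and its outcome, never the
#' generating probabilities.
#'
#' @param schedule a `trial_schedule` (MIL or EXPANDED).
#' @param params an `agent_params`.
#' @param seed optional integer seed for the outcome/choice RNG (independent
#'   of schedule generation).
#' @return a `choice_log`: data.frame with columns trial, block, condition,
#'   cue_ids, chosen, outcome, value_chosen (the agent's value of the chosen
#'   cue at choice time), plus a `cues` attribute (data.frame cue_id,
#'   win_prob, valence) for scoring.
#' @export
simulate_choices <- function(schedule, params, seed = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(params, "agent_params"))
  if (!is.null(seed)) set.seed(seed)
  tr <- schedule$trials
  n <- nrow(tr)
  cue_tab <- cue_table(schedule)
  values <- stats::setNames(numeric(nrow(cue_tab)), cue_tab$cue_id)
  avail <- split_cue_ids(tr$cue_ids)
  chosen <- character(n)
  outcome <- numeric(n)
  value_chosen <- numeric(n)
  last_choice <- list()  # per condition stream: list(cue, win)
  for (i in seq_len(n)) {
    cues_i <- avail[[i]]
    key <- paste(tr$block[i], tr$condition[i], sep = ":")
    pick <- switch(params$strategy,
      rw_softmax = {
        p <- softmax_choice_probs(values[cues_i], params$beta)
        cues_i[sample.int(length(cues_i), 1L, prob = p)]
      },
      wsls = {
        prev <- last_choice[[key]]
        if (is.null(prev)) {
          cues_i[sample.int(length(cues_i), 1L)]
        } else if (prev$win) {
          prev$cue
        } else {
          others <- setdiff(cues_i, prev$cue)
          others[sample.int(length(others), 1L)]
        }
      },
      random = cues_i[sample.int(length(cues_i), 1L)]
    )
    cue <- schedule$cues[[pick]]
    out <- sample_outcome(cue, 1L)
    chosen[i] <- pick
    outcome[i] <- out
    value_chosen[i] <- values[[pick]]
    if (params$strategy == "rw_softmax") {
      upd <- rw_update(values[[pick]], out, params$alpha)
      values[[pick]] <- upd$value
    }
    last_choice[[key]] <- list(cue = pick,
                               win = wsls_win(out, cue$valence))
  }
  log <- data.frame(
    trial = tr$trial, block = tr$block, condition = tr$condition,
    cue_ids = tr$cue_ids, chosen = chosen, outcome = outcome,
    value_chosen = value_chosen, stringsAsFactors = FALSE
  )
  attr(log, "cues") <- cue_tab
  attr(log, "task_kind") <- schedule$task_kind
  class(log) <- c("choice_log", "data.frame")
  log
}

cue_table <- function(schedule) {
  if (length(schedule$cues) == 0L) {
    return(data.frame(cue_id = character(0), win_prob = numeric(0),
                      valence = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    cue_id = vapply(schedule$cues, `[[`, "", "cue_id"),
    win_prob = vapply(schedule$cues, `[[`, 0, "win_prob"),
    valence = vapply(schedule$cues, `[[`, "", "valence"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Simulate responding on a MID schedule
#'
#' Reaction times are drawn from a lognormal model (positive and right-skewed
#' like human RTs). Each trial's target duration comes from the per-cue-type
#' adaptive timing algorithm ([adaptive_target_duration()]), seeded with the
#' responder's practice mean RT; a trial is a hit when the RT does not exceed
#' the target. Gain cues pay their magnitude on a hit and $0 on a miss; loss
#' cues deduct their magnitude on a miss and $0 on a hit.
#'
#' @param schedule a MID `trial_schedule`.
#' @param rt_model list: `median_ms` (default 300), `sdlog` (default 0.2).
#' @param staircase staircase settings passed to [adaptive_target_duration()];
#'   `seed_rt_ms` defaults to the practice mean implied by `rt_model`.
#' @param seed optional integer seed.
#' @return data.frame: trial, condition, magnitude, valence, rt_ms, target_ms,
#'   hit, outcome.
#' @export
simulate_mid_performance <- function(schedule, rt_model = list(),
                                     staircase = list(), seed = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (schedule$task_kind != "MID") stop("schedule is not a MID schedule")
  if (!is.null(seed)) set.seed(seed)
  median_ms <- rt_model$median_ms %||% 300
  sdlog <- rt_model$sdlog %||% 0.2
  stopifnot(median_ms > 0)
  if (is.null(staircase$seed_rt_ms)) {
    # practice mean of the lognormal RT model
    staircase$seed_rt_ms <- median_ms * exp(sdlog^2 / 2)
  }
  types <- schedule$cue_types
  tr <- schedule$trials
  n <- nrow(tr)
  rts <- numeric(n); targets <- numeric(n); hit <- logical(n)
  history <- stats::setNames(vector("list", nrow(types)), types$label)
  for (lab in types$label) history[[lab]] <- numeric(0)
  for (i in seq_len(n)) {
    lab <- tr$condition[i]
    targets[i] <- adaptive_target_duration(history[[lab]], params = staircase)
    rts[i] <- stats::rlnorm(1, log(median_ms), sdlog)
    hit[i] <- rts[i] <= targets[i]
    history[[lab]] <- c(history[[lab]], rts[i])
  }
  mag <- types$magnitude[match(tr$condition, types$label)]
  val <- types$valence[match(tr$condition, types$label)]
  outcome <- ifelse(val == "gain", ifelse(hit, mag, 0),
                    ifelse(hit, 0, -mag))
  data.frame(
    trial = tr$trial, condition = tr$condition, magnitude = mag,
    valence = val, rt_ms = rts, target_ms = targets, hit = hit,
    outcome = outcome, stringsAsFactors = FALSE
  )
}

#' Run a single-stream adaptive-timing session
#'
#' Plays one responder through `n_trials` target-detection trials for a
#' single cue stream: each trial's target duration comes from
#' [adaptive_target_duration()] applied to the trial history, the RT is drawn
#' from the lognormal model, and a hit is recorded when the RT does not
#' exceed the target. Used to measure the long-run hit rate the staircase
#' achieves.
#'
#' @param n_trials number of trials.
#' @param rt_model list: `median_ms` (default 300), `sdlog` (default 0.2).
#' @param staircase settings for [adaptive_target_duration()]; `seed_rt_ms`
#'   defaults to the responder's practice mean RT (the mean of 50 practice
#'   draws).
#' @param seed optional integer seed.
#' @return data.frame: trial, rt_ms, target_ms, hit.
#' @export
simulate_staircase_run <- function(n_trials = 500, rt_model = list(),
                                   staircase = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  median_ms <- rt_model$median_ms %||% 300
  sdlog <- rt_model$sdlog %||% 0.2
  stopifnot(median_ms > 0, n_trials >= 0)
  if (is.null(staircase$seed_rt_ms)) {
    staircase$seed_rt_ms <- mean(stats::rlnorm(50, log(median_ms), sdlog))
  }
  rts <- numeric(n_trials); targets <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    targets[i] <- adaptive_target_duration(rts[seq_len(i - 1L)],
                                           params = staircase)
    rts[i] <- stats::rlnorm(1, log(median_ms), sdlog)
  }
  data.frame(trial = seq_len(n_trials), rt_ms = rts, target_ms = targets,
             hit = rts <= targets)
}
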