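#' Cue specification
#'
#' A cue is a stochastic payoff source: it pays `win_amount` dollars with
#' probability `win_prob` and `lose_amount` otherwise. Neutral cues must pay
#' nothing either way.
#'
#' @param cue_id character token identifying the cue.
#' @param win_prob probability in `[0, 1]` of the winning outcome.
#' @param win_amount dollars paid on a win.
#' @param lose_amount dollars paid otherwise (negative for losses).
#' @param valence one of `"gain"`, `"loss"`, `"neutral"`.
#' @return an object of class `cue_spec`.
#' @export
cue_spec <- function(cue_id, win_prob, win_amount, lose_amount = 0,
                     valence = c("gain", "loss", "neutral")) {
  valence <- match.arg(valence)
  stopifnot(is.character(cue_id), length(cue_id) == 1L)
  if (!is.numeric(win_prob) || length(win_prob) != 1L ||
      win_prob < 0 || win_prob > 1) {
    stop("win_prob must be a single probability in [0, 1]")
  }
  if (valence == "neutral" && (win_amount != 0 || lose_amount != 0)) {
    stop("neutral cues must have win_amount = lose_amount = 0")
  }
  structure(
    list(cue_id = cue_id, win_prob = win_prob, win_amount = win_amount,
         lose_amount = lose_amount, valence = valence),
    class = "cue_spec"
  )
}

#' @export
print.cue_spec <- function(x, ...) {
  cat(sprintf("<cue %s [%s]: $%.2f at %.0f%%, else $%.2f>\n",
              x$cue_id, x$valence, x$win_amount, 100 * x$win_prob,
              x$lose_amount))
  invisible(x)
}

#' Default MIL cue set
#'
#' Three cue pairs. In the gain pair the better cue pays +$1 with probability
#' 2/3 ($0 otherwise) and the worse cue with probability 1/3. The loss pair
#' mirrors it with outcomes {-$1, $0}: the better cue avoids the -$1 loss with
#' probability 2/3. Neutral cues always pay $0.
#'
#' @param p_better win probability of the better cue (default 2/3).
#' @return named list of `cue_spec` objects.
#' @export
mil_cues <- function(p_better = 2 / 3) {
  list(
    gain_better = cue_spec("gain_better", p_better, 1, 0, "gain"),
    gain_worse  = cue_spec("gain_worse", 1 - p_better, 1, 0, "gain"),
    loss_better = cue_spec("loss_better", p_better, 0, -1, "loss"),
    loss_worse  = cue_spec("loss_worse", 1 - p_better, 0, -1, "loss"),
    neutral_a   = cue_spec("neutral_a", 1, 0, 0, "neutral"),
    neutral_b   = cue_spec("neutral_b", 1, 0, 0, "neutral")
  )
}

#' Expanded four-cue set for one block
#'
#' @param win_probs win probabilities of the four cues; defaults 0.40, 0.50,
#'   0.60, 0.70 so adjacent expected values are 10 cents apart.
#' @param block_id integer used to suffix cue ids (each block uses fresh cues).
#' @return named list of `cue_spec` objects.
#' @export
expanded_cues <- function(win_probs = c(0.40, 0.50, 0.60, 0.70), block_id = 1L) {
  stats::setNames(
    lapply(seq_along(win_probs), function(i) {
      id <- sprintf("b%d_cue%d", block_id, i)
      cue_spec(id, win_probs[i], 1, 0, "gain")
    }),
    sprintf("b%d_cue%d", block_id, seq_along(win_probs))
  )
}

#' The six MID cue types
#'
#' @return data.frame with columns `label`, `magnitude`, `valence`.
#' @export
mid_cue_types <- function() {
  data.frame(
    label = c("win0", "win050", "win500", "lose0", "lose050", "lose500"),
    magnitude = c(0, 0.5, 5, 0, 0.5, 5),
    valence = rep(c("gain", "loss"), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Build a randomized trial schedule
#'
#' Generates the ordered trial stream for one subject on one task:
#'
#' * `"mil"`: three interleaved cue-pair conditions (gain, loss, neutral),
#'   24 repetitions each by default, 10-s trials, ITIs drawn uniformly from
#'   \{2, 4, 6\} s, and the better cue of each pair shown equally often on the
#'   left and right.
#' * `"mid"`: six cue types, 15 repetitions each, 8-s trials, the same ITI
#'   distribution.
#' * `"expanded"`: a four-cue gain-only choice task run as four blocks in the
#'   fixed order short-long-short-long (default lengths 25 and 75), each block
#'   with a fresh cue set; self-paced, so ITI 0.
#'
#' @param task_kind `"mil"`, `"mid"` or `"expanded"`.
#' @param config list of design overrides. Recognized entries:
#'   `n_per_condition` (mil), `n_per_type` (mid), `block_lengths` (expanded,
#'   default `c(25, 75, 25, 75)`), `trial_duration_s`, `itis`,
#'   `win_probs` (expanded cue probabilities), `p_better` (mil).
#' @param seed integer seed for the schedule-level RNG; schedules are
#'   reproducible given the seed and independent of outcome draws.
#' @return an object of class `trial_schedule`: a list with `task_kind`,
#'   `trials` (data.frame: trial, block, condition, cue_ids, side, onset_s,
#'   duration_s, iti_s), `cues` (named list of `cue_spec`), `block_structure`.
#' @export
build_schedule <- function(task_kind = c("mil", "mid", "expanded"),
                           config = list(), seed = NULL) {
  task_kind <- match.arg(task_kind)
  if (!is.null(seed)) set.seed(seed)
  switch(task_kind,
    mil = build_schedule_mil(config),
    mid = build_schedule_mid(config),
    expanded = build_schedule_expanded(config)
  )
}

default_itis <- c(2, 4, 6)

build_schedule_mil <- function(config) {
  n_rep <- config$n_per_condition %||% 24L
  stopifnot(n_rep >= 0)
  dur <- config$trial_duration_s %||% 10
  itis <- config$itis %||% default_itis
  cues <- mil_cues(config$p_better %||% (2 / 3))
  conds <- c("gain", "loss", "neutral")
  if (n_rep > 0 && n_rep %% 2L != 0L) {
    stop("per-condition count must be even so left/right sides can be ",
         "counterbalanced within each cue pair (got ", n_rep, ")")
  }
  condition <- rep(conds, each = n_rep)
  # equal left/right placement of the first (better) cue within each pair
  side <- unlist(lapply(conds, function(cc) {
    sample(rep(c("left", "right"), length.out = n_rep))
  }), use.names = FALSE)
  ord <- sample.int(length(condition))
  condition <- condition[ord]
  side <- side[ord]
  n <- length(condition)
  pair_ids <- c(
    gain = "gain_better;gain_worse",
    loss = "loss_better;loss_worse",
    neutral = "neutral_a;neutral_b"
  )
  iti <- if (n > 0) sample(itis, n, replace = TRUE) else numeric(0)
  onset <- if (n > 0) cumsum(c(0, (dur + iti)[-n])) else numeric(0)
  trials <- data.frame(
    trial = seq_len(n), block = rep(1L, n), condition = condition,
    cue_ids = unname(pair_ids[condition]), side = side,
    onset_s = onset, duration_s = rep(dur, n), iti_s = iti,
    stringsAsFactors = FALSE
  )
  new_trial_schedule("MIL", trials, cues,
                     block_structure = data.frame(block_id = 1L, length = n))
}

build_schedule_mid <- function(config) {
  n_rep <- config$n_per_type %||% 15L
  stopifnot(n_rep >= 0)
  dur <- config$trial_duration_s %||% 8
  itis <- config$itis %||% default_itis
  types <- mid_cue_types()
  condition <- rep(types$label, each = n_rep)
  condition <- sample(condition)
  n <- length(condition)
  iti <- if (n > 0) sample(itis, n, replace = TRUE) else numeric(0)
  onset <- if (n > 0) cumsum(c(0, (dur + iti)[-n])) else numeric(0)
  trials <- data.frame(
    trial = seq_len(n), block = rep(1L, n), condition = condition,
    cue_ids = condition, side = rep(NA_character_, n),
    onset_s = onset, duration_s = rep(dur, n), iti_s = iti,
    stringsAsFactors = FALSE
  )
  sched <- new_trial_schedule("MID", trials, cues = list(),
                              block_structure = data.frame(block_id = 1L,
                                                           length = n))
  sched$cue_types <- types
  sched
}

build_schedule_expanded <- function(config) {
  lens <- config$block_lengths %||% c(25L, 75L, 25L, 75L)
  stopifnot(all(lens >= 0))
  dur <- config$trial_duration_s %||% 3
  win_probs <- config$win_probs %||% c(0.40, 0.50, 0.60, 0.70)
  cues <- list()
  rows <- vector("list", length(lens))
  trial0 <- 0L
  onset0 <- 0
  for (b in seq_along(lens)) {
    bc <- expanded_cues(win_probs, block_id = b)
    cues <- c(cues, bc)
    nb <- lens[b]
    ids <- paste(names(bc), collapse = ";")
    onset <- onset0 + (seq_len(nb) - 1L) * dur
    rows[[b]] <- data.frame(
      trial = trial0 + seq_len(nb), block = rep(b, nb),
      condition = rep("gain", nb),
      cue_ids = rep(ids, nb), side = rep(NA_character_, nb),
      onset_s = onset, duration_s = rep(dur, nb), iti_s = rep(0, nb),
      stringsAsFactors = FALSE
    )
    trial0 <- trial0 + nb
    onset0 <- onset0 + nb * dur
  }
  trials <- do.call(rbind, rows)
  if (is.null(trials)) trials <- data.frame()
  new_trial_schedule(
    "EXPANDED", trials, cues,
    block_structure = data.frame(block_id = seq_along(lens), length = lens)
  )
}

new_trial_schedule <- function(task_kind, trials, cues, block_structure) {
  if (nrow(trials) > 1 && any(diff(trials$onset_s) <= 0)) {
    stop("trial onsets must be strictly increasing")
  }
  structure(
    list(task_kind = task_kind, trials = trials, cues = cues,
         block_structure = block_structure),
    class = "trial_schedule"
  )
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<%s schedule: %d trials, %d block(s), run length %.0f s>\n",
              x$task_kind, nrow(x$trials), nrow(x$block_structure),
              schedule_run_length(x)))
  invisible(x)
}

#' Total run length of a schedule in seconds
#' @param schedule a `trial_schedule`.
#' @export
schedule_run_length <- function(schedule) {
  tr <- schedule$trials
  if (nrow(tr) == 0) return(0)
  n <- nrow(tr)
  tr$onset_s[n] + tr$duration_s[n] + tr$iti_s[n]
}

#' Draw outcomes from a cue
#'
#' Returns `win_amount` with probability `win_prob`, else `lose_amount`,
#' using the current RNG state (seed it with [set.seed()] for reproducible
#' outcome streams, independently of schedule generation).
#'
#' @param cue a `cue_spec`.
#' @param n number of draws.
#' @return numeric vector of outcomes in dollars.
#' @export
sample_outcome <- function(cue, n = 1L) {
  stopifnot(inherits(cue, "cue_spec"), n >= 0)
  ifelse(stats::runif(n) < cue$win_prob, cue$win_amount, cue$lose_amount)
}

#' Next target duration for the MID adaptive timing algorithm
#'
#' Tracks the responder's reaction-time distribution to hold the hit rate
#' near the task's 66% target. With no history the seeded practice duration
#' is returned (seed mean RT plus the fixed percentile offset
#' `z * seed_sd_ms`); afterwards the duration is the running estimate of the
#' responder's 66th RT percentile, `mean + z * sd` over the last
#' `window` reaction times with `z = qnorm(target)`.
#'
#' @param rt_history numeric vector of previous reaction times (ms); may be
#'   empty.
#' @param hit_history logical vector of previous hits (unused by this rule;
#'   accepted so alternative closed-loop rules share the signature).
#' @param params list of staircase settings: `seed_rt_ms` (required, mean
#'   practice RT), `target` (default 0.66), `window` (default 20),
#'   `seed_sd_ms` (default 50), `floor_ms` (default 50).
#' @return next target duration in ms (never below `floor_ms`).
#' @export
adaptive_target_duration <- function(rt_history = numeric(0),
                                     hit_history = logical(0),
                                     params = list()) {
  seed_rt <- params$seed_rt_ms
  if (is.null(seed_rt) || !is.finite(seed_rt) || seed_rt <= 0) {
    stop("params$seed_rt_ms must be a positive practice mean RT")
  }
  target <- params$target %||% 0.66
  window <- params$window %||% 20L
  seed_sd <- params$seed_sd_ms %||% 50
  floor_ms <- params$floor_ms %||% 50
  z <- stats::qnorm(target)
  h <- utils::tail(rt_history, window)
  dur <- if (length(h) < 2L) {
    seed_rt + z * seed_sd
  } else {
    mean(h) + z * stats::sd(h)
  }
  max(dur, floor_ms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
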