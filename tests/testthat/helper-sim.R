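# Hand-built choice logs for likelihood oracles and counting checks.
make_choice_log <- function(condition, cue_ids, chosen, outcome, cues,
                            task_kind = "MIL", block = 1L) {
  log <- data.frame(
    trial = seq_along(condition), block = block, condition = condition,
    cue_ids = cue_ids, chosen = chosen, outcome = outcome,
    value_chosen = NA_real_, stringsAsFactors = FALSE
  )
  attr(log, "cues") <- cues
  attr(log, "task_kind") <- task_kind
  class(log) <- c("choice_log", "data.frame")
  log
}

two_cue_table <- data.frame(
  cue_id = c("A", "B"), win_prob = c(2 / 3, 1 / 3),
  valence = "gain", stringsAsFactors = FALSE
)

# Slow, transparent R reference for the RW/softmax likelihood: propagates
# values trial by trial with plain arithmetic, independent of the package's
# compiled recursion.
reference_nll <- function(alpha, beta, log) {
  keep <- log$condition != "neutral"
  log <- log[keep, , drop = FALSE]
  v <- list()
  nll <- 0
  for (i in seq_len(nrow(log))) {
    cues_i <- strsplit(log$cue_ids[i], ";")[[1]]
    for (cue in cues_i) if (is.null(v[[cue]])) v[[cue]] <- 0
    vals <- vapply(cues_i, function(cue) v[[cue]], 0)
    p <- exp(beta * vals) / sum(exp(beta * vals))
    nll <- nll - log2(p[[log$chosen[i]]]) * log(2)  # plain -ln p
    ch <- log$chosen[i]
    v[[ch]] <- v[[ch]] + alpha * (log$outcome[i] - v[[ch]])
  }
  nll
}

# 99% equal-tailed binomial interval for an observed count.
binom_ci_contains <- function(successes, n, p, level = 0.99) {
  a <- (1 - level) / 2
  lo <- stats::qbinom(a, n, p)
  hi <- stats::qbinom(1 - a, n, p)
  successes >= lo && successes <= hi
}
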