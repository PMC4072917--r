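#' Second-level age regression on subject statistics
#'
#' OLS of a per-subject value (first-level coefficient, contrast or
#' behavioral score) on mean-centered age and, optionally, mean-centered
#' squared age, so the intercept estimates the sample mean effect
#' controlling for age. Also reports the standardized linear coefficient
#' `beta = slope * sd(age) / sd(value)`.
#'
#' @param stats data.frame with columns `age` and `value` (and optionally
#'   `subject_id`).
#' @param include_quadratic include the quadratic age term (default TRUE).
#' @return an object of class `age_regression`: `intercept` (estimate, t, p),
#'   `linear` and (optionally) `quadratic` rows, `std_beta`, `n`.
#' @export
age_effect_regression <- function(stats, include_quadratic = TRUE) {
  stopifnot(all(c("age", "value") %in% names(stats)))
  stats <- stats[is.finite(stats$age) & is.finite(stats$value), ,
                 drop = FALSE]
  n <- nrow(stats)
  if (n < (if (include_quadratic) 4L else 3L)) stop("too few subjects")
  if (stats::sd(stats$age) == 0) stop("zero variance in age")
  if (stats::sd(stats$value) == 0) stop("zero variance in value")
  ac <- stats$age - mean(stats$age)
  if (include_quadratic) {
    ac2 <- ac^2 - mean(ac^2)
    fit <- stats::lm(value ~ ac + ac2, data = data.frame(stats, ac = ac,
                                                         ac2 = ac2))
  } else {
    fit <- stats::lm(value ~ ac, data = data.frame(stats, ac = ac))
  }
  sm <- summary(fit)$coefficients
  std_beta <- sm["ac", "Estimate"] * stats::sd(stats$age) /
    stats::sd(stats$value)
  structure(
    list(intercept = sm["(Intercept)", ],
         linear = sm["ac", ],
         quadratic = if (include_quadratic) sm["ac2", ] else NULL,
         std_beta = unname(std_beta), n = n, fit = fit),
    class = "age_regression"
  )
}

#' @export
print.age_regression <- function(x, digits = 3, ...) {
  cat(sprintf("Age regression (n = %d): standardized linear beta = %.2f\n",
              x$n, x$std_beta))
  tab <- rbind(intercept = x$intercept, linear = x$linear)
  if (!is.null(x$quadratic)) tab <- rbind(tab, quadratic = x$quadratic)
  print(round(tab, digits))
  invisible(x)
}

#' Learning-performance metrics from a choice log
#'
#' MIL: the fraction of learning (gain and loss) trials on which the choice
#' matched the better cue of its pair, i.e. the cue with the higher
#' probability of the advantageous outcome; neutral trials are excluded.
#' Expanded task: the fraction of choices allocated to either of the two
#' highest-probability cues of the block's cue set, reported per block
#' (round) and overall.
#'
#' @param log a `choice_log` (carries its cue table as an attribute).
#' @param task_kind `"MIL"` or `"EXPANDED"`; default taken from the log.
#' @return for MIL a single proportion; for EXPANDED a list with `overall`
#'   and `per_block` (data.frame block, n, proportion).
#' @export
performance_metrics <- function(log, task_kind = NULL) {
  task_kind <- task_kind %||% attr(log, "task_kind")
  cues <- attr(log, "cues")
  if (is.null(cues)) stop("choice log carries no cue table")
  wp <- stats::setNames(cues$win_prob, cues$cue_id)
  avail <- split_cue_ids(log$cue_ids)
  if (identical(task_kind, "MIL")) {
    keep <- log$condition != "neutral"
    if (!any(keep)) stop("no scoreable learning trials")
    best <- vapply(avail[keep], function(a) a[which.max(wp[a])], "")
    return(mean(log$chosen[keep] == best))
  }
  if (identical(task_kind, "EXPANDED")) {
    if (nrow(log) == 0L) stop("no scoreable trials")
    top2 <- vapply(seq_len(nrow(log)), function(i) {
      a <- avail[[i]]
      log$chosen[i] %in% a[order(wp[a], decreasing = TRUE)[1:2]]
    }, logical(1))
    per_block <- do.call(rbind, lapply(unique(log$block), function(b) {
      sel <- log$block == b
      data.frame(block = b, n = sum(sel), proportion = mean(top2[sel]))
    }))
    return(list(overall = mean(top2), per_block = per_block))
  }
  stop("unsupported task_kind: ", task_kind)
}

#' Win-stay/lose-shift adherence and the exclusion rule
#'
#' Scores, from the second trial of each condition stream (same block and
#' cue set) onward, whether the choice matches the WSLS prescription given
#' the previous trial: repeat the previous cue after a win, choose any other
#' cue after a non-win. Wins follow the valence rule used by the WSLS agent
#' (gain: outcome > 0; loss: outcome == 0). Subjects adhering on every
#' single scoreable trial are flagged for exclusion.
#'
#' @param log a `choice_log`.
#' @return list with `proportion` (adherence in `[0, 1]`), `n_scored`, and
#'   `exclude` (`TRUE` when proportion == 1).
#' @export
wsls_adherence <- function(log) {
  if (nrow(log) < 2L) stop("need at least 2 trials")
  cues <- attr(log, "cues")
  val <- stats::setNames(cues$valence, cues$cue_id)
  key <- paste(log$block, log$condition, sep = ":")
  adherent <- logical(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    prev <- idx[-length(idx)]
    cur <- idx[-1]
    win_prev <- wsls_win(log$outcome[prev], val[log$chosen[prev]])
    stay <- log$chosen[cur] == log$chosen[prev]
    adherent <- c(adherent, ifelse(win_prev, stay, !stay))
  }
  if (length(adherent) == 0L) stop("no scoreable trial pairs")
  p <- mean(adherent)
  list(proportion = p, n_scored = length(adherent), exclude = p == 1)
}

#' Mixed-design 2 x 2 ANOVA (group x block length)
#'
#' Standard mixed-design sums of squares with one between-subjects factor
#' (two groups) and one within-subjects factor (two block lengths), one
#' score per subject per length. All three F tests carry df = (1, n - 2).
#'
#' @param scores data.frame with columns `subject`, `group` (2 levels),
#'   `length` (2 levels) and `score`; every subject complete.
#' @return list of data.frames `length`, `group`, `interaction`, each with
#'   `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova_2x2 <- function(scores) {
  stopifnot(all(c("subject", "group", "length", "score") %in% names(scores)))
  scores$subject <- factor(scores$subject)
  scores$group <- factor(scores$group)
  scores$length <- factor(scores$length)
  if (nlevels(scores$group) != 2L || nlevels(scores$length) != 2L) {
    stop("need exactly two groups and two block lengths")
  }
  tab <- table(scores$subject, scores$length)
  if (any(tab != 1L)) stop("each subject needs exactly one score per length")
  fit <- stats::aov(score ~ group * length + Error(subject),
                    data = scores)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  # an effect whose sum of squares is zero (to rounding) is a null effect:
  # report F = 0 rather than the 0/0 ratio of degenerate strata
  ss_total <- sum((scores$score - mean(scores$score))^2)
  ss_floor <- max(ss_total, .Machine$double.eps) * 1e-10
  pick <- function(stratum, term) {
    i <- match(term, trimws(rownames(stratum)))
    f <- stratum[i, "F value"]
    p <- stratum[i, "Pr(>F)"]
    if (is.na(f) || stratum[i, "Sum Sq"] <= ss_floor) {
      f <- 0
      p <- 1
    }
    data.frame(F = f, df1 = stratum[i, "Df"],
               df2 = stratum[nrow(stratum), "Df"], p = p)
  }
  list(group = pick(between, "group"),
       length = pick(within, "length"),
       interaction = pick(within, "group:length"))
}

#' Follow-up t tests for the 2 x 2 learning-performance table
#'
#' Paired t tests of long vs short within each group (df = n_group - 1) and
#' pooled-variance independent t tests between groups within each block
#' length (df = n1 + n2 - 2, matching the conventional reporting of such
#' designs).
#'
#' @param scores as in [mixed_anova_2x2()].
#' @return data.frame with columns `comparison`, `t`, `df`, `p`,
#'   `estimate` (mean difference).
#' @export
group_comparison_tests <- function(scores) {
  scores$group <- factor(scores$group)
  scores$length <- factor(scores$length)
  glev <- levels(scores$group)
  llev <- levels(scores$length)
  if (any(table(scores$group) < 2L)) stop("singleton group")
  rows <- list()
  wide <- stats::reshape(
    scores[, c("subject", "group", "length", "score")],
    idvar = c("subject", "group"), timevar = "length", direction = "wide"
  )
  names(wide) <- sub("^score\\.", "", names(wide))
  for (g in glev) {
    w <- wide[wide$group == g, ]
    # within_sample_t rather than t.test(paired = TRUE): identical scores in
    # the two lengths are a legitimate degenerate case and must give t = 0
    wt <- within_sample_t(w[[llev[2]]] - w[[llev[1]]])
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = sprintf("%s vs %s within %s", llev[2], llev[1], g),
      t = wt$t, df = wt$df, p = wt$p, estimate = wt$mean)
  }
  for (l in llev) {
    s <- scores[scores$length == l, ]
    tt <- stats::t.test(score ~ group, data = s, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = sprintf("%s vs %s within %s block", glev[1], glev[2], l),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, estimate = unname(diff(rev(tt$estimate))))
  }
  do.call(rbind, rows)
}
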