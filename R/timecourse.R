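#' Extract trial-locked peristimulus segments
#'
#' Cuts the PSC series into TR-gridded windows starting at the volume
#' containing each trial onset. Trials whose window would run past the end of
#' the series are dropped with a warning.
#'
#' @param series a `roi_timeseries` or numeric vector.
#' @param onsets trial onsets in seconds.
#' @param window_s window length in seconds (default 16, i.e. 8 timepoints at
#'   TR 2).
#' @param tr repetition time (taken from the series when available).
#' @return a trials x timepoints matrix of class `peristimulus_matrix` with
#'   attributes `offsets_s` (timepoint offsets from trial onset) and
#'   `kept` (indices of retained onsets).
#' @export
extract_peristimulus <- function(series, onsets, window_s = 16, tr = NULL) {
  if (inherits(series, "roi_timeseries")) {
    tr <- tr %||% series$tr_s
    y <- series$values
  } else {
    tr <- tr %||% 2
    y <- series
  }
  if (length(onsets) == 0L) stop("empty onset list")
  n_t <- round(window_s / tr)
  start <- floor(onsets / tr) + 1L
  ok <- start + n_t - 1L <= length(y) & start >= 1L
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) dropped: window extends past the series")
  }
  start <- start[ok]
  mat <- t(vapply(start, function(s) y[s:(s + n_t - 1L)], numeric(n_t)))
  structure(mat,
            offsets_s = (seq_len(n_t) - 1L) * tr,
            kept = which(ok),
            class = c("peristimulus_matrix", "matrix", "array"))
}

#' Condition-average time courses and feedback-window contrast
#'
#' Averages peristimulus segments by condition label (mean and SEM per
#' timepoint) and computes the scalar feedback-window contrast: the mean over
#' the hemodynamic-lag-adjusted window of (first condition - second
#' condition). With feedback presented 6 s into the trial and an HRF peaking
#' near 4.7 s, the default window is 10-14 s after trial onset (feedback + 4
#' to + 8 s).
#'
#' @param mat a `peristimulus_matrix`.
#' @param labels per-trial condition labels (length = rows of `mat`; rows
#'   dropped by extraction must already be removed).
#' @param contrast character vector of the two labels to difference
#'   (default: the first two label levels in sorted order).
#' @param feedback_window_s two-vector, window bounds in seconds from trial
#'   onset (inclusive; default `c(10, 14)`).
#' @return list with `curves` (data.frame: condition, time_s, mean, sem, n),
#'   `difference` (scalar feedback-window contrast), `contrast`, `window_s`.
#' @export
condition_contrast_curves <- function(mat, labels, contrast = NULL,
                                      feedback_window_s = c(10, 14)) {
  stopifnot(inherits(mat, "peristimulus_matrix"))
  if (length(labels) != nrow(mat)) {
    stop("labels must have one entry per retained trial")
  }
  offs <- attr(mat, "offsets_s")
  levs <- sort(unique(as.character(labels)))
  counts <- table(factor(labels, levels = levs))
  if (any(counts == 0) || length(levs) < 2L) {
    stop("condition(s) with zero trials: the contrast needs two populated ",
         "conditions (got ", paste(levs[counts > 0], collapse = ", "), ")")
  }
  curves <- do.call(rbind, lapply(levs, function(lv) {
    rows <- mat[labels == lv, , drop = FALSE]
    data.frame(condition = lv, time_s = offs,
               mean = colMeans(rows),
               sem = apply(rows, 2, stats::sd) / sqrt(nrow(rows)),
               n = nrow(rows), stringsAsFactors = FALSE)
  }))
  if (is.null(contrast)) contrast <- levs[1:2]
  if (!all(contrast %in% levs)) stop("contrast labels not found")
  win <- offs >= feedback_window_s[1] & offs <= feedback_window_s[2]
  if (!any(win)) stop("feedback window contains no timepoints")
  mean_in_win <- function(lv) {
    mean(colMeans(mat[labels == lv, win, drop = FALSE]))
  }
  diff <- mean_in_win(contrast[1]) - mean_in_win(contrast[2])
  list(curves = curves, difference = diff, contrast = contrast,
       window_s = feedback_window_s)
}

#' One-sample t test of per-subject contrast scalars against zero
#'
#' @param differences numeric vector, one feedback-window difference per
#'   subject.
#' @return list with `t`, `df` (n - 1), `p`, `mean`, `n`. A zero-variance
#'   sample with nonzero mean is reported as an infinite t (p = 0) rather
#'   than an error.
#' @export
within_sample_t <- function(differences) {
  differences <- differences[is.finite(differences)]
  n <- length(differences)
  if (n < 2L) stop("need at least 2 subjects")
  m <- mean(differences)
  s <- stats::sd(differences)
  df <- n - 1L
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean = m, n = n)
}

#' Bin ages into the study's plotting groups
#'
#' @param age numeric ages in years.
#' @param breaks upper bounds of the young and middle bins (defaults: young
#'   up to 44, middle 45-60, older 61+).
#' @return factor with levels young, middle, older.
#' @export
age_group <- function(age, breaks = c(young_max = 44, middle_max = 60)) {
  cut(age, c(-Inf, breaks[1], breaks[2], Inf),
      labels = c("young", "middle", "older"))
}
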