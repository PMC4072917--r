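#' Build a first-level design matrix
#'
#' Three model variants, each completed with baseline, linear and quadratic
#' trend columns (volume index normalized to `[-1, 1]`) and optional motion
#' nuisance columns:
#'
#' * `"mil-parametric"`: one event column per condition at feedback onsets
#'   plus two parametric regressors of interest, the signed prediction error
#'   on gain trials and on loss trials (each mean-centered within valence).
#' * `"mil-binary"`: the model-free variant that directly contrasts gains
#'   (positive prediction error) with nongains (negative prediction error):
#'   +1/-1 contrast columns per valence, centered within valence.
#' * `"mid"`: task-period nuisance columns (all anticipations, all outcomes)
#'   plus four contrast regressors of interest: gain vs nongain anticipation,
#'   loss vs nonloss anticipation, gain (hit at $0.50/$5.00) vs nongain
#'   (miss) outcome, and nonloss (hit) vs loss (miss) outcome.
#'
#' @param schedule a `trial_schedule` matching the mode.
#' @param modulation for the MIL modes, the per-trial signed PE aligned with
#'   the schedule (NA on neutral trials); for `"mid"`, the data.frame from
#'   [simulate_mid_performance()].
#' @param mode `"mil-parametric"`, `"mil-binary"` or `"mid"`.
#' @param n_volumes number of volumes (default: covers the run).
#' @param tr repetition time, seconds.
#' @param feedback_offset_s feedback onset within each trial (default 6 s).
#' @param kernel HRF kernel on the TR grid.
#' @param motion optional matrix of motion nuisance columns.
#' @return an object of class `design_matrix`: list with `X` (volumes x
#'   columns), `labels`, `interest` (labels of the regressors of interest),
#'   `df_residual`.
#' @export
build_design_matrix <- function(schedule, modulation = NULL,
                                mode = c("mil-parametric", "mil-binary",
                                         "mid"),
                                n_volumes = NULL, tr = 2,
                                feedback_offset_s = 6,
                                kernel = hrf_kernel(tr), motion = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "trial_schedule"))
  trs <- schedule$trials
  if (nrow(trs) == 0L) stop("schedule has no trials")
  run_s <- schedule_run_length(schedule)
  if (is.null(n_volumes)) n_volumes <- ceiling(run_s / tr)
  fb <- trs$onset_s + feedback_offset_s
  cols <- list()
  interest <- character(0)
  if (mode %in% c("mil-parametric", "mil-binary")) {
    for (cc in unique(trs$condition)) {
      sel <- trs$condition == cc
      cols[[paste0("ev_", cc)]] <-
        build_event_regressor(fb[sel], 1, n_volumes, tr, kernel)
    }
    for (vv in intersect(c("gain", "loss"), unique(trs$condition))) {
      sel <- trs$condition == vv
      m <- modulation[sel]
      if (is.null(m) || all(is.na(m))) {
        stop("modulation (signed PE) required on ", vv, " trials")
      }
      m[is.na(m)] <- 0
      if (mode == "mil-binary") m <- sign(m)
      m <- m - mean(m)
      lab <- paste0(if (mode == "mil-binary") "bin_" else "pe_", vv)
      cols[[lab]] <- build_event_regressor(fb[sel], m, n_volumes, tr, kernel)
      interest <- c(interest, lab)
    }
  } else {
    perf <- modulation
    if (is.null(perf) || !all(c("hit", "magnitude", "valence") %in%
                              names(perf))) {
      stop("mid mode needs the performance data.frame (hit, magnitude, ",
           "valence)")
    }
    ant <- trs$onset_s
    cols[["ev_anticip"]] <- build_event_regressor(ant, 1, n_volumes, tr,
                                                  kernel)
    cols[["ev_outcome"]] <- build_event_regressor(fb, 1, n_volumes, tr,
                                                  kernel)
    code_centered <- function(sel, code) {
      x <- numeric(nrow(trs))
      x[sel] <- code[sel] - mean(code[sel])
      x
    }
    gain <- perf$valence == "gain"
    loss <- perf$valence == "loss"
    stake <- perf$magnitude > 0
    # anticipation: at-stake cue vs $0.00 cue, per valence
    ant_gain <- code_centered(gain, ifelse(stake, 1, -1))
    ant_loss <- code_centered(loss, ifelse(stake, 1, -1))
    # outcome: hit vs miss among at-stake trials, per valence
    out_gain <- code_centered(gain & stake, ifelse(perf$hit, 1, -1))
    out_loss <- code_centered(loss & stake, ifelse(perf$hit, 1, -1))
    cols[["ant_gain"]] <- build_event_regressor(ant, ant_gain, n_volumes,
                                                tr, kernel)
    cols[["ant_loss"]] <- build_event_regressor(ant, ant_loss, n_volumes,
                                                tr, kernel)
    cols[["out_gain"]] <- build_event_regressor(fb, out_gain, n_volumes,
                                                tr, kernel)
    cols[["out_loss"]] <- build_event_regressor(fb, out_loss, n_volumes,
                                                tr, kernel)
    interest <- c("ant_gain", "ant_loss", "out_gain", "out_loss")
  }
  u <- norm_volume_index(n_volumes)
  cols[["baseline"]] <- rep(1, n_volumes)
  cols[["linear"]] <- u
  cols[["quadratic"]] <- u^2
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_volumes)
    mn <- colnames(motion) %||% paste0("motion", seq_len(ncol(motion)))
    for (j in seq_len(ncol(motion))) cols[[mn[j]]] <- motion[, j]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qr_x$pivot[seq_len(qr_x$rank)]])
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(X = X, labels = colnames(X), interest = interest,
         df_residual = n_volumes - ncol(X), tr = tr),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design matrix: %d volumes x %d columns, %d of interest (%s), df %d>\n",
              nrow(x$X), ncol(x$X), length(x$interest),
              paste(x$interest, collapse = ", "), x$df_residual))
  invisible(x)
}

#' Fit the first-level ordinary-least-squares GLM
#'
#' OLS of a ROI time series on a design matrix, with homoskedastic standard
#' errors (any AR(1) structure in the noise is accepted as model mismatch,
#' as in the era's single-subject practice). t statistics are converted to
#' z scores through the t CDF.
#'
#' @param series a `roi_timeseries` or numeric vector.
#' @param design a `design_matrix`.
#' @param contrasts optional named list of contrast weight vectors (length =
#'   number of columns, or named by a single column label).
#' @return an object of class `roi_glm`: coefficient table (estimate, se, t,
#'   z), `sigma2`, `df_residual`, `contrasts` table, `residuals`, `fitted`.
#' @export
fit_glm <- function(series, design, contrasts = NULL) {
  y <- if (inherits(series, "roi_timeseries")) series$values else series
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (length(y) != nrow(X)) {
    stop("series length (", length(y), ") != design rows (", nrow(X), ")")
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("singular design matrix")
  b <- qr.coef(qr_x, y)
  fitted <- drop(X %*% b)
  res <- y - fitted
  df <- design$df_residual
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- b / se
  ctab <- NULL
  if (!is.null(contrasts)) {
    rows <- lapply(names(contrasts), function(nm) {
      w <- contrasts[[nm]]
      if (is.character(w)) {
        lab <- w
        w <- as.numeric(design$labels == lab)
      }
      stopifnot(length(w) == ncol(X))
      est <- sum(w * b)
      se_c <- sqrt(drop(t(w) %*% xtx_inv %*% w) * sigma2)
      tc <- est / se_c
      data.frame(contrast = nm, estimate = est, se = se_c, t = tc,
                 z = t_to_z(tc, df), p = 2 * stats::pt(-abs(tc), df),
                 stringsAsFactors = FALSE)
    })
    ctab <- do.call(rbind, rows)
  }
  structure(
    list(coefficients = data.frame(label = design$labels, estimate = b,
                                   se = se, t = tval, z = t_to_z(tval, df),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
         interest = design$interest, sigma2 = sigma2, df_residual = df,
         contrasts = ctab, residuals = res, fitted = fitted),
    class = "roi_glm"
  )
}

#' @export
print.roi_glm <- function(x, digits = 3, ...) {
  cat(sprintf("First-level OLS GLM (df = %d, sigma %.3f)\n", x$df_residual,
              sqrt(x$sigma2)))
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], digits)
  print(tab)
  if (!is.null(x$contrasts)) {
    cat("Contrasts:\n")
    ct <- x$contrasts
    ct[, -1] <- round(ct[, -1], digits)
    print(ct)
  }
  invisible(x)
}

#' @export
coef.roi_glm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$label)
}

#' Extract the statistic of a regressor of interest
#'
#' @param glm a `roi_glm`.
#' @param label column label (e.g. `"pe_gain"`).
#' @param what `"estimate"`, `"t"` or `"z"`.
#' @return scalar.
#' @export
glm_stat <- function(glm, label, what = c("estimate", "t", "z")) {
  what <- match.arg(what)
  i <- match(label, glm$coefficients$label)
  if (is.na(i)) stop("no column labelled ", label)
  glm$coefficients[[what]][i]
}

#' Convert t statistics to z scores
#'
#' `z = qnorm(F_t(t; df))`, evaluated through log-probabilities in the tail
#' that preserves accuracy for large `|t|`; the sign of `t` is preserved and
#' `t = 0` maps to `z = 0`.
#'
#' @param t t statistic(s).
#' @param df residual degrees of freedom, `> 0`.
#' @return z score(s), same sign as `t`.
#' @export
t_to_z <- function(t, df) {
  if (any(df <= 0)) stop("df must be > 0")
  z <- numeric(length(t))
  neg <- !is.na(t) & t <= 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], df, log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], df, log.p = TRUE),
                           log.p = TRUE)
  z[is.na(t)] <- NA_real_
  z
}
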