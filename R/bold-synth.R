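#' Gamma-variate hemodynamic response function
#'
#' `h(t) = (t / (p w))^p * exp(p - t / w)`: zero at `t = 0` and unit peak at
#' `t = p * w`. The defaults `p = 8.6`, `w = 0.547` place the peak near
#' 4.7 s, a prototypical event-related response.
#'
#' @param time_grid nonnegative, increasing times in seconds.
#' @param p shape parameter (> 0, dimensionless).
#' @param w scale parameter in seconds (> 0).
#' @return kernel values on `time_grid`.
#' @export
gamma_hrf <- function(time_grid, p = 8.6, w = 0.547) {
  if (!(p > 0) || !(w > 0)) stop("HRF parameters p and w must be positive")
  if (any(time_grid < 0)) stop("time grid must be nonnegative")
  if (is.unsorted(time_grid, strictly = TRUE)) {
    stop("time grid must be increasing")
  }
  (time_grid / (p * w))^p * exp(p - time_grid / w)
}

#' HRF kernel sampled on the TR grid
#'
#' @param tr repetition time in seconds (default 2).
#' @param length_s kernel support in seconds (default 20, by which the
#'   default gamma-variate has decayed to < 1e-4 of its peak).
#' @param p,w gamma-variate parameters, see [gamma_hrf()].
#' @return numeric vector, the kernel at `t = 0, tr, 2 tr, ...`.
#' @export
hrf_kernel <- function(tr = 2, length_s = 20, p = 8.6, w = 0.547) {
  gamma_hrf(seq(0, length_s, by = tr), p = p, w = w)
}

#' Convolve an event train with an HRF kernel on the volume grid
#'
#' Places amplitude-scaled impulses at the volumes containing each onset and
#' convolves them discretely with the kernel, truncating to the run length.
#'
#' @param onsets event onsets in seconds, all within the run.
#' @param amplitudes per-event weights (recycled if length 1).
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param kernel kernel values on the TR grid, e.g. from [hrf_kernel()].
#' @return numeric regressor of length `n_volumes`.
#' @export
build_event_regressor <- function(onsets, amplitudes = 1, n_volumes, tr = 2,
                                  kernel = hrf_kernel(tr)) {
  if (length(onsets) == 0L) return(numeric(n_volumes))
  amplitudes <- rep(amplitudes, length.out = length(onsets))
  vol <- floor(onsets / tr) + 1L
  if (any(vol < 1L | vol > n_volumes)) {
    stop("onset beyond run end (", n_volumes * tr, " s)")
  }
  x <- numeric(n_volumes)
  for (i in seq_along(vol)) x[vol[i]] <- x[vol[i]] + amplitudes[i]
  out <- numeric(n_volumes + length(kernel) - 1L)
  for (j in seq_along(kernel)) {
    idx <- seq_len(n_volumes) + j - 1L
    out[idx] <- out[idx] + x * kernel[j]
  }
  out[seq_len(n_volumes)]
}

#' Coupling specification for synthetic ROI series
#'
#' @param event_amplitude named vector of per-condition event response
#'   amplitudes in percent-signal-change (PSC) units; unnamed scalar applies
#'   to all conditions.
#' @param pe_coupling PSC units of response per unit of (mean-centered)
#'   trial modulation, inserted at feedback onsets.
#' @param noise_sd marginal SD of the AR(1) Gaussian noise, PSC units.
#' @param ar1 lag-1 autocorrelation, `|ar1| < 1` (default 0.3).
#' @param drift baseline/linear/quadratic trend coefficients (PSC units on a
#'   volume index normalized to `[-1, 1]`).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(event_amplitude = 0.5, pe_coupling = 0.5,
                          noise_sd = 0.5, ar1 = 0.3,
                          drift = c(baseline = 0, linear = 0.5,
                                    quadratic = 0.2)) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(ar1) >= 1) stop("|ar1| must be < 1")
  drift <- rep(drift, length.out = 3)
  structure(list(event_amplitude = event_amplitude,
                 pe_coupling = pe_coupling, noise_sd = noise_sd,
                 ar1 = ar1, drift = drift),
            class = "coupling_spec")
}

# volume index normalized to [-1, 1] (conditioning of trend columns)
norm_volume_index <- function(n) {
  if (n == 1L) return(0)
  seq(-1, 1, length.out = n)
}

ar1_noise <- function(n, sd, ar1) {
  if (sd == 0 || n == 0L) return(numeric(n))
  innov_sd <- sd * sqrt(1 - ar1^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), ar1,
                           method = "recursive"))
}

#' Synthesize a ROI BOLD time series with PE-coupled event responses
#'
#' Forward model for one ROI and one run. A percent-signal component is
#' assembled from drift trends, per-condition event responses at feedback
#' onsets, and a parametric term `pe_coupling * modulation` (the modulation is
#' mean-centered within condition, standard parametric-modulation practice, so
#' it is decorrelated from the event regressor); AR(1) Gaussian noise is
#' added. The component is embedded multiplicatively around a raw baseline and
#' converted back to percent signal change relative to the run mean, so the
#' output is mean-zero and invariant to rescaling the raw series.
#'
#' @param schedule a `trial_schedule` (MIL or MID).
#' @param modulation per-trial modulation aligned with the schedule (e.g. the
#'   fitted signed PE on learning trials, `NA` or 0 elsewhere).
#' @param coupling a `coupling_spec`.
#' @param tr repetition time in seconds (default 2).
#' @param feedback_offset_s onset of the feedback event within each trial
#'   (default 6 s; choice and anticipation occupy the earlier phases).
#' @param hrf_params optional list with `p`, `w`, `length_s` for the kernel.
#' @param roi_label label for the ROI (e.g. `"MPFC"`).
#' @param seed optional integer seed for the noise stream.
#' @return an object of class `roi_timeseries`: list with `roi_label`, `tr_s`,
#'   `values` (PSC per volume), `n_volumes`, `time_s`.
#' @export
synthesize_roi_timeseries <- function(schedule, modulation = NULL,
                                      coupling = coupling_spec(), tr = 2,
                                      feedback_offset_s = 6,
                                      hrf_params = list(),
                                      roi_label = "ROI", seed = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(coupling, "coupling_spec"))
  if (!is.null(seed)) set.seed(seed)
  trs <- schedule$trials
  n_trials <- nrow(trs)
  if (is.null(modulation)) modulation <- rep(0, n_trials)
  if (length(modulation) != n_trials) {
    stop("modulation must align with the schedule (one value per trial)")
  }
  run_s <- schedule_run_length(schedule)
  n_vol <- ceiling(run_s / tr)
  kernel <- hrf_kernel(tr, hrf_params$length_s %||% 20,
                       hrf_params$p %||% 8.6, hrf_params$w %||% 0.547)
  fb <- trs$onset_s + feedback_offset_s
  if (any(fb >= run_s)) {
    warning("feedback events extend past the run end; truncating")
    keep <- fb < run_s
    trs <- trs[keep, , drop = FALSE]
    modulation <- modulation[keep]
    fb <- fb[keep]
  }
  u <- norm_volume_index(n_vol)
  signal <- coupling$drift[1] + coupling$drift[2] * u +
    coupling$drift[3] * u^2
  conds <- unique(trs$condition)
  amp <- coupling$event_amplitude
  for (cc in conds) {
    sel <- trs$condition == cc
    a <- if (!is.null(names(amp)) && cc %in% names(amp)) amp[[cc]] else amp[[1]]
    signal <- signal + build_event_regressor(fb[sel], a, n_vol, tr, kernel)
    m <- modulation[sel]
    m[is.na(m)] <- 0
    if (any(m != 0)) {
      m <- m - mean(m)
      signal <- signal + coupling$pe_coupling *
        build_event_regressor(fb[sel], m, n_vol, tr, kernel)
    }
  }
  noise <- ar1_noise(n_vol, coupling$noise_sd, coupling$ar1)
  baseline_raw <- 100
  raw <- baseline_raw * (1 + (signal - mean(signal) + noise) / 100)
  values <- psc_convert(raw)
  structure(
    list(roi_label = roi_label, tr_s = tr, values = values,
         n_volumes = n_vol, time_s = (seq_len(n_vol) - 1L) * tr),
    class = "roi_timeseries"
  )
}

#' Convert a raw series to percent signal change
#'
#' `100 * (raw - mean) / mean`; requires a positive run mean.
#'
#' @param raw raw series with positive mean.
#' @return mean-zero PSC series.
#' @export
psc_convert <- function(raw) {
  m <- mean(raw)
  if (!is.finite(m) || m <= 0) {
    stop("PSC conversion requires a positive run mean")
  }
  100 * (raw - m) / m
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<ROI %s: %d volumes at TR %.1f s, PSC sd %.3f>\n",
              x$roi_label, x$n_volumes, x$tr_s, stats::sd(x$values)))
  invisible(x)
}
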