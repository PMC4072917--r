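#' Write / read a trial schedule as TSV
#'
#' Columns: trial, block, condition, cue_ids (semicolon-joined), side,
#' onset_s, duration_s, iti_s. The cue table is written alongside with a
#' `# cue:` header comment per cue so the file round-trips.
#'
#' @param schedule a `trial_schedule`.
#' @param path output path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task_kind: %s", schedule$task_kind), con)
  for (cue in schedule$cues) {
    writeLines(sprintf("# cue: %s\t%.17g\t%.17g\t%.17g\t%s", cue$cue_id,
                       cue$win_prob, cue$win_amount, cue$lose_amount,
                       cue$valence), con)
  }
  utils::write.table(schedule$trials, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  task_kind <- sub("^# task_kind: ", "", grep("^# task_kind:", hdr,
                                              value = TRUE))
  cue_lines <- sub("^# cue: ", "", grep("^# cue:", hdr, value = TRUE))
  cues <- list()
  for (cl in cue_lines) {
    f <- strsplit(cl, "\t", fixed = TRUE)[[1]]
    cues[[f[1]]] <- cue_spec(f[1], as.numeric(f[2]), as.numeric(f[3]),
                             as.numeric(f[4]), f[5])
  }
  trials <- utils::read.table(text = lines[!grepl("^#", lines)],
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  trials$side <- as.character(trials$side)
  trials$cue_ids <- as.character(trials$cue_ids)
  blocks <- unique(trials$block)
  sched <- new_trial_schedule(
    task_kind, trials, cues,
    block_structure = data.frame(block_id = blocks,
                                 length = as.integer(table(trials$block)))
  )
  if (task_kind == "MID") sched$cue_types <- mid_cue_types()
  sched
}

#' Write / read a choice log as TSV
#'
#' Serializes the per-trial columns; when a fit is supplied, the fitted
#' value, signed PE and PE sign label are appended per learning trial.
#'
#' @param log a `choice_log`.
#' @param path output path.
#' @param fit optional `rwfit` whose PE series augments the log.
#' @export
write_choices_tsv <- function(log, path, fit = NULL) {
  out <- as.data.frame(log)
  if (!is.null(fit)) {
    i <- match(out$trial, fit$pe$trial)
    out$value_fit <- fit$pe$value_chosen[i]
    out$pe <- fit$pe$pe[i]
    out$pe_sign <- fit$pe$pe_sign[i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  cues <- attr(log, "cues")
  writeLines(sprintf("# task_kind: %s", attr(log, "task_kind")), con)
  for (i in seq_len(nrow(cues))) {
    writeLines(sprintf("# cue: %s\t%.17g\t%s", cues$cue_id[i],
                       cues$win_prob[i], cues$valence[i]), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_choices_tsv
#' @export
read_choices_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  task_kind <- sub("^# task_kind: ", "", grep("^# task_kind:", hdr,
                                              value = TRUE))
  cue_lines <- sub("^# cue: ", "", grep("^# cue:", hdr, value = TRUE))
  cues <- do.call(rbind, lapply(cue_lines, function(cl) {
    f <- strsplit(cl, "\t", fixed = TRUE)[[1]]
    data.frame(cue_id = f[1], win_prob = as.numeric(f[2]), valence = f[3],
               stringsAsFactors = FALSE)
  }))
  log <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  attr(log, "cues") <- cues
  attr(log, "task_kind") <- task_kind
  class(log) <- c("choice_log", "data.frame")
  log
}

#' Write a model fit as JSON
#'
#' @param fit an `rwfit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rwfit"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients),
         log_likelihood = fit$log_likelihood, bic = fit$bic,
         n_trials_used = fit$n_trials_used,
         convergence = fit$convergence, pe = fit$pe),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
}

#' Write / read a ROI time series as TSV
#'
#' Columns: volume, time_s, psc.
#'
#' @param series a `roi_timeseries`.
#' @param path output path.
#' @export
write_timeseries_tsv <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# roi: %s\ttr_s: %g", series$roi_label, series$tr_s),
             con)
  utils::write.table(
    data.frame(volume = seq_len(series$n_volumes), time_s = series$time_s,
               psc = series$values),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# roi:", lines, value = TRUE)[1]
  f <- strsplit(sub("^# roi: ", "", hdr), "\ttr_s: ", fixed = TRUE)[[1]]
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = "\t")
  structure(
    list(roi_label = f[1], tr_s = as.numeric(f[2]), values = d$psc,
         n_volumes = nrow(d), time_s = d$time_s),
    class = "roi_timeseries"
  )
}
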