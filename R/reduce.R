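# A cursor event is "on the line" when it falls inside the line strip;
# start-square events lie outside the strip by construction.
on_line <- function(cursor_x, config) {
  abs(cursor_x - 0.5) <= config$line_half_width + 1e-9
}

#' Reduce one trial's event log to the standard dependent variables
#'
#' Extracts, from the ordered click/release events of a single trial:
#' the initial vertical click position (first click on the line), the final
#' vertical cursor position (last release), the number of submovements
#' (click/release pairs on the line), and the response time (target onset,
#' i.e. the start-square release, to the final release). A trial is excluded
#' when the time from start-square onset (t = 0) to completion exceeds 10 s.
#'
#' @param log event data frame of a single trial (see [simulate_trial()]).
#' @param config the trial's [task_config()].
#' @return A one-row data frame: the trial-spec columns plus
#'   `initial_click_y`, `final_cursor_y`, `n_submovements`, `response_time`,
#'   `trial_duration`, and `excluded`.
#' @export
reduce_trial <- function(log, config) {
  log <- log[order(log$event_index), , drop = FALSE]
  kinds <- log$event_kind
  want <- rep(c("click", "release"), length.out = length(kinds))
  bad <- which(kinds != want)
  if (length(kinds) %% 2 == 1 || length(bad) > 0) {
    abort_domain("malformed trial log: events do not alternate click/release at event %d",
                 if (length(bad) > 0) bad[1] else length(kinds))
  }
  line <- on_line(log$cursor_x, config)
  line_clicks <- which(kinds == "click" & line)
  if (length(line_clicks) == 0) {
    abort_domain("malformed trial log: no click on the line")
  }
  sq_release <- which(kinds == "release" & !line)
  target_onset <- if (length(sq_release) > 0) log$time_s[sq_release[1]] else 0
  last <- nrow(log)
  duration <- log$time_s[last] # trial starts at start-square onset, t = 0
  data.frame(
    log[1, setdiff(names(log), c("event_index", "event_kind", "time_s",
                                 "cursor_x", "cursor_y", "line_offset")),
        drop = FALSE],
    initial_click_y = log$cursor_y[line_clicks[1]],
    final_cursor_y = log$cursor_y[last],
    n_submovements = length(line_clicks),
    response_time = log$time_s[last] - target_onset,
    trial_duration = duration,
    excluded = duration > 10,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Reduce a full event table, one summary row per trial
#'
#' @param events event data frame covering any number of trials.
#' @param config the [task_config()] of the experiment.
#' @return A data frame of per-trial summaries (see [reduce_trial()]).
#' @export
reduce_trials <- function(events, config) {
  key <- trial_key(events)
  rows <- lapply(split(events, key), reduce_trial, config = config)
  out <- do.call(rbind, rows)
  out <- out[order(out$participant, out$block,
                   if (all(is.na(out$subblock))) out$block else out$subblock,
                   out$trial_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a trial's submovements
#'
#' A submovement (one click/release pair on the line) is `corrective` when
#' the residual displacement to perfect alignment at its click is less than
#' 0.1 units, and `substantive` otherwise. A substantive submovement whose
#' cursor repositioning since the previous release is less than 0.1 units is
#' additionally flagged as a negligible reposition (the thresholds are
#' strict inequalities).
#'
#' @param log event data frame of a single trial.
#' @param config the trial's [task_config()].
#' @return A data frame with `submovement`, `label` (`corrective` /
#'   `substantive`), and `negligible_reposition`.
#' @export
classify_submovements <- function(log, config) {
  log <- log[order(log$event_index), , drop = FALSE]
  line <- on_line(log$cursor_x, config)
  clicks <- which(log$event_kind == "click" & line)
  d_total <- required_displacement(log$target_number[1], config)
  labels <- character(length(clicks))
  negligible <- logical(length(clicks))
  for (i in seq_along(clicks)) {
    j <- clicks[i]
    residual <- abs(d_total - log$line_offset[j])
    labels[i] <- if (residual < 0.1) "corrective" else "substantive"
    if (i > 1 && labels[i] == "substantive") {
      prev_release <- clicks[i] - 1L # the matching release precedes the click
      repositioning <- abs(log$cursor_y[j] - log$cursor_y[prev_release])
      negligible[i] <- repositioning < 0.1
    }
  }
  data.frame(
    submovement = seq_along(clicks), label = labels,
    negligible_reposition = negligible, stringsAsFactors = FALSE
  )
}

#' Per-participant condition means of the dependent variables
#'
#' Averages each dependent variable over non-excluded trials within every
#' participant-by-grouping cell. Empty cells (no non-excluded trial) are
#' reported explicitly rather than silently dropped.
#'
#' @param summaries per-trial summary data frame (see [reduce_trials()]).
#' @param grouping character vector of grouping columns (e.g.
#'   `c("target_number", "start_vertical")`).
#' @param dvs dependent-variable columns to average.
#' @return A data frame keyed by participant and the grouping columns, with
#'   cell means, a cell count `n_trials`, and an attribute `missing_cells`
#'   listing empty cells (also raised as a warning).
#' @export
summarize_conditions <- function(summaries, grouping,
                                 dvs = c("initial_click_y", "final_cursor_y",
                                         "n_submovements", "response_time")) {
  stopifnot(all(c("participant", grouping, dvs, "excluded") %in% names(summaries)))
  keep <- summaries[!summaries$excluded, , drop = FALSE]
  keys <- c("participant", grouping)
  # full grid of observed key levels so empty cells are visible
  lv <- lapply(keys, function(k) sort(unique(summaries[[k]])))
  names(lv) <- keys
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agg <- stats::aggregate(keep[dvs], by = keep[keys], FUN = mean)
  cnt <- stats::aggregate(list(n_trials = keep[[dvs[1]]]), by = keep[keys],
                          FUN = length)
  out <- merge(merge(grid, agg, by = keys, all.x = TRUE), cnt,
               by = keys, all.x = TRUE)
  out$n_trials[is.na(out$n_trials)] <- 0L
  missing <- out[out$n_trials == 0L, keys, drop = FALSE]
  if (nrow(missing) > 0) {
    warning(sprintf("%d empty participant-by-condition cell(s); see attr 'missing_cells'",
                    nrow(missing)), call. = FALSE)
  }
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_cells") <- missing
  out
}
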