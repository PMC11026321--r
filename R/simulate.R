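#' Motor-execution parameters for the trial simulator
#'
#' The simulator models execution, not planning: drags end with Gaussian
#' endpoint noise truncated at the screen borders, corrective re-clicks are
#' placed at the on-screen line point nearest the screen centre, and every
#' cursor segment takes a fixed preparation time plus a per-distance time.
#'
#' @param drag_sd SD of the drag endpoint noise (screen-height units).
#' @param reaction_s preparation time per segment (seconds).
#' @param speed_s_per_unit movement time per screen-height unit (seconds).
#' @param max_submovements abort threshold for non-converging trials.
#' @return A list of class `motor_params`.
#' @export
motor_params <- function(drag_sd = 0.02, reaction_s = 0.2,
                         speed_s_per_unit = 1.0, max_submovements = 50L) {
  stopifnot(drag_sd >= 0, reaction_s >= 0, speed_s_per_unit >= 0)
  structure(
    list(
      drag_sd = drag_sd, reaction_s = reaction_s,
      speed_s_per_unit = speed_s_per_unit,
      max_submovements = as.integer(max_submovements)
    ),
    class = "motor_params"
  )
}

# core event simulation for one trial; returns parallel event vectors.
# Times: t = 0 at start-square onset; the start-square release is the target
# onset. The line strip is clicked at its edge nearest the start square.
sim_trial_events <- function(spec, click_y, config, motor) {
  d_total <- required_displacement(spec$target_number, config)
  side <- if (spec$start_side == "left") -1 else 1
  start_x <- 0.5 + side * config$start_offset_horizontal
  start_y <- 0.5 + spec$start_vertical
  line_x <- 0.5 + side * config$line_half_width

  seg_time <- function(dist) motor$reaction_s + motor$speed_s_per_unit * dist

  kind <- character(0); time_s <- numeric(0)
  cx <- numeric(0); cy <- numeric(0); off <- numeric(0)
  push <- function(k, t, x, y, o) {
    kind <<- c(kind, k); time_s <<- c(time_s, t)
    cx <<- c(cx, x); cy <<- c(cy, y); off <<- c(off, o)
  }

  # start square: click and release (target onset at the release)
  t <- seg_time(0)
  push("click", t, start_x, start_y, 0)
  t <- t + motor$reaction_s
  push("release", t, start_x, start_y, 0)

  # reach the line at the planned click height
  reach <- sqrt((line_x - start_x)^2 + (click_y - start_y)^2)
  t <- t + seg_time(reach)

  offset <- 0
  y <- click_y
  n_sub <- 0L
  repeat {
    n_sub <- n_sub + 1L
    if (n_sub > motor$max_submovements) {
      abort_domain("trial did not converge within %d submovements",
                   motor$max_submovements)
    }
    push("click", t, line_x, y, offset)
    rem <- d_total - offset
    capacity <- if (rem < 0) y else 1 - y
    intended <- y + sign(rem) * min(abs(rem), capacity)
    end <- intended
    if (motor$drag_sd > 0) end <- end + stats::rnorm(1, 0, motor$drag_sd)
    end <- clamp(end, 0, 1)
    offset <- offset + (end - y)
    t <- t + seg_time(abs(end - y))
    push("release", t, line_x, end, offset)
    y <- end
    residual <- d_total - offset
    if (abs(residual) <= config$target_tolerance + 1e-12) {
      break # the line aligns itself on release
    }
    # plan the next submovement
    ci <- line_state(config, offset)$clickable_interval
    if (abs(residual) >= 0.1) {
      ideal <- if (residual < 0) -residual else 1 - residual
      y_new <- clamp(ideal, ci[1], ci[2])
    } else {
      y_new <- clamp(0.5, ci[1], ci[2])
    }
    t <- t + seg_time(abs(y_new - y))
    y <- y_new
  }
  list(kind = kind, time_s = time_s, cursor_x = cx, cursor_y = cy,
       line_offset = off)
}

#' Simulate one trial's click/release event log
#'
#' Produces the ordered click/release events of a single trial: the
#' start-square click and release (whose release is the target onset),
#' followed by one or more drags on the line. Drags end with Gaussian
#' endpoint noise truncated at the screen borders; if a release leaves the
#' target outside the alignment tolerance, further submovements are appended
#' (an optimal continuation re-click when at least 0.1 units remain, a
#' corrective re-click near the screen centre otherwise) until the target is
#' within tolerance, at which point the line aligns itself.
#'
#' @param spec one-row data frame (or list) of trial-spec fields as produced
#'   by [generate_exp1_design()] / [generate_exp2_design()].
#' @param click_y initial click position chosen by a strategy, in `[0, 1]`.
#' @param config the trial's [task_config()].
#' @param motor a [motor_params()].
#' @return A data frame of events with the trial-spec columns plus
#'   `event_index`, `event_kind`, `time_s`, `cursor_x`, `cursor_y`,
#'   `line_offset`.
#' @export
simulate_trial <- function(spec, click_y, config, motor = motor_params()) {
  stopifnot(click_y >= 0, click_y <= 1)
  ev <- sim_trial_events(spec, click_y, config, motor)
  n <- length(ev$kind)
  data.frame(
    participant = spec$participant, experiment = spec$experiment,
    block = spec$block, subblock = spec$subblock,
    trial_index = spec$trial_index, target_number = spec$target_number,
    start_vertical = spec$start_vertical, start_side = spec$start_side,
    condition = spec$condition,
    eccentricity_condition = spec$eccentricity_condition,
    event_index = seq_len(n), event_kind = ev$kind, time_s = ev$time_s,
    cursor_x = ev$cursor_x, cursor_y = ev$cursor_y,
    line_offset = ev$line_offset,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# choose the initial click for one trial under a named strategy
strategy_click <- function(strategy, req, spec, config, ctx, params) {
  y <- switch(strategy,
    minimal_path = {
      side <- if (spec$start_side == "left") -1 else 1
      start <- c(0.5 + side * config$start_offset_horizontal,
                 0.5 + spec$start_vertical)
      minimal_path_click(start, req, config)$click_y
    },
    target_click = target_click(req, config),
    edge_buffer = edge_buffer_click(req, line_state(config))$click_y,
    heuristic = return(heuristic_click(req, ctx, params)), # noise included
    abort_domain("unknown strategy '%s'", strategy)
  )
  if (params$noise_sd > 0) y <- y + stats::rnorm(1, 0, params$noise_sd)
  clamp(y, 0, 1)
}

#' Generate a full synthetic dataset from a design and a strategy
#'
#' Runs every trial of a design through a click-selection strategy and the
#' motor simulator, maintaining the heuristic's task-context state within
#' each participant (reset at block boundaries to the design's mean absolute
#' displacement and no previous click). Optional between-participant
#' variability perturbs the heuristic's base eccentricity and amplitude gain
#' with normal deviations.
#'
#' @param design trial-spec data frame from a design generator.
#' @param strategy one of `"minimal_path"`, `"target_click"`,
#'   `"edge_buffer"`, `"heuristic"`.
#' @param params a [strategy_params()]; `noise_sd` is applied to every
#'   strategy's click position.
#' @param motor a [motor_params()].
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @param jitter_e0,jitter_k SDs of per-participant normal deviations on the
#'   heuristic's base eccentricity and amplitude gain (0 disables).
#' @return A list with `events` (one data frame of all trials' event logs),
#'   and `manifest` (seed, strategy, parameters).
#' @export
generate_dataset <- function(design, strategy = "heuristic",
                             params = strategy_params(),
                             motor = motor_params(),
                             seed = 1L, jitter_e0 = 0.05, jitter_k = 0.1) {
  experiment <- unique(design$experiment)
  stopifnot(length(experiment) == 1)
  config <- task_config(experiment)
  init_mean <- mean(abs(required_displacement(design$target_number, config)))

  withr::with_seed(seed, {
    chunks <- vector("list", nrow(design))
    n_events <- integer(nrow(design))
    i <- 0L
    for (p in unique(design$participant)) {
      dp <- design[design$participant == p, , drop = FALSE]
      pp <- params
      if (strategy == "heuristic") {
        pp$base_eccentricity <- params$base_eccentricity +
          stats::rnorm(1, 0, jitter_e0)
        pp$amplitude_gain <- clamp(
          params$amplitude_gain + stats::rnorm(1, 0, jitter_k), 0, 1
        )
      }
      ctx <- context_state(mean_abs_amplitude = init_mean)
      cur_block <- NA
      for (r in seq_len(nrow(dp))) {
        spec <- dp[r, ]
        if (!identical(spec$block, cur_block)) {
          cur_block <- spec$block
          ctx <- context_state(mean_abs_amplitude = init_mean)
        }
        req <- scroll_requirement(spec$target_number, config)
        click_y <- strategy_click(strategy, req, spec, config, ctx, pp)
        ev <- sim_trial_events(spec, click_y, config, motor)
        i <- i + 1L
        chunks[[i]] <- ev
        n_events[i] <- length(ev$kind)
        ctx <- update_context(ctx, req, click_y, pp)
      }
    }
    chunks <- chunks[seq_len(i)]
    n_events <- n_events[seq_len(i)]
    idx <- rep(seq_len(nrow(design)), n_events)
    events <- data.frame(
      design[idx, , drop = FALSE],
      event_index = unlist(lapply(n_events, seq_len)),
      event_kind = unlist(lapply(chunks, `[[`, "kind")),
      time_s = unlist(lapply(chunks, `[[`, "time_s")),
      cursor_x = unlist(lapply(chunks, `[[`, "cursor_x")),
      cursor_y = unlist(lapply(chunks, `[[`, "cursor_y")),
      line_offset = unlist(lapply(chunks, `[[`, "line_offset")),
      row.names = NULL, stringsAsFactors = FALSE
    )
    list(
      events = events,
      manifest = list(
        seed = seed, experiment = experiment, strategy = strategy,
        params = unclass(params), motor = unclass(motor),
        jitter_e0 = jitter_e0, jitter_k = jitter_k,
        n_participants = length(unique(design$participant)),
        n_trials = nrow(design)
      )
    )
  })
}

trial_log_columns <- c(
  "participant", "experiment", "block", "subblock", "trial_index",
  "target_number", "start_vertical", "start_side", "condition",
  "eccentricity_condition", "event_index", "event_kind", "time_s",
  "cursor_x", "cursor_y", "line_offset"
)

#' Write / read trial logs in the package's CSV dialect
#'
#' One row per click/release event, header required, UTF-8, "." decimal
#' separator. `write_trial_logs()` optionally writes a JSON manifest next to
#' the CSV. `read_trial_logs()` validates the schema and the event
#' alternation invariant and round-trips with the writer.
#'
#' @param events event data frame (see [simulate_trial()] for columns).
#' @param path CSV file path.
#' @param manifest optional manifest list; written to `<path>.manifest.json`.
#' @return `read_trial_logs()` returns the validated event data frame;
#'   `write_trial_logs()` returns `path` invisibly.
#' @export
write_trial_logs <- function(events, path, manifest = NULL) {
  stopifnot(all(trial_log_columns %in% names(events)))
  utils::write.csv(events[, trial_log_columns], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trial_logs
#' @export
read_trial_logs <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  missing <- setdiff(trial_log_columns, names(events))
  if (length(missing) > 0) {
    abort_domain("trial-log file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", "))
  }
  if (nrow(events) > 0) {
    key <- trial_key(events)
    for (tr in split(seq_len(nrow(events)), key)) {
      kinds <- events$event_kind[tr]
      want <- rep(c("click", "release"), length.out = length(kinds))
      bad <- which(kinds != want)
      if (length(kinds) %% 2 == 1 || length(bad) > 0) {
        row <- tr[if (length(bad) > 0) bad[1] else length(kinds)]
        abort_domain(
          "trial-log file %s: events do not alternate click/release at row %d",
          path, row
        )
      }
    }
  }
  events[, trial_log_columns]
}
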