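#' Parameters of the two-component click-selection heuristic
#'
#' The heuristic selects a click eccentricity (absolute distance from the
#' screen centre) in two steps: a direction component placed at
#' `base_eccentricity` on the side opposite the scroll direction, adapted to
#' the running task context, and an amplitude component that shifts the
#' click outward or inward by `amplitude_gain` times the deviation of the
#' current required amplitude from the context's running mean amplitude.
#' A convex hysteresis blend pulls the planned eccentricity toward the
#' previous trial's realised click eccentricity.
#'
#' @param base_eccentricity direction-component distance of the click from
#'   the screen centre (screen-height units).
#' @param amplitude_gain dimensionless gain in `[0, 1]`: eccentricity shift
#'   per unit of amplitude deviation from the context mean. The default 0.5
#'   corresponds to a 50-pixel click shift per 100-pixel amplitude change.
#' @param hysteresis_weight lambda in `[0, 1]`: weight of the previous
#'   trial's click eccentricity in the convex blend.
#' @param context_rate alpha in `[0, 1]`: per-trial exponential-smoothing
#'   rate of the running mean absolute amplitude.
#' @param noise_sd SD of trial-level Gaussian click noise (screen-height
#'   units); draws are clipped to the screen.
#' @return A list of class `strategy_params`.
#' @export
strategy_params <- function(base_eccentricity = 0.25, amplitude_gain = 0.5,
                            hysteresis_weight = 0.3, context_rate = 0.1,
                            noise_sd = 0.07) {
  stopifnot(
    amplitude_gain >= 0, amplitude_gain <= 1,
    hysteresis_weight >= 0, hysteresis_weight <= 1,
    context_rate >= 0, context_rate <= 1,
    noise_sd >= 0
  )
  structure(
    list(
      base_eccentricity = base_eccentricity, amplitude_gain = amplitude_gain,
      hysteresis_weight = hysteresis_weight, context_rate = context_rate,
      noise_sd = noise_sd
    ),
    class = "strategy_params"
  )
}

#' Task-context state carried between trials
#'
#' @param mean_abs_amplitude running mean of absolute required displacements
#'   experienced in the current block.
#' @param prev_click_eccentricity `|y - 0.5|` of the previous click.
#' @param prev_click_y previous initial click position.
#' @return A list of class `context_state`.
#' @export
context_state <- function(mean_abs_amplitude, prev_click_eccentricity = NA_real_,
                          prev_click_y = NA_real_) {
  structure(
    list(
      mean_abs_amplitude = mean_abs_amplitude,
      prev_click_eccentricity = prev_click_eccentricity,
      prev_click_y = prev_click_y
    ),
    class = "context_state"
  )
}

#' Minimal-trajectory-length click position
#'
#' Finds the click position that minimises the total cursor path: the
#' Euclidean reach from the start square to the nearest point of the line
#' strip at the chosen height, plus the scroll path cost
#' ([scroll_path_cost()]) of completing the displacement from there,
#' assuming linear trajectories and no unnecessary movements. Ties are
#' broken toward the click closest to the start height, then toward the
#' screen centre.
#'
#' @param start numeric `c(x, y)` of the start-square centre.
#' @param requirement a [scroll_requirement()].
#' @param config a [task_config()].
#' @param state starting [line_state()].
#' @param resolution grid step for the click-position search.
#' @return A list with `click_y` and `total_path_length`.
#' @export
minimal_path_click <- function(start, requirement, config,
                               state = line_state(config),
                               resolution = 0.001) {
  d <- requirement$displacement
  ci <- state$clickable_interval
  gap <- max(0, abs(start[1] - 0.5) - config$line_half_width)
  candidates <- seq(ci[1], ci[2], by = resolution)
  extra <- c(clamp(start[2], ci[1], ci[2]), ci)
  og <- one_go_interval(d, state)
  if (!is.null(og)) extra <- c(extra, og, clamp(start[2], og[1], og[2]))
  candidates <- sort(unique(c(candidates, extra)))
  cost <- vapply(candidates, function(y) {
    sqrt(gap^2 + (y - start[2])^2) + scroll_path_cost(y, d, config, state)$length
  }, numeric(1))
  best <- min(cost)
  tied <- which(cost <= best + 1e-9)
  # tie-breaks: nearest to start height, then nearest to the screen centre
  tied <- tied[order(abs(candidates[tied] - start[2]), abs(candidates[tied] - 0.5))]
  y <- candidates[tied[1]]
  list(click_y = y, total_path_length = cost[tied[1]])
}

#' Target-square click position
#'
#' The centre of the target number's square if it is on screen, otherwise
#' the on-screen point of the line closest to it.
#'
#' @inheritParams minimal_path_click
#' @return Click position `click_y`.
#' @export
target_click <- function(requirement, config, state = line_state(config)) {
  y <- square_center_y(requirement$target_number, config, offset = state$offset)
  ci <- state$clickable_interval
  clamp(y, ci[1], ci[2])
}

#' Border-buffer click position
#'
#' Models clicking anywhere that allows completing the scroll in one rapid
#' movement to the screen border, without caring about accuracy. The point
#' prediction is the midpoint of the one-go interval; the strategy predicts
#' the final cursor at the destination border.
#'
#' @inheritParams minimal_path_click
#' @return A list with `click_y`, the one-go `interval`, and
#'   `predicted_final_y` (the destination screen border).
#' @export
edge_buffer_click <- function(requirement, state) {
  d <- requirement$displacement
  if (d == 0) abort_domain("edge_buffer_click: displacement is zero")
  og <- one_go_interval(d, state)
  if (is.null(og)) abort_domain("edge_buffer_click: no one-go click position exists")
  list(
    click_y = mean(og), interval = og,
    predicted_final_y = if (d < 0) 0 else 1,
    predicted_final_at_border = TRUE
  )
}

#' Two-component heuristic click position
#'
#' Deterministic core: `e* = base_eccentricity + amplitude_gain *
#' (|d| - mean_abs_amplitude)`, blended with the previous click eccentricity
#' as `e = (1 - lambda) e* + lambda * prev_click_eccentricity`, then placed
#' on the side opposite the scroll direction, `y = 0.5 - sign(d) * e`
#' (upward scrolls yield low clicks), plus Gaussian noise clipped to the
#' screen.
#'
#' @param requirement a [scroll_requirement()] with nonzero displacement.
#' @param ctx a [context_state()]. A missing previous eccentricity (start of
#'   a block) drops the hysteresis blend for that trial.
#' @param params a [strategy_params()].
#' @return Click position in `[0, 1]`.
#' @export
heuristic_click <- function(requirement, ctx, params) {
  d <- requirement$displacement
  if (d == 0) abort_domain("heuristic_click: displacement is zero")
  e_star <- params$base_eccentricity +
    params$amplitude_gain * (abs(d) - ctx$mean_abs_amplitude)
  lambda <- params$hysteresis_weight
  e <- if (is.na(ctx$prev_click_eccentricity) || lambda == 0) {
    e_star
  } else {
    (1 - lambda) * e_star + lambda * ctx$prev_click_eccentricity
  }
  y <- 0.5 - sign(d) * e
  if (params$noise_sd > 0) y <- y + stats::rnorm(1, 0, params$noise_sd)
  clamp(y, 0, 1)
}

#' Update the task-context state after a trial
#'
#' The running mean absolute amplitude is exponentially smoothed at rate
#' `context_rate`; the previous-click fields are replaced by the current
#' trial's realised click.
#'
#' @param ctx a [context_state()].
#' @param requirement the trial's [scroll_requirement()].
#' @param click_y the trial's realised initial click position.
#' @param params a [strategy_params()].
#' @return The updated [context_state()].
#' @export
update_context <- function(ctx, requirement, click_y, params) {
  a <- params$context_rate
  context_state(
    mean_abs_amplitude =
      (1 - a) * ctx$mean_abs_amplitude + a * abs(requirement$displacement),
    prev_click_eccentricity = abs(click_y - 0.5),
    prev_click_y = click_y
  )
}

#' Minimal-path click predictions for every design cell
#'
#' Computes the minimal-trajectory click position for each combination of
#' target number and vertical start position of a design (sides are mirror
#' images in x and give identical vertical predictions; the horizontal reach
#' uses the configured start offset).
#'
#' @param config a [task_config()].
#' @param targets integer targets; defaults to all non-centre numbers.
#' @return A data frame with `target_number`, `start_vertical`,
#'   `displacement`, `click_y`, and `total_path_length`.
#' @export
minimal_path_predictions <- function(config, targets = NULL) {
  if (is.null(targets)) {
    targets <- setdiff(line_numbers(config), config$center_number)
  }
  grid <- expand.grid(
    target_number = targets,
    start_vertical = config$start_offsets_vertical,
    KEEP.OUT.ATTRS = FALSE
  )
  start_x <- 0.5 + config$start_offset_horizontal
  res <- lapply(seq_len(nrow(grid)), function(i) {
    req <- scroll_requirement(grid$target_number[i], config)
    mp <- minimal_path_click(
      c(start_x, 0.5 + grid$start_vertical[i]), req, config
    )
    data.frame(
      target_number = grid$target_number[i],
      start_vertical = grid$start_vertical[i],
      displacement = req$displacement,
      click_y = mp$click_y,
      total_path_length = mp$total_path_length
    )
  })
  do.call(rbind, res)
}

#' Recover heuristic parameters from observed trials
#'
#' Under the two-component heuristic, the observed click eccentricity on
#' trial t satisfies `ecc_t = (1 - lambda) (e0 + k (|d_t| - m_t)) +
#' lambda * ecc_{t-1} + noise`, where `m_t` is the running mean amplitude
#' (reconstructed from the displacement stream at rate `alpha`). Ordinary
#' least squares of the signed eccentricity on the amplitude deviation and
#' the previous eccentricity therefore identifies `lambda` (the previous-
#' eccentricity weight) and `k = b_dev / (1 - lambda)`. Fits are per
#' participant and averaged.
#'
#' @param trials data frame with columns `participant`, `block`,
#'   `trial_index`, `displacement`, `click_y` (trial order within block).
#' @param alpha context-smoothing rate used to reconstruct the running mean.
#' @param init_mean initial running-mean amplitude at each block start;
#'   default is the design's overall mean absolute displacement.
#' @return A list with `lambda`, `k`, `e0`, and the per-participant
#'   estimates.
#' @export
recover_heuristic_params <- function(trials, alpha = 0.1, init_mean = NULL) {
  stopifnot(all(c("participant", "block", "trial_index", "displacement",
                  "click_y") %in% names(trials)))
  if (is.null(init_mean)) init_mean <- mean(abs(trials$displacement))
  per <- lapply(split(trials, trials$participant), function(df) {
    df <- df[order(df$block, df$trial_index), ]
    ecc <- sign(-df$displacement) * (df$click_y - 0.5)
    n <- nrow(df)
    m <- numeric(n)
    prev <- numeric(n)
    first <- logical(n)
    cur_m <- init_mean
    cur_prev <- NA_real_
    cur_block <- NA
    for (i in seq_len(n)) {
      if (!identical(df$block[i], cur_block)) {
        cur_block <- df$block[i]
        cur_m <- init_mean
        cur_prev <- NA_real_
      }
      m[i] <- cur_m
      prev[i] <- cur_prev
      first[i] <- is.na(cur_prev)
      cur_m <- (1 - alpha) * cur_m + alpha * abs(df$displacement[i])
      cur_prev <- abs(df$click_y[i] - 0.5)
    }
    keep <- !first
    dev <- abs(df$displacement) - m
    fit <- stats::lm(ecc[keep] ~ dev[keep] + prev[keep])
    b <- stats::coef(fit)
    lambda <- unname(b[3])
    k <- unname(b[2]) / (1 - lambda)
    e0 <- unname(b[1]) / (1 - lambda)
    c(lambda = lambda, k = k, e0 = e0)
  })
  est <- do.call(rbind, per)
  list(
    lambda = mean(est[, "lambda"]), k = mean(est[, "k"]),
    e0 = mean(est[, "e0"]), per_participant = est
  )
}
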