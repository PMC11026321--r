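#' Task geometry for a number-line scrolling experiment
#'
#' A `task_config` encodes the screen geometry and drag mechanics of one
#' experiment: a vertical line of numbered squares centred on the screen,
#' which moves with the cursor's y coordinate while the mouse button is held.
#' All lengths are in screen-height units; y = 0 is the bottom edge of the
#' screen and y = 1 the top edge. The square containing `center_number`
#' starts at the screen centre (y = 0.5), and the square for number `t` is
#' centred at `0.5 + (center_number - t) * square_edge` (numbers ascend
#' downwards).
#'
#' Two presets are provided:
#' \describe{
#'   \item{`"exp1"`}{9 squares of edge 0.2, numbered 1 (top) to 9 (bottom),
#'     centre number 5, numbers 3-7 initially visible, release tolerance
#'     0.02, start squares at vertical offsets -0.4/0/+0.4 and horizontal
#'     offset +/-0.4, line half-width 0.1.}
#'   \item{`"exp2"`}{11 squares of edge 0.14, numbered 10 (top) to 20
#'     (bottom), centre number 15, numbers 12-18 initially visible, release
#'     tolerance 0.014, vertically centred start squares at horizontal
#'     offset +/-0.29, line half-width 0.07.}
#' }
#'
#' @param preset `"exp1"`, `"exp2"`, or `NULL` to build a config from the
#'   remaining arguments.
#' @param square_edge edge length of one number square.
#' @param n_squares number of squares on the line.
#' @param top_number,bottom_number numbers printed on the top and bottom
#'   squares (consecutive integers in between).
#' @param center_number number whose square starts at the screen centre.
#' @param visible_numbers integer range of numbers initially on screen.
#' @param target_tolerance release tolerance for successful alignment.
#' @param start_offsets_vertical vertical start-square offsets from centre.
#' @param start_offset_horizontal absolute horizontal start-square offset.
#' @param line_half_width half-width of the clickable strip.
#' @param start_square_edge edge length of the start square.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config("exp1")
#' required_displacement(9, cfg)
#' @export
task_config <- function(preset = NULL,
                        square_edge = NULL, n_squares = NULL,
                        top_number = NULL, bottom_number = NULL,
                        center_number = NULL, visible_numbers = NULL,
                        target_tolerance = NULL,
                        start_offsets_vertical = NULL,
                        start_offset_horizontal = NULL,
                        line_half_width = NULL,
                        start_square_edge = 0.1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("exp1", "exp2"))
    cfg <- switch(preset,
      exp1 = list(
        name = "exp1", square_edge = 0.2, n_squares = 9L,
        top_number = 1L, bottom_number = 9L, center_number = 5L,
        visible_numbers = 3:7, target_tolerance = 0.02,
        start_offsets_vertical = c(-0.4, 0, 0.4),
        start_offset_horizontal = 0.4,
        line_half_width = 0.1, start_square_edge = 0.1
      ),
      exp2 = list(
        name = "exp2", square_edge = 0.14, n_squares = 11L,
        top_number = 10L, bottom_number = 20L, center_number = 15L,
        visible_numbers = 12:18, target_tolerance = 0.014,
        start_offsets_vertical = 0,
        start_offset_horizontal = 0.29,
        line_half_width = 0.07, start_square_edge = 0.1
      )
    )
  } else {
    cfg <- list(
      name = "custom", square_edge = square_edge, n_squares = n_squares,
      top_number = top_number, bottom_number = bottom_number,
      center_number = center_number, visible_numbers = visible_numbers,
      target_tolerance = target_tolerance,
      start_offsets_vertical = start_offsets_vertical,
      start_offset_horizontal = start_offset_horizontal,
      line_half_width = line_half_width, start_square_edge = start_square_edge
    )
    if (any(vapply(cfg, is.null, logical(1)))) {
      abort_domain("task_config: all geometry fields are required when no preset is given")
    }
  }
  stopifnot(cfg$n_squares == cfg$bottom_number - cfg$top_number + 1L)
  class(cfg) <- "task_config"
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(
    "<task_config '%s'> %d squares (%d..%d), edge %.3g, centre %d, tolerance %.3g\n",
    x$name, x$n_squares, x$top_number, x$bottom_number,
    x$square_edge, x$center_number, x$target_tolerance
  ))
  invisible(x)
}

#' Numbers printed on the line
#' @param config a [task_config()].
#' @return Integer vector of all numbers on the line, top to bottom.
#' @export
line_numbers <- function(config) config$top_number:config$bottom_number

#' Screen y of a number square's centre
#'
#' @param number integer number(s) on the line.
#' @param config a [task_config()].
#' @param offset current vertical line offset from its initial position.
#' @return y coordinate(s) of the square centre(s).
#' @export
square_center_y <- function(number, config, offset = 0) {
  bad <- !(number %in% line_numbers(config))
  if (any(bad)) {
    abort_domain("unknown target number(s): %s", paste(number[bad], collapse = ", "))
  }
  0.5 + (config$center_number - number) * config$square_edge + offset
}

# initial on-axis extremes of the line (bottom of bottom square, top of top
# square), before any offset
line_extent <- function(config) {
  e <- config$square_edge / 2
  c(
    bottom = square_center_y(config$bottom_number, config) - e,
    top    = square_center_y(config$top_number, config) + e
  )
}

#' Current state of the number line
#'
#' @param config a [task_config()].
#' @param offset signed vertical shift of the whole line from its initial
#'   position (positive = line moved up).
#' @return A `line_state` with the offset and the on-screen clickable
#'   y-interval of the line.
#' @export
line_state <- function(config, offset = 0) {
  ext <- line_extent(config)
  lo <- max(0, ext[["bottom"]] + offset)
  hi <- min(1, ext[["top"]] + offset)
  structure(
    list(offset = offset, clickable_interval = c(lo, hi)),
    class = "line_state"
  )
}

#' Signed line displacement required to centre a target
#'
#' Positive values mean the line must move up (an upward scroll, realised by
#' dragging the cursor upwards); negative values mean a downward scroll.
#'
#' @param target integer number on the line.
#' @param config a [task_config()].
#' @param state a [line_state()]; defaults to the initial state.
#' @return Signed displacement in screen-height units.
#' @export
required_displacement <- function(target, config, state = line_state(config)) {
  0.5 - square_center_y(target, config, offset = state$offset)
}

#' Scroll requirement for a target
#'
#' @inheritParams required_displacement
#' @return A list with `target_number`, signed `displacement`, and
#'   `direction` (`"up"` for positive displacement, `"down"` for negative;
#'   `NA` for zero, which occurs in neither design).
#' @export
scroll_requirement <- function(target, config, state = line_state(config)) {
  d <- required_displacement(target, config, state)
  dir <- if (d > 0) "up" else if (d < 0) "down" else NA_character_
  list(target_number = target, displacement = d, direction = dir)
}

#' Click positions from which a displacement is achievable in one go
#'
#' A single press-drag-release can move the line down by at most `click_y`
#' (the cursor stops at the bottom screen border) and up by at most
#' `1 - click_y`. The one-go set is the part of the line's clickable
#' interval satisfying the corresponding capacity constraint.
#'
#' @param d signed displacement (positive = upward scroll).
#' @param state a [line_state()].
#' @return Numeric `c(lo, hi)`, or `NULL` if the set is empty.
#' @export
one_go_interval <- function(d, state) {
  ci <- state$clickable_interval
  lo <- ci[1]; hi <- ci[2]
  if (d < 0) lo <- max(lo, -d)   # need capacity to drag down by |d|
  if (d > 0) hi <- min(hi, 1 - d) # need capacity to drag up by d
  if (lo > hi + 1e-12) return(NULL)
  c(lo, hi)
}

#' Cursor path length of a scroll under the no-unnecessary-movement policy
#'
#' Starting from a click at `click_y`, the policy drags as far as the screen
#' border allows, releases, travels vertically to the best re-click position
#' within the line's new clickable extent, and repeats until the remaining
#' displacement fits in one drag. Drags sum exactly to `|d|`; any excess
#' path length is return travel between drags.
#'
#' @param click_y initial click position (inside the clickable interval).
#' @param d signed displacement (positive = upward scroll).
#' @param config a [task_config()].
#' @param state starting [line_state()].
#' @return A list with `length` (total vertical cursor distance from the
#'   first click to the final release) and `n_drags`.
#' @export
scroll_path_cost <- function(click_y, d, config, state = line_state(config)) {
  ci <- state$clickable_interval
  if (click_y < ci[1] - 1e-9 || click_y > ci[2] + 1e-9) {
    abort_domain("click_y = %g is outside the clickable interval [%g, %g]",
                 click_y, ci[1], ci[2])
  }
  total <- 0
  n_drags <- 0L
  y <- click_y
  offset <- state$offset
  rem <- d
  repeat {
    if (abs(rem) < 1e-12) break
    capacity <- if (rem < 0) y else 1 - y
    if (abs(rem) <= capacity + 1e-12) {
      total <- total + abs(rem)
      n_drags <- n_drags + 1L
      rem <- 0
      break
    }
    # drag to the border, release
    step <- sign(rem) * capacity
    total <- total + capacity
    n_drags <- n_drags + 1L
    offset <- offset + step
    rem <- rem - step
    y <- if (rem < 0) 0 else 1   # cursor now at the border
    # best re-click: just enough capacity for the remainder, clamped to the
    # line's new clickable extent
    ci_new <- line_state(config, offset)$clickable_interval
    if (ci_new[1] > ci_new[2] + 1e-12) {
      abort_domain("displacement unreachable: clickable extent is empty at offset %g", offset)
    }
    ideal <- if (rem < 0) -rem else 1 - rem
    y_new <- clamp(ideal, ci_new[1], ci_new[2])
    total <- total + abs(y_new - y)
    y <- y_new
    if (n_drags > 100L) {
      abort_domain("scroll_path_cost did not converge (degenerate geometry?)")
    }
  }
  list(length = total, n_drags = n_drags)
}

#' Write / read a task configuration as a flat key-value file
#'
#' @param config a [task_config()].
#' @param path file path.
#' @return `read_task_config()` returns a [task_config()];
#'   `write_task_config()` returns `path` invisibly.
#' @export
write_task_config <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 15, scientific = FALSE), collapse = ",")
  keys <- setdiff(names(unclass(config)), NULL)
  lines <- vapply(keys, function(k) paste0(k, " = ", fmt(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  }
  cfg <- lapply(vals, parse1)
  names(cfg) <- keys
  int_fields <- c("n_squares", "top_number", "bottom_number", "center_number",
                  "visible_numbers")
  for (f in intersect(int_fields, names(cfg))) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$name <- as.character(cfg$name)
  class(cfg) <- "task_config"
  cfg
}
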