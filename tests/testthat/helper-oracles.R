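# Independent oracles used across test files. They deliberately avoid the
# package's own scroll_path_cost / minimal_path_click / rm_anova_gg code
# paths: costs are found by exhaustive grid search and ANOVA sums of squares
# by explicit mean decompositions.

# step-simulation oracle for required_displacement: nudge the line until the
# target square centre is within tol of the screen centre, accumulating the
# displacement
oracle_required_displacement <- function(target, config, step = 1e-4,
                                         tol = 5e-5) {
  offset <- 0
  y <- square_center_y(target, config, offset)
  dir <- if (y > 0.5) -1 else 1
  n <- 0
  while (abs(y - 0.5) > tol) {
    offset <- offset + dir * step
    y <- square_center_y(target, config, offset)
    n <- n + 1
    if (n > 5e5) stop("oracle did not converge")
  }
  offset
}

# clickable interval of the line at a given offset (re-derived from first
# principles: square centres +/- half an edge, truncated at the screen)
oracle_clickable <- function(config, offset) {
  ys <- square_center_y(line_numbers(config), config, offset)
  c(max(0, min(ys) - config$square_edge / 2),
    min(1, max(ys) + config$square_edge / 2))
}

# exhaustive-grid oracle for the scroll path cost: if the displacement fits
# in one drag, the cost is |d|; otherwise drag to the border and search all
# re-click positions on a 0.001 grid (both designs complete in <= 2 drags
# from any click, asserted here)
oracle_scroll_cost <- function(click_y, d, config, grid = 1e-3) {
  capacity <- if (d < 0) click_y else 1 - click_y
  if (abs(d) <= capacity + 1e-12) {
    return(list(length = abs(d), n_drags = 1L))
  }
  step <- sign(d) * capacity
  rem <- d - step
  border <- if (d < 0) 0 else 1
  ci <- oracle_clickable(config, step)
  yp <- seq(ci[1], ci[2], by = grid)
  yp <- unique(c(yp, ci[2], abs(rem), 1 - abs(rem)))
  yp <- yp[yp >= ci[1] - 1e-12 & yp <= ci[2] + 1e-12]
  cap2 <- if (rem < 0) yp else 1 - yp
  feasible <- cap2 >= abs(rem) - 1e-12
  stopifnot(any(feasible)) # two drags always suffice in these designs
  costs <- abs(yp[feasible] - border) + abs(rem)
  list(length = capacity + min(costs), n_drags = 2L)
}

# exhaustive-grid oracle for the minimal-trajectory click position, with the
# same tie-breaking convention (closest to start height, then to centre)
oracle_minimal_path <- function(start, d, config, grid = 1e-3) {
  ci <- oracle_clickable(config, 0)
  gap <- max(0, abs(start[1] - 0.5) - config$line_half_width)
  ys <- unique(sort(c(seq(ci[1], ci[2], by = grid), ci,
                      min(max(start[2], ci[1]), ci[2]))))
  total <- vapply(ys, function(y) {
    sqrt(gap^2 + (y - start[2])^2) +
      oracle_scroll_cost(y, d, config, grid)$length
  }, numeric(1))
  best <- min(total)
  tied <- which(total <= best + 1e-9)
  tied <- tied[order(abs(ys[tied] - start[2]), abs(ys[tied] - 0.5))]
  list(click_y = ys[tied[1]], total = total[tied[1]])
}

# brute-force sums-of-squares decomposition for a two-way fully within
# design given a participants x (a*b) cell-mean matrix (columns: factor A
# varying fastest)
oracle_rm_anova_2way <- function(Y, a, b) {
  n <- nrow(Y)
  A <- array(Y, c(n, a, b))
  g <- mean(A)
  m_i <- apply(A, 1, mean); m_a <- apply(A, 2, mean); m_b <- apply(A, 3, mean)
  m_ia <- apply(A, c(1, 2), mean); m_ib <- apply(A, c(1, 3), mean)
  m_ab <- apply(A, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_ab <- n * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + g)^2)
  ss_s <- a * b * sum((m_i - g)^2)
  ss_as <- b * sum((m_ia - outer(m_i, rep(1, a)) -
                      outer(rep(1, n), m_a) + g)^2)
  ss_bs <- a * sum((m_ib - outer(m_i, rep(1, b)) -
                      outer(rep(1, n), m_b) + g)^2)
  resid <- A
  for (i in 1:n) for (j in 1:a) for (k in 1:b) {
    resid[i, j, k] <- A[i, j, k] - m_ia[i, j] - m_ib[i, k] - m_ab[j, k] +
      m_i[i] + m_a[j] + m_b[k] - g
  }
  ss_abs <- sum(resid^2)
  list(
    F_A = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    F_B = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    F_AB = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_abs / ((a - 1) * (b - 1) * (n - 1))),
    ss = c(A = ss_a, B = ss_b, AB = ss_ab, S = ss_s,
           AS = ss_as, BS = ss_bs, ABS = ss_abs)
  )
}

# Box / Greenhouse-Geisser epsilon for a one-way repeated factor via the
# double-centred covariance matrix (an algebraically different route from
# the package's orthonormal-contrast eigenvalue formula)
oracle_gg_epsilon_1way <- function(M) {
  S <- stats::cov(M)
  k <- ncol(S)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

# small canonical fixture: a deterministic heuristic dataset
make_exp1_dataset <- function(n = 4, seed = 11, lambda = 0.3,
                              noise_sd = 0.07, drag_sd = 0.02) {
  design <- generate_exp1_design(n, seed = seed)
  generate_dataset(
    design, strategy = "heuristic",
    params = strategy_params(hysteresis_weight = lambda, noise_sd = noise_sd),
    motor = motor_params(drag_sd = drag_sd),
    seed = seed + 1
  )
}

# hand-built single-trial event log (start-square pair + given line drags)
make_manual_log <- function(drags, target = 3, config = task_config("exp1"),
                            times = NULL) {
  n_ev <- 2 + 2 * nrow(drags)
  if (is.null(times)) times <- seq(0.2, by = 0.5, length.out = n_ev)
  offs <- cumsum(c(0, drags$to - drags$from))
  data.frame(
    participant = 1L, experiment = "exp1", block = 1L, subblock = NA_integer_,
    trial_index = 1L, target_number = target, start_vertical = 0,
    start_side = "right", condition = "none", eccentricity_condition = "none",
    event_index = seq_len(n_ev),
    event_kind = rep(c("click", "release"), n_ev / 2),
    time_s = times,
    cursor_x = c(0.9, 0.9, rep(0.6, n_ev - 2)),
    cursor_y = c(0.5, 0.5, as.vector(rbind(drags$from, drags$to))),
    line_offset = c(0, 0, as.vector(rbind(offs[-length(offs)], offs[-1]))),
    stringsAsFactors = FALSE
  )
}
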