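test_that("minimal-path clicks match the grid oracle on hand-worked cases", {
  cfg <- task_config("exp1")
  # one-go reachable at own height: click where you are
  res <- minimal_path_click(c(0.9, 0.9), scroll_requirement(3, cfg), cfg)
  expect_equal(res$click_y, 0.9)
  expect_equal(res$total_path_length, 0.3 + 0.4)
  # far downward scroll from the centre: diagonal reach to the one-go border
  res <- minimal_path_click(c(0.9, 0.5), scroll_requirement(1, cfg), cfg)
  expect_equal(res$click_y, 0.8)
  expect_equal(res$total_path_length, sqrt(0.3^2 + 0.3^2) + 0.8, tolerance = 1e-9)
  # zero displacement: straight horizontal move
  res <- minimal_path_click(c(0.9, 0.5), scroll_requirement(5, cfg), cfg)
  expect_equal(res$click_y, 0.5)
  expect_equal(res$total_path_length, 0.3)
})

test_that("minimal-path clicks equal the brute-force oracle on every design cell", {
  for (preset in c("exp1", "exp2")) {
    cfg <- task_config(preset)
    start_x <- 0.5 + cfg$start_offset_horizontal
    for (t in setdiff(line_numbers(cfg), cfg$center_number)) {
      d <- required_displacement(t, cfg)
      for (sv in cfg$start_offsets_vertical) {
        start <- c(start_x, 0.5 + sv)
        got <- minimal_path_click(start, scroll_requirement(t, cfg), cfg)
        want <- oracle_minimal_path(start, d, cfg)
        expect_equal(got$click_y, want$click_y, tolerance = 1e-9,
                     info = sprintf("%s target %d start %g", preset, t, sv))
        expect_equal(got$total_path_length, want$total, tolerance = 1e-9)
      }
    }
  }
})

test_that("minimal-path predictions show the clamp-to-one-go signature", {
  cfg <- task_config("exp1")
  st <- line_state(cfg)
  pred <- minimal_path_predictions(cfg)
  for (i in seq_len(nrow(pred))) {
    og <- one_go_interval(pred$displacement[i], st)
    start_y <- 0.5 + pred$start_vertical[i]
    expect_equal(pred$click_y[i], min(max(start_y, og[1]), og[2]),
                 info = sprintf("target %d start %g",
                                pred$target_number[i], pred$start_vertical[i]))
  }
})

test_that("target clicks aim at the target square, clamped to the screen", {
  cfg <- task_config("exp1")
  expect_equal(target_click(scroll_requirement(3, cfg), cfg), 0.9)
  expect_equal(target_click(scroll_requirement(5, cfg), cfg), 0.5)
  # square centre at -0.3 is off screen; nearest on-screen line point
  expect_equal(target_click(scroll_requirement(9, cfg), cfg), 0)
})

test_that("border-buffer clicks sit in the one-go set and predict a border stop", {
  cfg1 <- task_config("exp1")
  res <- edge_buffer_click(scroll_requirement(3, cfg1), line_state(cfg1))
  expect_equal(res$interval, c(0.4, 1))
  expect_true(res$click_y >= 0.4 && res$click_y <= 1)
  expect_identical(res$predicted_final_y, 0)
  cfg2 <- task_config("exp2")
  res <- edge_buffer_click(scroll_requirement(20, cfg2), line_state(cfg2))
  expect_equal(res$interval, c(0, 0.3))
  expect_identical(res$predicted_final_y, 1)
  expect_error(edge_buffer_click(scroll_requirement(5, cfg1), line_state(cfg1)),
               "zero")
})

test_that("heuristic clicks follow the two-component rule", {
  p <- strategy_params(base_eccentricity = 0.25, amplitude_gain = 0.5,
                       hysteresis_weight = 0, noise_sd = 0)
  req_up <- list(target_number = 8, displacement = 0.6, direction = "up")
  ctx <- context_state(mean_abs_amplitude = 0.6)
  # amplitude term vanishes when |d| equals the context mean
  expect_equal(heuristic_click(req_up, ctx, p), 0.5 - 0.25)
  # increasing |d| by delta shifts the click by gain * delta away from centre
  req_up2 <- list(target_number = 9, displacement = 0.8, direction = "up")
  expect_equal(heuristic_click(req_up, ctx, p) - heuristic_click(req_up2, ctx, p),
               0.5 * 0.2)
  # full hysteresis reproduces the previous eccentricity regardless of d
  p1 <- strategy_params(hysteresis_weight = 1, noise_sd = 0)
  ctx1 <- context_state(0.4, prev_click_eccentricity = 0.12, prev_click_y = 0.62)
  expect_equal(heuristic_click(req_up, ctx1, p1), 0.5 - 0.12)
  expect_error(heuristic_click(list(displacement = 0), ctx, p), "zero")
})

test_that("heuristic clicks are antisymmetric in direction and monotone in amplitude", {
  p <- strategy_params(hysteresis_weight = 0, noise_sd = 0)
  ctx <- context_state(mean_abs_amplitude = 0.5)
  for (d in c(0.2, 0.4, 0.6, 0.8)) {
    up <- heuristic_click(list(displacement = d), ctx, p)
    down <- heuristic_click(list(displacement = -d), ctx, p)
    expect_equal(up + down, 1, info = sprintf("d = %g", d))
  }
  eccs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(d) {
    abs(heuristic_click(list(displacement = d), ctx, p) - 0.5)
  }, numeric(1))
  expect_true(all(diff(eccs) >= 0))
})

test_that("strategy outputs always lie on the screen after clipping", {
  p <- strategy_params(noise_sd = 0.4)
  ctx <- context_state(0.5, 0.2, 0.7)
  withr::with_seed(99, {
    ys <- replicate(500, heuristic_click(list(displacement = sample(c(-0.8, 0.8), 1)),
                                         ctx, p))
  })
  expect_true(all(ys >= 0 & ys <= 1))
})

test_that("context updates follow exponential smoothing exactly", {
  p0 <- strategy_params(context_rate = 0)
  p1 <- strategy_params(context_rate = 1)
  pa <- strategy_params(context_rate = 0.3)
  ctx <- context_state(0.5)
  req <- list(displacement = -0.8)
  expect_equal(update_context(ctx, req, 0.9, p0)$mean_abs_amplitude, 0.5)
  expect_equal(update_context(ctx, req, 0.9, p1)$mean_abs_amplitude, 0.8)
  # constant-|d| stream converges geometrically at rate (1 - alpha)^t
  m <- 0.5
  for (i in 1:6) m <- update_context(context_state(m), req, 0.9, pa)$mean_abs_amplitude
  expect_equal(m - 0.8, (0.5 - 0.8) * 0.7^6, tolerance = 1e-12)
  upd <- update_context(ctx, req, 0.9, pa)
  expect_equal(upd$prev_click_eccentricity, 0.4)
  expect_equal(upd$prev_click_y, 0.9)
})

test_that("heuristic parameters are recoverable from clean simulated clicks", {
  # deterministic-core recovery sanity check at low noise, no motor stage
  cfg <- task_config("exp1")
  design <- generate_exp1_design(6, seed = 5)
  p <- strategy_params(hysteresis_weight = 0.4, amplitude_gain = 0.5,
                       noise_sd = 0.02)
  ds <- generate_dataset(design, "heuristic", params = p,
                         motor = motor_params(drag_sd = 0),
                         seed = 6, jitter_e0 = 0, jitter_k = 0)
  summ <- reduce_trials(ds$events, cfg)
  trials <- data.frame(summ,
                       displacement = required_displacement(summ$target_number, cfg),
                       click_y = summ$initial_click_y)
  rec <- recover_heuristic_params(trials, alpha = p$context_rate)
  expect_equal(rec$lambda, 0.4, tolerance = 0.1)
  expect_equal(rec$k, 0.5, tolerance = 0.1)
  expect_equal(rec$e0, 0.25, tolerance = 0.1)
})
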