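test_that("the first design is exhaustive and balanced within every block", {
  des <- generate_exp1_design(2, seed = 7)
  expect_equal(nrow(des), 2 * 8 * 48)
  for (p in 1:2) {
    dp <- des[des$participant == p, ]
    expect_equal(max(dp$block), 8)
    for (b in unique(dp$block)) {
      blk <- dp[dp$block == b, ]
      expect_equal(nrow(blk), 48)
      combos <- table(blk$target_number, blk$start_vertical, blk$start_side)
      expect_true(all(combos == 1))
    }
  }
  expect_true(all(des$target_number %in% c(1, 2, 3, 4, 6, 7, 8, 9)))
})

test_that("different seeds permute but never change the design's trial multiset", {
  a <- generate_exp1_design(1, seed = 1)
  b <- generate_exp1_design(1, seed = 2)
  expect_false(identical(a$target_number, b$target_number))
  key <- function(d) sort(paste(d$block, d$target_number, d$start_vertical, d$start_side))
  expect_identical(key(a), key(b))
})

test_that("the second design has 32-trial subblocks with the stated target sets", {
  des <- generate_exp2_design(3, seed = 9)
  sets <- list(low = c(13, 14, 16, 17), medium = c(12, 13, 17, 18),
               high = c(10, 13, 17, 20))
  for (p in 1:3) {
    dp <- des[des$participant == p, ]
    expect_setequal(unique(dp$eccentricity_condition), names(sets))
    for (b in unique(dp$block)) {
      blk <- dp[dp$block == b, ]
      type <- unique(blk$eccentricity_condition)
      expect_length(type, 1)
      for (s in 1:3) {
        sb <- blk[blk$subblock == s, ]
        expect_equal(nrow(sb), 32)
        expect_setequal(unique(sb$target_number), sets[[type]])
        counts <- table(sb$target_number, sb$start_side)
        expect_true(all(counts == 4))
      }
      # test targets appear in every block type, flagged as such
      expect_true(all(c(13, 17) %in% blk$target_number))
      expect_setequal(blk$condition[blk$target_number %in% c(13, 17)], "test")
      expect_setequal(blk$condition[!blk$target_number %in% c(13, 17)], "inducer")
    }
  }
})

test_that("noiseless trials complete in the drag count predicted by the path cost", {
  cfg <- task_config("exp1")
  motor0 <- motor_params(drag_sd = 0)
  spec <- list(participant = 1L, experiment = "exp1", block = 1L,
               subblock = NA_integer_, trial_index = 1L, target_number = 1L,
               start_vertical = 0, start_side = "right", condition = "none",
               eccentricity_condition = "none")
  # click inside the one-go set: exactly one click/release pair on the line
  log <- simulate_trial(spec, 0.9, cfg, motor0)
  expect_equal(sum(log$event_kind == "click" & abs(log$cursor_x - 0.5) <= 0.1), 1)
  # forced click at the centre for d = -0.8: two drags, 0.5 then 0.3
  log <- simulate_trial(spec, 0.5, cfg, motor0)
  line_releases <- log[log$event_kind == "release" & abs(log$cursor_x - 0.5) <= 0.1, ]
  expect_equal(nrow(line_releases), 2)
  expect_equal(diff(c(0, line_releases$line_offset)), c(-0.5, -0.3))
  # whole-design check against the cost model's drag counts
  for (t in setdiff(line_numbers(cfg), 5)) {
    d <- required_displacement(t, cfg)
    for (y in c(0.15, 0.5, 0.85)) {
      spec$target_number <- t
      log <- simulate_trial(spec, y, cfg, motor0)
      n_drags <- sum(log$event_kind == "click" & abs(log$cursor_x - 0.5) <= 0.1)
      expect_equal(n_drags, scroll_path_cost(y, d, cfg)$n_drags,
                   info = sprintf("target %d click %g", t, y))
    }
  }
})

test_that("every generated log satisfies the event-alternation and offset-sync invariants", {
  ds <- make_exp1_dataset(n = 2, seed = 21)
  cfg <- task_config("exp1")
  ev <- ds$events
  key <- paste(ev$participant, ev$block, ev$trial_index)
  for (tr in split(ev, key)) {
    tr <- tr[order(tr$event_index), ]
    kinds <- tr$event_kind
    expect_identical(kinds, rep(c("click", "release"), length(kinds) / 2))
    # line offset moves only within a drag, and by the drag's cursor change
    for (i in seq(1, nrow(tr) - 1, by = 2)) {
      if (abs(tr$cursor_x[i] - 0.5) <= cfg$line_half_width) {
        expect_equal(tr$line_offset[i + 1] - tr$line_offset[i],
                     tr$cursor_y[i + 1] - tr$cursor_y[i], tolerance = 1e-12)
      } else {
        expect_equal(tr$line_offset[i + 1], tr$line_offset[i])
      }
      if (i + 2 <= nrow(tr)) {
        expect_equal(tr$line_offset[i + 2], tr$line_offset[i + 1])
      }
    }
    # final offset aligns the target within tolerance
    d <- required_displacement(tr$target_number[1], cfg)
    expect_lte(abs(d - tr$line_offset[nrow(tr)]), cfg$target_tolerance + 1e-9)
  }
})

test_that("more drag noise produces more corrective submovements", {
  cfg <- task_config("exp1")
  design <- generate_exp1_design(2, seed = 31)
  frac_multi <- vapply(c(0.01, 0.08), function(sd) {
    ds <- generate_dataset(design, "heuristic",
                           params = strategy_params(noise_sd = 0),
                           motor = motor_params(drag_sd = sd), seed = 32)
    summ <- reduce_trials(ds$events, cfg)
    mean(summ$n_submovements > 1)
  }, numeric(1))
  expect_gt(frac_multi[2], frac_multi[1])
})

test_that("datasets are byte-identical for a repeated seed and differ across seeds", {
  design <- generate_exp1_design(1, seed = 4)[1:30, ]
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  ds1 <- generate_dataset(design, "heuristic", seed = 10)
  ds2 <- generate_dataset(design, "heuristic", seed = 10)
  ds3 <- generate_dataset(design, "heuristic", seed = 11)
  write_trial_logs(ds1$events, f1)
  write_trial_logs(ds2$events, f2)
  write_trial_logs(ds3$events, f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("hysteresis induces positive lag-1 autocorrelation of click eccentricity", {
  cfg <- task_config("exp1")
  design <- generate_exp1_design(4, seed = 41)
  ds <- generate_dataset(design, "heuristic",
                         params = strategy_params(hysteresis_weight = 0.6),
                         seed = 42, jitter_e0 = 0, jitter_k = 0)
  summ <- reduce_trials(ds$events, cfg)
  ecc <- abs(summ$initial_click_y - 0.5)
  same_block <- c(FALSE, summ$participant[-1] == summ$participant[-nrow(summ)] &
                    summ$block[-1] == summ$block[-nrow(summ)])
  r <- cor(ecc[same_block], ecc[which(same_block) - 1])
  expect_gt(r, 0.1)
})
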