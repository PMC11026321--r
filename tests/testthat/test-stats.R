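random_table <- function(n, a, b, sd_subj = 0.5, seed) {
  withr::with_seed(seed, {
    d <- expand.grid(participant = seq_len(n), A = factor(seq_len(a)),
                     B = factor(seq_len(b)))
    d$y <- rnorm(nrow(d)) + rep(rnorm(n, 0, sd_subj), a * b) +
      as.numeric(d$A) * rnorm(1) + as.numeric(d$B) * rnorm(1)
    d
  })
}

test_that("F statistics match the brute-force sums-of-squares oracle", {
  for (seed in 1:8) {
    n <- sample(3:8, 1)
    a <- sample(2:4, 1)
    b <- sample(2:5, 1)
    d <- random_table(n, a, b, seed = seed)
    res <- rm_anova_gg(d, "y", c("A", "B"))
    Y <- matrix(d$y[order(d$B, d$A, d$participant)], n) # A fastest
    orc <- oracle_rm_anova_2way(Y, a, b)
    expect_equal(res$F[res$effect == "A"], orc$F_A, tolerance = 1e-8)
    expect_equal(res$F[res$effect == "B"], orc$F_B, tolerance = 1e-8)
    expect_equal(res$F[res$effect == "A:B"], orc$F_AB, tolerance = 1e-8)
    # generalized eta squared against the same decomposition
    denom <- orc$ss[["S"]] + orc$ss[["AS"]] + orc$ss[["BS"]] + orc$ss[["ABS"]]
    expect_equal(res$eta_g[res$effect == "A"],
                 orc$ss[["A"]] / (orc$ss[["A"]] + denom), tolerance = 1e-8)
    # main-effect epsilon against the double-centred covariance formula
    MA <- sapply(seq_len(a), function(j) {
      rowMeans(Y[, seq(j, a * b, by = a), drop = FALSE])
    })
    expect_equal(res$epsilon[res$effect == "A"],
                 min(1, max(1 / (a - 1), oracle_gg_epsilon_1way(MA))),
                 tolerance = 1e-8)
  }
})

test_that("epsilon respects its lower and upper bounds on random tables", {
  for (seed in 1:300) {
    n <- 3 + seed %% 6
    a <- 2 + seed %% 3
    b <- 2 + (seed %/% 3) %% 3
    d <- random_table(n, a, b, seed = 1000 + seed)
    res <- rm_anova_gg(d, "y", c("A", "B"))
    for (i in seq_len(nrow(res))) {
      expect_gte(res$epsilon[i], 1 / res$df_num[i] - 1e-12)
      expect_lte(res$epsilon[i], 1 + 1e-12)
    }
    expect_true(all(res$F >= 0))
    expect_true(all(res$eta_g >= 0 & res$eta_g <= 1))
  }
})

test_that("two-level factors have epsilon 1 and flat effects give F = 0", {
  d <- random_table(5, 2, 3, seed = 77)
  res <- rm_anova_gg(d, "y", c("A", "B"))
  expect_equal(res$epsilon[res$effect == "A"], 1)
  d$y <- rep(rnorm(5), 6) # constant within participant
  res0 <- rm_anova_gg(d, "y", c("A", "B"))
  expect_equal(res0$F, rep(0, 3))
})

test_that("incomplete or single-participant tables are rejected", {
  d <- random_table(4, 2, 2, seed = 5)
  expect_error(rm_anova_gg(d[-1, ], "y", c("A", "B")), "missing cell")
  d1 <- random_table(1, 2, 2, seed = 5)
  expect_error(rm_anova_gg(d1, "y", c("A", "B")), "2 participants")
})

test_that("consecutive contrasts equal the hand-computed paired t", {
  d <- random_table(5, 3, 2, seed = 42)
  res <- consecutive_contrasts(d, "y", "A")
  expect_equal(nrow(res), 2)
  m <- with(d, tapply(y, list(participant, A), mean))
  for (i in 1:2) {
    diff <- m[, i + 1] - m[, i]
    t_hand <- mean(diff) / (sd(diff) / sqrt(5))
    expect_equal(res$t[i], t_hand, tolerance = 1e-12)
    expect_equal(res$d_z[i], t_hand / sqrt(5), tolerance = 1e-12)
    expect_equal(res$p[i], 2 * pt(abs(t_hand), 4, lower.tail = FALSE))
  }
  # identical level means: t = 0; constant nonzero difference: degenerate
  d$y <- rep(rnorm(5), 6)
  res0 <- consecutive_contrasts(d, "y", "A")
  expect_equal(res0$t, c(0, 0))
  d$y <- as.numeric(d$A)
  resd <- consecutive_contrasts(d, "y", "A")
  expect_true(all(resd$degenerate))
  expect_error(consecutive_contrasts(d[d$A == 1, ], "y", "A"), "2 levels")
})

test_that("hysteresis predictors code the previous click as specified", {
  cfg <- task_config("exp1")
  mk <- function(target, prev_click, dur = c(1, 1)) {
    data.frame(
      participant = 1, experiment = "exp1", block = 1, subblock = NA,
      trial_index = 1:2, target_number = c(5, target),
      start_vertical = c(0, 0.4), initial_click_y = c(prev_click, 0.5),
      trial_duration = dur, stringsAsFactors = FALSE
    )
  }
  # previous click at the top of the screen, current downward scroll -> +0.25
  p <- build_hysteresis_predictors(mk(3, prev_click = 1.0), cfg)
  expect_equal(p$prev_ecc_signed, 0.25)
  expect_equal(p$direction, -0.5)
  expect_equal(p$amplitude, -0.4)
  expect_equal(p$start_position, 0.4)
  # same previous click, upward scroll -> -0.25
  p <- build_hysteresis_predictors(mk(7, prev_click = 1.0), cfg)
  expect_equal(p$prev_ecc_signed, -0.25)
  expect_equal(p$direction, 0.5)
  # previous click at the centre, downward scroll -> -0.25 (0 - 0.25)
  p <- build_hysteresis_predictors(mk(3, prev_click = 0.5), cfg)
  expect_equal(p$prev_ecc_signed, -0.25)
  # slow predecessor or slow trial drops the row; first-of-block always drops
  expect_equal(nrow(build_hysteresis_predictors(mk(3, 1, dur = c(11, 1)), cfg)), 0)
  expect_equal(nrow(build_hysteresis_predictors(mk(3, 1, dur = c(1, 11)), cfg)), 0)
  df <- mk(3, 1)
  df$block <- c(1, 2)
  expect_equal(nrow(build_hysteresis_predictors(df, cfg)), 0)
})

test_that("the second design's predictors use the printed inducer-eccentricity codes", {
  cfg <- task_config("exp2")
  df <- data.frame(
    participant = 1, experiment = "exp2", block = 1, subblock = 1,
    trial_index = 1:4, target_number = c(13, 17, 13, 17),
    start_vertical = 0, initial_click_y = c(0.8, 0.2, 0.75, 0.3),
    trial_duration = 1,
    eccentricity_condition = c("low", "low", "high", "high"),
    stringsAsFactors = FALSE
  )
  p <- build_hysteresis_predictors(df, cfg)
  expect_equal(p$inducer_eccentricity, c(0.14, 0.71, 0.71))
  expect_false("start_position" %in% names(p))
})

test_that("the mixed model recovers known weights and flags degenerate designs", {
  # data generated from a pure linear model with random slopes, no hysteresis
  gen <- function(seed, n = 10, m = 60, beta = c(0.5, -0.3, 0.2)) {
    withr::with_seed(seed, {
      df <- data.frame(
        participant = rep(seq_len(n), each = m),
        x1 = rnorm(n * m), x2 = rnorm(n * m), x3 = rnorm(n * m)
      )
      slopes <- matrix(rnorm(n * 3, 0, 0.1), n)
      X <- as.matrix(df[, c("x1", "x2", "x3")])
      df$initial_click_y <- 0.5 +
        rowSums(X * sweep(slopes[df$participant, ], 2, beta, `+`)) +
        rnorm(n * m, 0, 0.05)
      df
    })
  }
  covered <- 0L
  n_sims <- 40
  for (s in seq_len(n_sims)) {
    fit <- suppressMessages(fit_mixed_model(gen(s)))
    ok <- abs(fit$fixed$beta_hat - c(0.5, -0.3, 0.2)) <= 2 * fit$fixed$se
    covered <- covered + sum(ok)
    if (s == 1) {
      expect_true(all(fit$fixed$vif >= 1))
      expect_true(all(fit$fixed$vif < 1.2)) # near-orthogonal by construction
      expect_lte(fit$r2_marginal, fit$r2_conditional)
      expect_gte(fit$r2_marginal, 0)
      expect_lte(fit$r2_conditional, 1)
    }
  }
  # per-weight 2-SE coverage across simulations
  expect_gte(covered / (3 * n_sims), 0.9)

  # rank-deficient fixed design is rejected with the collinear column named
  df <- gen(1)
  df$x3 <- df$x1 + df$x2
  expect_error(fit_mixed_model(df), "collinear")
})

test_that("predictors with no effect on the data get weights near zero", {
  withr::with_seed(8, {
    df <- data.frame(
      participant = rep(1:8, each = 50),
      x1 = rnorm(400), x2 = rnorm(400)
    )
    df$initial_click_y <- 0.5 + rnorm(400, 0, 0.05)
  })
  fit <- suppressMessages(fit_mixed_model(df))
  expect_true(all(abs(fit$fixed$beta_hat) < 3 * fit$fixed$se + 1e-3))
})
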