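#' Simulation-based power analysis for the first design
#'
#' Simulates experiments in which every participant's per-cell click
#' position equals the minimal-trajectory model prediction for that cell
#' plus independent Gaussian noise clipped to the screen (so data points of
#' individual participants are uncorrelated; one data point per cell and
#' participant). Each replicate runs the two-way within-participant ANOVA
#' (vertical start position x target number) with Greenhouse-Geisser
#' correction, and power per effect is the fraction of replicates with an
#' epsilon-corrected p below `alpha`.
#'
#' @param n_participants vector of sample sizes to probe.
#' @param noise_sd vector of per-cell noise SDs (screen-height units).
#' @param n_reps Monte-Carlo replicates per grid point.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param predictions optional cell-prediction table
#'   ([minimal_path_predictions()] format); a constant `click_y` column
#'   gives the null calibration.
#' @return A data frame with one row per (n, noise SD, effect): `power`
#'   (epsilon-corrected test), `power_uncorrected` (useful for calibration
#'   checks, since the corrected test is conservative when sphericity
#'   holds), `n_reps`, and the Monte-Carlo standard error
#'   `sqrt(power (1 - power) / n_reps)`.
#' @export
exp1_power_sim <- function(n_participants = c(18, 24, 30, 36),
                           noise_sd = c(0.20, 0.40),
                           n_reps = 1000, alpha = 0.05, seed = 1L,
                           predictions = NULL) {
  config <- task_config("exp1")
  if (is.null(predictions)) predictions <- minimal_path_predictions(config)
  # canonical cell order: target varies fastest within start position
  predictions <- predictions[order(predictions$start_vertical,
                                   predictions$target_number), ]
  pred <- predictions$click_y
  k <- c(
    length(unique(predictions$target_number)),
    length(unique(predictions$start_vertical))
  )
  within <- c("target_number", "start_vertical")
  p_cells <- length(pred)
  stopifnot(p_cells == prod(k))

  grid <- expand.grid(n = n_participants, noise_sd = noise_sd,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]
    sdn <- grid$noise_sd[g]
    withr::with_seed(derive_seed(seed, sprintf("exp1_power_%d_%g", n, sdn)), {
      hits <- matrix(0L, n_reps, 3)
      hits_unc <- matrix(0L, n_reps, 3)
      for (r in seq_len(n_reps)) {
        Y <- matrix(pred, n, p_cells, byrow = TRUE) +
          matrix(stats::rnorm(n * p_cells, 0, sdn), n, p_cells)
        Y <- clamp(Y, 0, 1)
        res <- rm_anova_core(Y, k, within)
        hits[r, ] <- as.integer(res$p < alpha)
        hits_unc[r, ] <- as.integer(res$p_uncorrected < alpha)
      }
      pw <- colMeans(hits)
      out[[g]] <- data.frame(
        n = n, noise_sd = sdn,
        effect = c("target_number", "start_vertical",
                   "target_number:start_vertical"),
        power = pw, power_uncorrected = colMeans(hits_unc), n_reps = n_reps,
        mc_se = sqrt(pw * (1 - pw) / n_reps)
      )
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulation-based power analysis for the second design
#'
#' Simulates test trials (the two targets common to all inducer-eccentricity
#' block types) from a surrogate trial model: each trial's click position is
#' drawn from a normal distribution centred at the target's typical click
#' position (symmetric about the screen centre at `surrogate_eccentricity`)
#' with trial-level SD `surrogate_sd`, plus a hypothetical inducer-
#' eccentricity effect that grows linearly within each block from zero to
#' `effect_size` per adjacent eccentricity level at block end, pushing
#' clicks away from the screen centre. Each replicate reduces trials to
#' participant cell means and runs the Greenhouse-Geisser corrected
#' repeated-measures ANOVA, both as target(2) x eccentricity(3) and as
#' target(2) x eccentricity(3) x subblock(3); power is the fraction of
#' replicates with a significant target-by-eccentricity interaction
#' (respectively three-way interaction).
#'
#' @param n_participants vector of sample sizes to probe.
#' @param effect_size vector of end-of-block click-eccentricity effects per
#'   adjacent inducer-eccentricity level (screen-height units).
#' @param n_reps Monte-Carlo replicates per grid point.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param surrogate_eccentricity distance of the test targets' typical click
#'   positions from the screen centre.
#' @param surrogate_sd trial-level click SD of the surrogate model.
#' @param trials_per_target_subblock test trials per target per subblock.
#' @return A data frame with one row per (n, effect size, effect term):
#'   `power`, `n_reps`, and the Monte-Carlo standard error.
#' @export
exp2_power_sim <- function(n_participants = c(6, 12, 18, 24, 30, 36, 42, 48),
                           effect_size = c(0.01, 0.03),
                           n_reps = 1000, alpha = 0.05, seed = 1L,
                           surrogate_eccentricity = 0.28,
                           surrogate_sd = 0.07,
                           trials_per_target_subblock = 8L) {
  n_sub <- 3L
  n_lev <- 3L
  trials_per_subblock <- 32L # 4 targets x 2 sides x 4 repetitions
  tpts <- trials_per_target_subblock
  # base means: one target clicked above centre, the other below
  base <- c(0.5 + surrogate_eccentricity, 0.5 - surrogate_eccentricity)
  away <- c(1, -1)       # direction that increases eccentricity
  lev_code <- c(-1, 0, 1) # low, medium, high (centred level codes)

  grid <- expand.grid(n = n_participants, effect = effect_size,
                      KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]
    eff <- grid$effect[g]
    withr::with_seed(derive_seed(seed, sprintf("exp2_power_%d_%g", n, eff)), {
      hits2 <- integer(n_reps)
      hits2_unc <- integer(n_reps)
      hits3 <- integer(n_reps)
      n_trials_cell <- tpts # per target x level x subblock
      for (r in seq_len(n_reps)) {
        # cell means per participant: target(2) x level(3) x subblock(3)
        M <- array(NA_real_, c(n, 2, n_lev, n_sub))
        for (i in seq_len(n)) {
          for (l in seq_len(n_lev)) {
            # positions of the test trials within the block's trial stream
            pos <- matrix(NA_integer_, n_sub, 2 * tpts)
            for (s in seq_len(n_sub)) {
              pos[s, ] <- (s - 1L) * trials_per_subblock +
                sort(sample.int(trials_per_subblock, 2 * tpts))
            }
            frac <- pos / (n_sub * trials_per_subblock)
            for (s in seq_len(n_sub)) {
              f_s <- sample(frac[s, ]) # assign positions to the two targets
              for (tg in 1:2) {
                f <- f_s[seq((tg - 1) * tpts + 1, tg * tpts)]
                y <- base[tg] + away[tg] * f * eff * lev_code[l] +
                  stats::rnorm(tpts, 0, surrogate_sd)
                M[i, tg, l, s] <- mean(clamp(y, 0, 1))
              }
            }
          }
        }
        # 2x3 ANOVA on means over subblocks (target fastest, then level)
        Y2 <- matrix(NA_real_, n, 2 * n_lev)
        for (l in seq_len(n_lev)) {
          for (tg in 1:2) {
            Y2[, (l - 1) * 2 + tg] <- rowMeans(M[, tg, l, , drop = FALSE], dims = 1)
          }
        }
        res2 <- rm_anova_core(Y2, c(2, n_lev), c("target", "eccentricity"))
        hits2[r] <- as.integer(
          res2$p[res2$effect == "target:eccentricity"] < alpha
        )
        hits2_unc[r] <- as.integer(
          res2$p_uncorrected[res2$effect == "target:eccentricity"] < alpha
        )
        # 2x3x3 ANOVA (target fastest, then level, then subblock)
        Y3 <- matrix(aperm(M, c(1, 2, 3, 4)), n, 2 * n_lev * n_sub)
        res3 <- rm_anova_core(Y3, c(2, n_lev, n_sub),
                              c("target", "eccentricity", "subblock"))
        hits3[r] <- as.integer(
          res3$p[res3$effect == "target:eccentricity:subblock"] < alpha
        )
      }
      pw <- c(mean(hits2), mean(hits3))
      out[[g]] <- data.frame(
        n = n, effect_size = eff,
        effect = c("target:eccentricity", "target:eccentricity:subblock"),
        power = pw,
        power_uncorrected = c(mean(hits2_unc), NA_real_),
        n_reps = n_reps,
        mc_se = sqrt(pw * (1 - pw) / n_reps)
      )
    })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
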