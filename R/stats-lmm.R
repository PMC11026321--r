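#' Build the motor-hysteresis predictor table from per-trial summaries
#'
#' For each trial that is not the first of its block and whose duration and
#' immediate predecessor's duration did not exceed 10 s, computes the
#' predictors of the hysteresis analysis of initial click positions:
#' \describe{
#'   \item{`prev_ecc_signed`}{eccentricity of the previous click
#'     (`|y_prev - 0.5|`), centred on zero by subtracting 0.25 (half its
#'     possible range), multiplied by +1 when the current trial requires a
#'     downward scroll and -1 when upward. A previous click at the top of
#'     the screen thus scores +0.25 before a downward scroll and -0.25
#'     before an upward one.}
#'   \item{`prev_click_y`}{previous initial vertical click position, centred
#'     on the screen centre (`y_prev - 0.5`) so that all predictors share
#'     screen-height units.}
#'   \item{`amplitude`}{signed displacement of the current scroll.}
#'   \item{`direction`}{-0.5 for downward, +0.5 for upward scrolls.}
#'   \item{`start_position`}{vertical start offset (-0.4, 0, 0.4); first
#'     design only.}
#'   \item{`inducer_eccentricity`}{distance of the block's inducer targets
#'     from the screen centre (0.14, 0.43, 0.71 for low/medium/high);
#'     second design only.}
#' }
#'
#' @param summaries per-trial summary table ([reduce_trials()]), ordered or
#'   orderable by participant, block, subblock, and trial index.
#' @param config the experiment's [task_config()].
#' @return A data frame with `participant`, the predictors appropriate for
#'   the experiment, and the response `initial_click_y`.
#' @export
build_hysteresis_predictors <- function(summaries, config) {
  need <- c("participant", "block", "trial_index", "target_number",
            "initial_click_y", "trial_duration")
  stopifnot(all(need %in% names(summaries)))
  experiment <- unique(summaries$experiment)
  stopifnot(length(experiment) == 1)
  sub <- summaries$subblock
  sub[is.na(sub)] <- 0L
  o <- order(summaries$participant, summaries$block, sub, summaries$trial_index)
  summaries <- summaries[o, , drop = FALSE]
  d <- required_displacement(summaries$target_number, config)
  prev_same <- c(FALSE,
                 summaries$participant[-1] == summaries$participant[-nrow(summaries)] &
                 summaries$block[-1] == summaries$block[-nrow(summaries)])
  prev_y <- c(NA, summaries$initial_click_y[-nrow(summaries)])
  prev_dur <- c(NA, summaries$trial_duration[-nrow(summaries)])
  keep <- prev_same & summaries$trial_duration <= 10 & prev_dur <= 10
  keep[is.na(keep)] <- FALSE

  out <- data.frame(
    participant = summaries$participant,
    initial_click_y = summaries$initial_click_y,
    prev_ecc_signed = (abs(prev_y - 0.5) - 0.25) * ifelse(d < 0, 1, -1),
    prev_click_y = prev_y - 0.5,
    amplitude = d,
    direction = ifelse(d < 0, -0.5, 0.5),
    stringsAsFactors = FALSE
  )
  if (experiment == "exp1") {
    out$start_position <- summaries$start_vertical
  } else {
    codes <- c(low = 0.14, medium = 0.43, high = 0.71)
    out$inducer_eccentricity <-
      unname(codes[summaries$eccentricity_condition])
  }
  out[keep, , drop = FALSE]
}

#' Hysteresis linear mixed model of initial click positions
#'
#' Fits `initial_click_y ~ predictors + (predictors | participant)` by REML
#' (lme4), with all predictors as fixed effects and by-participant random
#' slopes for all of them. If the unstructured random-effect covariance
#' yields a singular fit, the model is refitted with a diagonal covariance
#' (independent random slopes) and the fallback is noted. Per-predictor F
#' tests use Satterthwaite denominator degrees of freedom (lmerTest);
#' variance inflation factors are computed on the fixed-effect design
#' matrix; marginal and conditional R squared follow the variance-partition
#' formulation (fixed / fixed-plus-random variance over total).
#'
#' @param ptab predictor table from [build_hysteresis_predictors()].
#' @param predictors predictor column names; defaults to every column except
#'   the participant id and the response.
#' @return A list of class `mixed_model_result` with `fixed` (one row per
#'   fixed effect: `beta_hat`, `se`, `F`, `df_num`, `df_den`, `p`, `vif`),
#'   `r2_marginal`, `r2_conditional`, `singular_fallback`, and `model`.
#' @export
fit_mixed_model <- function(ptab, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(ptab), c("participant", "initial_click_y"))
  }
  stopifnot(length(predictors) >= 1,
            all(vapply(ptab[predictors], is.numeric, logical(1))))
  if (length(unique(ptab$participant)) < 2) {
    abort_domain("fit_mixed_model needs at least 2 participants")
  }
  X <- as.matrix(ptab[predictors])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_ix <- qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1
    abort_domain("rank-deficient fixed design; collinear column(s): %s",
                 paste(predictors[drop_ix], collapse = ", "))
  }
  rhs <- paste(predictors, collapse = " + ")
  form <- stats::as.formula(sprintf(
    "initial_click_y ~ %s + (%s | participant)", rhs, rhs
  ))
  fit <- lmerTest::lmer(form, data = ptab, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  singular_fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    singular_fallback <- TRUE
    form2 <- stats::as.formula(sprintf(
      "initial_click_y ~ %s + (%s || participant)", rhs, rhs
    ))
    fit <- lmerTest::lmer(form2, data = ptab, REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE))
    message("fit_mixed_model: unstructured random-slope covariance was singular; ",
            "refitted with independent (diagonal) random slopes")
  }

  co <- summary(fit)$coefficients
  an <- stats::anova(fit, type = 3)

  # VIFs on the (centred) fixed design
  vif <- if (length(predictors) == 1) {
    1
  } else {
    diag(solve(stats::cor(X)))
  }

  fixed <- data.frame(
    name = predictors,
    beta_hat = co[predictors, "Estimate"],
    se = co[predictors, "Std. Error"],
    F = an[predictors, "F value"],
    df_num = an[predictors, "NumDF"],
    df_den = an[predictors, "DenDF"],
    p = an[predictors, "Pr(>F)"],
    vif = unname(vif),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # variance-partition R2: fixed, random, residual components
  Xb <- stats::model.matrix(fit) %*% lme4::fixef(fit)
  var_f <- stats::var(as.vector(Xb))
  vc <- lme4::VarCorr(fit)
  mm <- stats::model.matrix(fit)
  var_r <- 0
  for (g in seq_along(vc)) {
    Sg <- as.matrix(vc[[g]])
    cols <- colnames(Sg)
    Xr <- mm[, cols, drop = FALSE]
    var_r <- var_r + mean(rowSums((Xr %*% Sg) * Xr))
  }
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  structure(
    list(
      fixed = fixed,
      r2_marginal = var_f / tot,
      r2_conditional = (var_f + var_r) / tot,
      singular_fallback = singular_fallback,
      model = fit
    ),
    class = "mixed_model_result"
  )
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Hysteresis linear mixed model (R2 marginal %.3f, conditional %.3f%s)\n",
              x$r2_marginal, x$r2_conditional,
              if (x$singular_fallback) "; diagonal random slopes" else ""))
  print(x$fixed, digits = 3)
  invisible(x)
}
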