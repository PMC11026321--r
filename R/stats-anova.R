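# orthonormal between-level contrast basis for a k-level factor
ortho_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# per-participant cell-mean matrix (participants x cells) in a canonical
# cell order (first factor varying fastest), plus factor level metadata
cell_matrix <- function(data, dv, within, id) {
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[id]] <- factor(data[[id]])
  levels_list <- lapply(data[within], levels)
  grid <- expand.grid(levels_list, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cell_key <- do.call(paste, c(grid, sep = "\r"))
  row_key <- do.call(paste, c(lapply(data[within], as.character), sep = "\r"))
  col <- match(row_key, cell_key)
  ids <- levels(data[[id]])
  n <- length(ids)
  p <- nrow(grid)
  Y <- matrix(NA_real_, n, p, dimnames = list(ids, cell_key))
  Y[cbind(match(data[[id]], ids), col)] <- data[[dv]]
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    lab <- paste0(ids[miss[, 1]], ": ",
                  gsub("\r", " x ", cell_key[miss[, 2]]))
    abort_domain("incomplete design; missing cell(s):\n  %s",
                 paste(utils::head(lab, 10), collapse = "\n  "))
  }
  if (nrow(data) != n * p) {
    abort_domain("more than one observation per participant-by-cell; aggregate first")
  }
  list(Y = Y, levels = levels_list)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-participant factorial ANOVA on a balanced table of
#' per-participant cell means (one observation per participant and cell).
#' Each effect is tested against its effect-by-participant interaction via
#' orthonormal-contrast projections; the Greenhouse-Geisser epsilon is
#' estimated from the covariance of the contrast scores, and degrees of
#' freedom and p values are epsilon-corrected. Effect sizes are generalized
#' eta squared with all within-participant variance components (participant
#' and every error stratum) in the denominator, the standard definition for
#' fully within designs.
#'
#' @param data long data frame of per-participant cell means.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-participant factor columns.
#' @param id participant-identifier column.
#' @return A data frame with one row per effect: `effect`, `df_num`,
#'   `df_den` (uncorrected), `epsilon`, `df_num_gg`, `df_den_gg`, `F`, `p`
#'   (epsilon-corrected), `p_uncorrected` (the corrected test is
#'   conservative when sphericity in fact holds), and `eta_g`.
#' @export
rm_anova_gg <- function(data, dv, within, id = "participant") {
  cm <- cell_matrix(data, dv, within, id)
  if (nrow(cm$Y) < 2) abort_domain("rm_anova_gg needs at least 2 participants")
  rm_anova_core(cm$Y, vapply(cm$levels, length, integer(1)), within)
}

# core computation on a participants-by-cells matrix whose columns follow
# the canonical order (first factor varying fastest); exposed internally so
# the power simulations can skip the data-frame reshaping
rm_anova_core <- function(Y, k, within) {
  n <- nrow(Y)
  m <- length(within)
  Cs <- lapply(k, ortho_contrasts)
  us <- lapply(k, function(l) matrix(1 / sqrt(l), l, 1))

  # kronecker over factors, slowest factor leftmost, so that the column
  # (first factor varies fastest) ordering of Y is respected
  kron_for <- function(in_effect) {
    mats <- lapply(seq_len(m), function(j) if (in_effect[j]) Cs[[j]] else us[[j]])
    Reduce(kronecker, rev(mats))
  }

  effects <- lapply(seq_len(m), function(sz) utils::combn(m, sz, simplify = FALSE))
  effects <- unlist(effects, recursive = FALSE)
  # sums of squares at rounding-noise level are treated as exact zeros
  zero_tol <- 1e-12 * max(mean(Y^2), .Machine$double.xmin)

  rows <- lapply(effects, function(ix) {
    in_effect <- seq_len(m) %in% ix
    Tm <- Y %*% kron_for(in_effect)
    d <- ncol(Tm)
    mu <- colMeans(Tm)
    ss_eff <- n * sum(mu^2)
    R <- sweep(Tm, 2, mu)
    ss_err <- sum(R^2)
    if (ss_eff < zero_tol) ss_eff <- 0
    if (ss_err < zero_tol) ss_err <- 0
    df1 <- d
    df2 <- d * (n - 1)
    Fv <- if (ss_err == 0) {
      if (ss_eff == 0) 0 else Inf
    } else {
      (ss_eff / df1) / (ss_err / df2)
    }
    S <- crossprod(R) / (n - 1)
    trS <- sum(diag(S))
    eps <- if (d == 1 || trS == 0) 1 else trS^2 / (d * sum(S * S))
    eps <- clamp(eps, 1 / d, 1)
    data.frame(
      effect = paste(within[ix], collapse = ":"),
      df_num = df1, df_den = df2, epsilon = eps,
      df_num_gg = eps * df1, df_den_gg = eps * df2,
      F = Fv,
      p = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
      p_uncorrected = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      ss_effect = ss_eff, ss_error = ss_err,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  t0 <- Y %*% Reduce(kronecker, rev(us))
  ss_subject <- sum((t0 - mean(t0))^2)
  denom_common <- ss_subject + sum(out$ss_error)
  out$eta_g <- out$ss_effect / (out$ss_effect + denom_common)
  rownames(out) <- NULL
  out
}

#' Consecutive paired contrasts along an ordered factor
#'
#' Paired t tests between each adjacent pair of factor levels on
#' per-participant marginal means (averaged over all other cells), with the
#' within-participant effect size `d_z = t / sqrt(n)`. A pair with constant
#' nonzero per-participant differences (zero variance) is flagged as
#' degenerate.
#'
#' @param data long data frame of per-participant cell means.
#' @param dv dependent-variable column.
#' @param factor_name ordered factor column to contrast.
#' @param id participant-identifier column.
#' @return A data frame with `level_lo`, `level_hi`, `t`, `df`, `p`, `d_z`,
#'   and `degenerate`.
#' @export
consecutive_contrasts <- function(data, dv, factor_name, id = "participant") {
  f <- factor(data[[factor_name]])
  lv <- levels(f)
  if (length(lv) < 2) abort_domain("factor '%s' needs at least 2 levels", factor_name)
  ids <- sort(unique(data[[id]]))
  n <- length(ids)
  if (n < 2) abort_domain("consecutive_contrasts needs at least 2 participants")
  marg <- stats::aggregate(data[[dv]],
                           by = list(id = data[[id]], level = f), FUN = mean)
  M <- matrix(NA_real_, n, length(lv), dimnames = list(ids, lv))
  M[cbind(match(marg$id, ids), match(marg$level, lv))] <- marg$x
  rows <- lapply(seq_len(length(lv) - 1), function(i) {
    diff <- M[, i + 1] - M[, i]
    md <- mean(diff)
    sdd <- stats::sd(diff)
    degenerate <- sdd == 0
    tv <- if (degenerate) {
      if (md == 0) 0 else Inf * sign(md)
    } else {
      md / (sdd / sqrt(n))
    }
    data.frame(
      level_lo = lv[i], level_hi = lv[i + 1],
      t = tv, df = n - 1,
      p = if (degenerate && md != 0) 0 else
        2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE),
      d_z = tv / sqrt(n), degenerate = degenerate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
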