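#' Canonical block HRF kernel for the condition regressors
#'
#' Unit-peak response model for one 2-s speech event: a gamma-variate
#' impulse response (shape 4, scale 1.1 s) convolved with a 2-s boxcar and
#' rescaled to peak 1. Its peak lies between 4.5 and 6 s after onset.
#'
#' @param dt_s sampling step (default 0.01 s).
#' @param duration_s kernel support (default 24 s).
#' @param block_s boxcar duration (default 2 s).
#' @param shape,scale gamma-variate parameters.
#' @return an `hrf_model`-like list with `time`, `kernel`, `dt_s`.
#' @export
block_hrf_kernel <- function(dt_s = 0.01, duration_s = 24, block_s = 2,
                             shape = 4, scale = 1.1) {
  t <- seq(0, duration_s, by = dt_s)
  g <- stats::dgamma(t, shape = shape, scale = scale)
  box <- rep(1, round(block_s / dt_s))
  k <- conv_open(g, box)[seq_along(t)] * dt_s
  structure(list(time = t, kernel = k / max(k), dt_s = dt_s,
                 duration_s = duration_s),
            class = "hrf_model")
}

# Per-run polynomial baseline columns (intercept, linear, quadratic).
baseline_columns <- function(n_vol_run, n_runs, degree = 2) {
  u <- seq(-1, 1, length.out = n_vol_run)
  polys <- cbind(1, stats::poly(u, degree))
  cols <- matrix(0, n_vol_run * n_runs, (degree + 1) * n_runs)
  nm <- character(ncol(cols))
  for (r in seq_len(n_runs)) {
    rows <- (r - 1) * n_vol_run + seq_len(n_vol_run)
    jj <- (r - 1) * (degree + 1) + seq_len(degree + 1)
    cols[rows, jj] <- polys
    nm[jj] <- paste0("run", r, "_poly", 0:degree)
  }
  colnames(cols) <- nm
  cols
}

new_design <- function(X, roles, basis, knots = NULL) {
  stopifnot(ncol(X) == length(roles))
  if (anyDuplicated(colnames(X))) stopf("design column labels must be unique")
  structure(
    list(X = X, roles = roles, basis = basis, knots = knots,
         n_model_regressors = sum(roles %in% c("condition", "motion"))),
    class = "glm_design"
  )
}

#' Canonical-block GLM design matrix
#'
#' One regressor per condition (the trial event train convolved with a
#' unit-peak block HRF, sampled at the TR) in the fixed order
#' AclearVclear, AclearVblur, AnoisyVclear, AnoisyVblur, plus six motion
#' nuisance regressors. `n_model_regressors` counts these ten; per-run
#' polynomial baseline columns (intercept/linear/quadratic) are additional
#' nuisance, excluded from the count by the usual convention.
#'
#' @param schedule an `event_schedule`.
#' @param motion_table volumes x 6 matrix of motion parameters.
#' @param hrf_kernel response kernel (default [block_hrf_kernel()]).
#' @param baseline_degree per-run polynomial degree (default 2).
#' @return a `glm_design`: `X`, `roles` (one of "condition", "motion",
#'   "baseline" per column), `basis`, `n_model_regressors`.
#' @export
build_block_design <- function(schedule, motion_table,
                               hrf_kernel = block_hrf_kernel(),
                               baseline_degree = 2) {
  n_vol <- schedule$volumes_per_run * schedule$n_runs
  motion_table <- as.matrix(motion_table)
  if (nrow(motion_table) != n_vol)
    stopf("motion table has %d rows; schedule implies %d volumes",
          nrow(motion_table), n_vol)
  cond <- condition_regressors(schedule, hrf_kernel)
  colnames(motion_table) <- paste0("motion", seq_len(ncol(motion_table)))
  base <- baseline_columns(schedule$volumes_per_run, schedule$n_runs,
                           baseline_degree)
  X <- cbind(cond, motion_table, base)
  roles <- c(rep("condition", ncol(cond)),
             rep("motion", ncol(motion_table)),
             rep("baseline", ncol(base)))
  new_design(X, roles, basis = "block")
}

#' Tent (FIR) GLM design matrix
#'
#' Piecewise-linear deconvolution basis: for each condition, one column per
#' knot lag, knots spaced one TR apart across the response window. The
#' response is estimated independently at each knot and constrained to zero
#' outside the window. Defaults give 11 knots over 0-15 s, hence
#' 4 x 11 = 44 condition columns plus 6 motion columns = 50 model
#' regressors.
#'
#' @param schedule an `event_schedule`.
#' @param motion_table volumes x 6 matrix.
#' @param window_s response window (default `c(0, 15)`; must start at 0).
#' @param n_knots number of knots (default 11; spacing must equal the TR).
#' @param baseline_degree per-run polynomial degree (default 2).
#' @return a `glm_design` with `knots` (lag times in s) and column labels
#'   `<condition>_t<lag>`.
#' @export
build_tent_design <- function(schedule, motion_table, window_s = c(0, 15),
                              n_knots = 11, baseline_degree = 2) {
  tr <- schedule$tr_s
  if (window_s[1] != 0) stopf("tent window must start at 0")
  spacing <- (window_s[2] - window_s[1]) / (n_knots - 1)
  if (abs(spacing - tr) > 1e-9)
    stopf("knot spacing %g s does not equal the TR (%g s)", spacing, tr)
  n_vol_run <- schedule$volumes_per_run
  n_vol <- n_vol_run * schedule$n_runs
  motion_table <- as.matrix(motion_table)
  if (nrow(motion_table) != n_vol)
    stopf("motion table has %d rows; schedule implies %d volumes",
          nrow(motion_table), n_vol)
  knots <- seq(window_s[1], window_s[2], by = tr)
  conds <- condition_levels()
  vol_t <- (seq_len(n_vol_run) - 1) * tr
  cond_cols <- matrix(0, n_vol, length(conds) * n_knots)
  nm <- character(ncol(cond_cols))
  j <- 0L
  for (cn in conds) {
    for (k in seq_len(n_knots)) {
      j <- j + 1L
      nm[j] <- sprintf("%s_t%g", cn, knots[k])
      for (r in seq_len(schedule$n_runs)) {
        rows <- (r - 1) * n_vol_run + seq_len(n_vol_run)
        on <- schedule$trials$onset_s[schedule$trials$run == r &
                                        schedule$trials$condition == cn]
        col <- numeric(n_vol_run)
        for (o in on) {
          lag <- vol_t - o - knots[k]
          col <- col + pmax(0, 1 - abs(lag) / tr)
        }
        cond_cols[rows, j] <- col
      }
    }
  }
  colnames(cond_cols) <- nm
  colnames(motion_table) <- paste0("motion", seq_len(ncol(motion_table)))
  base <- baseline_columns(n_vol_run, schedule$n_runs, baseline_degree)
  X <- cbind(cond_cols, motion_table, base)
  roles <- c(rep("condition", ncol(cond_cols)),
             rep("motion", ncol(motion_table)),
             rep("baseline", ncol(base)))
  new_design(X, roles, basis = "tent", knots = knots)
}

#' Scale voxel time series to percent-of-mean units
#'
#' Rescales each voxel's series to mean exactly 100, so that GLM betas read
#' directly as percent signal change. Voxels with non-positive mean are
#' masked (returned as NA columns) with a message.
#'
#' @param series volumes x voxels matrix (or a single series).
#' @return matrix of the same shape, each valid column with mean 100;
#'   attribute `masked` gives the masked column indices.
#' @export
scale_to_psc <- function(series) {
  x <- as.matrix(series)
  mu <- colMeans(x)
  bad <- unname(which(!is.finite(mu) | mu <= 0))
  if (length(bad) > 0) {
    message(sprintf("scale_to_psc: masked %d voxel(s) with non-positive mean",
                    length(bad)))
    x[, bad] <- NA_real_
  }
  ok <- setdiff(seq_len(ncol(x)), bad)
  x[, ok] <- sweep(x[, ok, drop = FALSE], 2, mu[ok] / 100, `/`)
  attr(x, "masked") <- bad
  x
}

#' Fit the voxelwise GLM
#'
#' Ordinary least squares for every voxel against a shared design matrix.
#' Returns betas, residual variance, and the omnibus F over the condition
#' columns (full model vs the model with all condition columns removed).
#' Voxels with zero residual variance are flagged; their t-statistics are
#' reported as `Inf` sentinels downstream.
#'
#' @param scaled_series volumes x voxels matrix (percent-signal units).
#' @param design a `glm_design` (full column rank).
#' @return Object of class `glm_fit`: `betas` (columns x voxels), `sigma2`,
#'   `df_resid`, `xtx_inv`, `omnibus_f`, `design`, `zero_resid` (logical).
#' @export
fit_glm <- function(scaled_series, design) {
  stopifnot(inherits(design, "glm_design"))
  Y <- as.matrix(scaled_series)
  X <- design$X
  if (nrow(Y) != nrow(X)) stopf("series and design have different lengths")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("design matrix is rank deficient")
  ok <- which(colSums(is.na(Y)) == 0)
  betas <- matrix(NA_real_, ncol(X), ncol(Y),
                  dimnames = list(colnames(X), colnames(Y)))
  betas[, ok] <- qr.coef(qrX, Y[, ok, drop = FALSE])
  resid <- Y
  resid[, ok] <- qr.resid(qrX, Y[, ok, drop = FALSE])
  df_resid <- nrow(X) - ncol(X)
  rss <- colSums(resid^2)
  sigma2 <- rss / df_resid
  zero_resid <- is.finite(sigma2) & sigma2 < .Machine$double.eps * 1e3

  cond_cols <- which(design$roles == "condition")
  q <- length(cond_cols)
  X0 <- X[, -cond_cols, drop = FALSE]
  qr0 <- qr(X0)
  rss0 <- rep(NA_real_, ncol(Y))
  rss0[ok] <- colSums(qr.resid(qr0, Y[, ok, drop = FALSE])^2)
  fstat <- ((rss0 - rss) / q) / pmax(sigma2, .Machine$double.xmin)
  fstat[zero_resid] <- Inf

  structure(
    list(betas = betas, sigma2 = sigma2, df_resid = df_resid,
         xtx_inv = chol2inv(qr.R(qrX)), omnibus_f = fstat,
         design = design, zero_resid = zero_resid),
    class = "glm_fit"
  )
}

#' Linear contrast t-statistics from a GLM fit
#'
#' @param fit a `glm_fit`.
#' @param weights numeric weight vector over the design columns (short
#'   vectors over the condition columns are padded with zeros elsewhere).
#' @return data.frame `estimate`, `t` per voxel (t is `Inf` for flagged
#'   zero-residual voxels).
#' @export
glm_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  X_cols <- nrow(fit$betas)
  cond_cols <- which(fit$design$roles == "condition")
  w <- numeric(X_cols)
  if (length(weights) == length(cond_cols)) {
    w[cond_cols] <- weights
  } else if (length(weights) == X_cols) {
    w <- weights
  } else {
    stopf("weights must cover the %d condition columns or all %d columns",
          length(cond_cols), X_cols)
  }
  est <- as.numeric(crossprod(w, fit$betas))
  var_w <- as.numeric(crossprod(w, fit$xtx_inv %*% w))
  tval <- est / sqrt(fit$sigma2 * var_w)
  tval[fit$zero_resid] <- Inf * sign(est[fit$zero_resid])
  data.frame(estimate = est, t = tval)
}

#' Clear-vs-noisy auditory contrast
#'
#' The study's main dependent measure: the general linear test with weights
#' exactly (+1, +1, -1, -1) over the condition regressors in the order
#' AclearVclear, AclearVblur, AnoisyVclear, AnoisyVblur -- positive where
#' responses to clear auditory speech exceed responses to noisy auditory
#' speech.
#'
#' @param fit a `glm_fit` from a block design (4 condition columns).
#' @return data.frame `estimate`, `t` per voxel.
#' @export
contrast_clear_vs_noisy <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  cond_cols <- which(fit$design$roles == "condition")
  if (length(cond_cols) != 4)
    stopf("clear-vs-noisy contrast needs a 4-condition block design")
  nm <- colnames(fit$design$X)[cond_cols]
  if (!identical(nm, condition_levels()))
    stopf("condition columns are not in the canonical order: %s",
          paste(nm, collapse = ", "))
  glm_contrast(fit, c(1, 1, -1, -1))
}

#' FIR response timecourse from a tent-design fit
#'
#' Returns the knot betas for one condition -- the deconvolved response
#' shape, in percent signal change at each lag.
#'
#' @param fit a `glm_fit` from [build_tent_design()].
#' @param condition condition label.
#' @param voxels optional voxel column indices (default all).
#' @return data.frame `time_s` (knot lags), plus one column per voxel of
#'   knot betas, and `mean` (across the selected voxels).
#' @export
estimate_hrf_tent <- function(fit, condition, voxels = NULL) {
  stopifnot(inherits(fit, "glm_fit"))
  if (fit$design$basis != "tent") stopf("not a tent-design fit")
  if (!condition %in% condition_levels()) stopf("unknown condition '%s'", condition)
  rows <- grep(sprintf("^%s_t", condition), rownames(fit$betas))
  if (length(rows) == 0) stopf("condition '%s' absent from the design", condition)
  b <- fit$betas[rows, , drop = FALSE]
  if (!is.null(voxels)) b <- b[, voxels, drop = FALSE]
  out <- data.frame(time_s = fit$design$knots)
  out$mean <- rowMeans(b, na.rm = TRUE)
  attr(out, "betas") <- b
  out
}

#' Localizer response amplitude from a long tent window
#'
#' For slow block localizer runs the response is deconvolved over 0-30 s
#' (21 knots at TR 1.5 s) and summarized as the mean of the betas at the
#' 4.5 s, 6 s and 7.5 s knots.
#'
#' @param fir data.frame with `time_s` and `mean` (e.g. from
#'   [estimate_hrf_tent()]), or a `glm_fit` plus `condition`.
#' @param condition condition label when `fir` is a `glm_fit`.
#' @param at_s knot times to average (default `c(4.5, 6, 7.5)`).
#' @return scalar amplitude (percent signal change).
#' @export
localizer_response <- function(fir, condition = NULL, at_s = c(4.5, 6, 7.5)) {
  if (inherits(fir, "glm_fit")) fir <- estimate_hrf_tent(fir, condition)
  idx <- match(at_s, fir$time_s)
  if (anyNA(idx))
    stopf("knot(s) %s missing from the tent window",
          paste(at_s[is.na(idx)], collapse = ", "))
  mean(fir$mean[idx])
}
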