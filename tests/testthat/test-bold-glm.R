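test_that("block design has 10 model regressors and a 4.5-6 s regressor peak", {
  fx <- small_bold_noiseless()
  d <- build_block_design(fx$sched, fx$ses$motion)
  expect_equal(d$n_model_regressors, 10)
  expect_equal(sum(d$roles == "condition"), 4)
  expect_equal(colnames(d$X)[d$roles == "condition"], condition_levels())
  # a single isolated trial: regressor argmax 4.5-6 s after onset
  s1 <- make_event_schedule(n_runs = 1, trials_per_condition_per_run = 1,
                            seed = 2)
  m1 <- matrix(0, s1$volumes_per_run, 6)
  d1 <- build_block_design(s1, m1)
  vol_t <- (seq_len(s1$volumes_per_run) - 1) * s1$tr_s
  for (cn in condition_levels()) {
    on <- s1$trials$onset_s[s1$trials$condition == cn]
    lag <- vol_t[which.max(d1$X[, cn])] - on
    expect_gte(lag, 4.5)
    expect_lte(lag, 6)
  }
  # motion-only design when there are no events
  s0 <- make_event_schedule(n_runs = 1, trials_per_condition_per_run = 0)
  d0 <- build_block_design(s0, matrix(0, 160, 6))
  expect_equal(sum(d0$roles == "condition"), 4)   # columns exist but are zero
  expect_true(all(d0$X[, d0$roles == "condition"] == 0))
  expect_error(build_block_design(fx$sched, fx$ses$motion[-1, ]), "rows")
})

test_that("tent design realizes 11 knots over 0-15 s and 50 model regressors", {
  fx <- small_bold_noiseless()
  d <- build_tent_design(fx$sched, fx$ses$motion)
  expect_equal(d$n_model_regressors, 50)
  expect_equal(sum(d$roles == "condition"), 44)
  expect_equal(d$knots, seq(0, 15, by = 1.5))
  expect_length(d$knots, 11)
  # 21 knots for the 0-30 s localizer window
  d30 <- build_tent_design(fx$sched, fx$ses$motion, window_s = c(0, 30),
                           n_knots = 21)
  expect_length(d30$knots, 21)
  expect_error(build_tent_design(fx$sched, fx$ses$motion, n_knots = 12),
               "TR")
  # grid-aligned single trial: each tent column is a unit impulse at its lag
  s1 <- make_event_schedule(n_runs = 1, trials_per_condition_per_run = 1,
                            seed = 2)
  d1 <- build_tent_design(s1, matrix(0, 160, 6))
  vol_t <- (seq_len(160) - 1) * 1.5
  cn <- "AnoisyVclear"
  on <- s1$trials$onset_s[s1$trials$condition == cn]
  for (k in c(0, 7.5, 15)) {
    col <- d1$X[, sprintf("%s_t%g", cn, k)]
    expect_equal(sum(col), 1)
    expect_equal(vol_t[which.max(col)], on + k)
  }
})

test_that("percent-signal scaling normalizes to mean 100 and is idempotent", {
  fx <- small_bold_noisy()
  psc <- scale_to_psc(fx$ses$series)
  expect_equal(unname(colMeans(psc)), rep(100, ncol(psc)), tolerance = 1e-12)
  expect_equal(scale_to_psc(psc), psc, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(as.numeric(scale_to_psc(matrix(200, 10, 1))), rep(100, 10))
  # scaled beta = raw beta x 100 / raw mean (algebraic identity)
  y <- fx$ses$series[, 5]
  x <- seq_along(y) / length(y)
  b_raw <- coef(lm(y ~ x))[2]
  b_scaled <- coef(lm(scale_to_psc(y) ~ x))[2]
  expect_equal(unname(b_scaled), unname(b_raw * 100 / mean(y)), tolerance = 1e-10)
  # non-positive voxels are masked, not propagated
  bad <- cbind(y, -y)
  expect_message(out <- scale_to_psc(bad), "masked 1")
  expect_true(all(is.na(out[, 2])))
  expect_equal(attr(out, "masked"), 2L)
})

test_that("OLS betas and contrasts match the pseudoinverse oracle", {
  set.seed(7)
  n <- 120
  X <- cbind(matrix(rnorm(n * 4), n, 4), matrix(rnorm(n * 3), n, 3), 1)
  colnames(X) <- c(condition_levels(), paste0("motion", 1:3), "intercept")
  design <- stgboundary:::new_design(
    X, c(rep("condition", 4), rep("motion", 3), "baseline"), "block")
  Y <- matrix(rnorm(n * 6), n, 6)
  fit <- fit_glm(Y, design)
  b_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_equal(unname(fit$betas), unname(b_oracle), tolerance = 1e-8)
  # contrast t via the direct formula
  w <- c(1, 1, -1, -1, 0, 0, 0, 0)
  con <- glm_contrast(fit, c(1, 1, -1, -1))
  for (v in 1:3) {
    resid <- Y[, v] - X %*% b_oracle[, v]
    s2 <- sum(resid^2) / (n - ncol(X))
    t_oracle <- sum(w * b_oracle[, v]) /
      sqrt(s2 * t(w) %*% solve(t(X) %*% X) %*% w)
    expect_equal(con$t[v], as.numeric(t_oracle), tolerance = 1e-8)
  }
  # omnibus F via explicit full-vs-reduced RSS
  X0 <- X[, -(1:4)]
  for (v in 1:2) {
    rss1 <- sum(lm.fit(X, Y[, v])$residuals^2)
    rss0 <- sum(lm.fit(X0, Y[, v])$residuals^2)
    f_oracle <- ((rss0 - rss1) / 4) / (rss1 / (n - ncol(X)))
    expect_equal(fit$omnibus_f[v], f_oracle, tolerance = 1e-8)
  }
  expect_error(fit_glm(Y, stgboundary:::new_design(
    cbind(X, X[, 1] + X[, 2]), c(design$roles, "motion"), "block")),
    "rank")
})

test_that("null-data contrast t follows the Student reference distribution", {
  fx <- small_bold_noiseless()
  d <- build_block_design(fx$sched, fx$ses$motion)
  set.seed(8)
  n_vox <- 400
  Y <- matrix(rnorm(nrow(d$X) * n_vox), nrow(d$X), n_vox)
  fit <- fit_glm(Y, d)
  tt <- contrast_clear_vs_noisy(fit)$t
  ks <- suppressWarnings(ks.test(tt, "pt", df = fit$df_resid))
  expect_gt(ks$p.value, 0.01)
})

test_that("contrast weighting is symmetric on equal betas", {
  set.seed(9)
  n <- 160
  sched <- make_event_schedule(n_runs = 1, seed = 3)
  d <- build_block_design(sched, matrix(rnorm(n * 6, sd = 0.01), n, 6))
  cond <- d$X[, d$roles == "condition"]
  y <- rowSums(cond) * 0.5 + rnorm(n, sd = 1e-8) + 100
  fit <- fit_glm(matrix(y), d)
  est_sum <- glm_contrast(fit, c(1, 1, 1, 1))$estimate
  est_dif <- contrast_clear_vs_noisy(fit)$estimate
  expect_equal(est_sum, 4 * 0.5, tolerance = 1e-4)
  expect_equal(est_dif, 0, tolerance = 1e-6)
})

test_that("the +1 +1 -1 -1 contrast on printed amplitudes gives +0.26", {
  # betas (0.37, 0.37, 0.24, 0.24): clear-pair sum minus noisy-pair sum
  expect_equal(sum(c(1, 1, -1, -1) * c(0.37, 0.37, 0.24, 0.24)), 0.26)
})

test_that("noiseless simulation recovers generating amplitudes through the GLM", {
  fx <- small_bold_noiseless()
  psc <- scale_to_psc(fx$ses$series)
  # the generating design: condition regressors built from the truth kernel
  d <- build_block_design(fx$sched, fx$ses$motion, hrf_kernel = fx$ses$kernel)
  fit <- fit_glm(psc, d)
  on <- which(fx$ses$voxels$on_gyrus)
  b <- fit$betas[condition_levels(), on]
  truth <- t(fx$ses$amplitudes[on, ])
  expect_equal(unname(b), unname(truth), tolerance = 0.01)
  # and the normal-equations oracle agrees to numerical precision
  b_oracle <- qr.solve(d$X, psc[, on[1:5]])
  expect_equal(unname(fit$betas[, on[1:5]]), unname(b_oracle), tolerance = 1e-8)
})

test_that("tent fit recovers a response generated from the tent basis exactly", {
  fx <- small_bold_noiseless()
  d <- build_tent_design(fx$sched, fx$ses$motion)
  set.seed(10)
  beta_true <- rnorm(ncol(d$X), sd = 0.3)
  y <- as.numeric(d$X %*% beta_true) + 100
  fit <- fit_glm(matrix(y), d)
  expect_equal(unname(fit$betas[, 1])[seq_len(44)], beta_true[seq_len(44)],
               tolerance = 1e-6)
  fir <- estimate_hrf_tent(fit, "AclearVblur")
  expect_equal(fir$mean,
               beta_true[grep("^AclearVblur_t", colnames(d$X))],
               tolerance = 1e-6)
  expect_error(estimate_hrf_tent(fit, "NoSuchCondition"), "unknown|absent")
})

test_that("FIR from the noiseless simulation equals kernel x amplitude at the knots", {
  fx <- small_bold_noiseless()
  psc <- scale_to_psc(fx$ses$series)
  fit <- fit_glm(psc, build_tent_design(fx$sched, fx$ses$motion))
  ant <- which(fx$ses$voxels$on_gyrus & fx$ses$voxels$position_mm < 38)
  fir <- estimate_hrf_tent(fit, "AclearVclear", voxels = ant)
  amp <- mean(fx$ses$amplitudes[ant, "AclearVclear"])
  truth <- amp * hrf_at(fx$ses$kernel, fir$time_s)
  expect_equal(fir$mean, truth, tolerance = 0.03)
  # the onset knot is near zero (the kernel starts at 0; the only residue is
  # the generating response beyond the 15 s window, absent from the basis)
  expect_lt(abs(fir$mean[1]), 0.01)
})

test_that("localizer amplitude averages the 4.5, 6 and 7.5 s knot betas", {
  fir <- data.frame(time_s = seq(0, 30, by = 1.5), mean = 1)
  expect_equal(localizer_response(fir), 1)
  fir$mean <- 0
  fir$mean[fir$time_s == 4.5] <- 0.3
  fir$mean[fir$time_s == 6] <- 0.6
  fir$mean[fir$time_s == 7.5] <- 0.3
  expect_equal(localizer_response(fir), 0.4)
  expect_error(localizer_response(data.frame(time_s = c(0, 3), mean = 0:1)),
               "missing")
})
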