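test_that("volume-to-surface sampling averages 15 thickness steps", {
  g <- make_gyrus()
  vox <- expand.grid(position_mm = seq(1, 99, by = 2), depth = 1:3)
  vox$on_gyrus <- TRUE
  # uniform volume: every node gets the constant
  out <- sample_volume_to_surface(rep(4.2, nrow(vox)), vox, g)
  expect_equal(out$value, rep(4.2, length(g$nodes)))
  # gradient along thickness: node value = mean of the 15 nearest-voxel samples
  vals <- vox$depth * 1.5
  out <- sample_volume_to_surface(vals, vox, g, f_steps = 15)
  steps <- (1:15 - 0.5) / 15
  d_idx <- pmin(3, pmax(1, ceiling(steps * 3)))
  expect_equal(out$value[1], mean(d_idx * 1.5))
  expect_equal(out$value, rep(mean(d_idx * 1.5), length(g$nodes)))
})

test_that("binning reproduces brute-force bin means and marks empty bins", {
  set.seed(11)
  pos <- runif(300, 0, 100)
  val <- rnorm(300)
  prof <- bin_profile(val, pos, length_mm = 100)
  expect_equal(nrow(prof), 100)
  for (k in c(1, 37, 100)) {
    members <- val[pos >= prof$bin_start_mm[k] & pos < prof$bin_end_mm[k] |
                     (k == 100 & pos == 100)]
    if (length(members) == 0) {
      expect_true(is.na(prof$mean_t[k]))
    } else {
      expect_equal(prof$mean_t[k], mean(members))
    }
  }
  # constant input gives constant bin means
  prof_c <- bin_profile(rep(2, 300), pos, length_mm = 100)
  expect_true(all(prof_c$mean_t[prof_c$n_nodes > 0] == 2))
  expect_error(bin_profile(numeric(), numeric(), length_mm = 100), "no nodes")
})

test_that("first posterior-third zero crossing is located, with edge conventions", {
  mk <- function(v) bin_profile(v, 0:99 + 0.5, length_mm = 100)
  # step profile: +1 before 70 mm, -1 after
  v <- ifelse(0:99 < 70, 1, -1)
  expect_equal(find_functional_boundary(mk(v)), 70)
  # strictly positive profile: no crossing
  expect_true(is.na(find_functional_boundary(mk(rep(1, 100)))))
  # crossing anterior to the posterior third is ignored; next one found
  v2 <- c(rep(1, 40), rep(-1, 20), rep(1, 20), rep(-1, 20))  # crossings at 40, 60, 80
  expect_equal(find_functional_boundary(mk(v2)), 80)
  # an exact-zero bin counts as the crossing and is reported
  v3 <- rep(1, 100); v3[71] <- 0; v3[72:100] <- -1
  expect_equal(find_functional_boundary(mk(v3)), 70)
  # empty bins are skipped: comparison against nearest preceding non-empty bin
  pos <- c(seq(0.5, 66.5, by = 1), 80.5)
  val <- c(rep(1, 67), -1)
  expect_equal(find_functional_boundary(bin_profile(val, pos, length_mm = 100)),
               80)
})

test_that("boundary estimate combines functional and anatomical coordinates", {
  g <- make_gyrus()
  v <- ifelse(0:99 < 68, 1, -1)
  prof <- bin_profile(v, 0:99 + 0.5, length_mm = 100)
  est <- estimate_boundary(prof, g)
  expect_equal(est$functional_mm, 68)
  expect_equal(est$functional_y, -28)
  expect_equal(est$anatomical_y, -30)
  expect_equal(est$distance_mm, 2)
})

test_that("ROI membership equals the brute-force position/threshold filter", {
  fx <- small_bold_noisy()
  psc <- scale_to_psc(fx$ses$series)
  fit <- fit_glm(psc, build_block_design(fx$sched, fx$ses$motion))
  b <- 68
  rois <- define_rois(b, fx$ses$voxels, fit$omnibus_f)
  p <- fx$ses$voxels$position_mm
  ant_brute <- which(fx$ses$voxels$on_gyrus & fit$omnibus_f > 5 &
                       p >= b - 30 & p < b)
  post_brute <- which(fx$ses$voxels$on_gyrus & fit$omnibus_f > 5 &
                        p >= b & p <= b + 15)
  expect_equal(rois$anterior, ant_brute)
  expect_equal(rois$posterior, post_brute)
  # extents honored exactly at the edges
  vox <- data.frame(position_mm = c(b - 31, b - 30, b + 15, b + 16),
                    on_gyrus = TRUE)
  r2 <- define_rois(b, vox, rep(10, 4))
  expect_equal(r2$anterior, 2L)
  expect_equal(r2$posterior, 3L)
  # all-subthreshold F empties both ROIs
  r3 <- define_rois(b, vox, rep(1, 4))
  expect_true(r3$empty)
  expect_warning(define_rois(5, vox, rep(10, 4)), "clipped")
})

test_that("zero transition width and zero noise localize the boundary exactly", {
  g <- make_gyrus()
  sched <- make_event_schedule(n_runs = 2, seed = 31)
  p <- noiseless_params()
  p$transition_width_mm <- 1e-6
  ses <- simulate_bold(g, sched, params = p, seed = 32, n_off_gyrus = 2)
  psc <- scale_to_psc(ses$series)
  fit <- fit_glm(psc, build_block_design(sched, ses$motion))
  con <- contrast_clear_vs_noisy(fit)
  nodes <- sample_volume_to_surface(con$t, ses$voxels, g)
  prof <- bin_profile(nodes$value, nodes$position_mm, length_mm = g$length_mm)
  est <- find_functional_boundary(prof)
  # the crossing bin contains the planted boundary up to voxel sampling width
  expect_lte(abs(est - g$true_boundary_mm), 2)
})

test_that("group boundary report summarizes hemispheres and compares positions", {
  g <- make_gyrus()
  mk_est <- function(f_mm) {
    v <- ifelse(0:99 < f_mm, 1, -1)
    estimate_boundary(bin_profile(v, 0:99 + 0.5, length_mm = 100), g)
  }
  # constructed +/-2 mm alternating offsets around the landmark
  ests <- lapply(c(72, 68, 72, 68), mk_est)
  rep <- boundary_report(ests)
  expect_equal(rep$mean_distance_mm, 2)
  expect_equal(rep$mean_functional_y, mean(c(-32, -28, -32, -28)))
  expect_equal(rep$mean_anatomical_y, -30)
  expect_false(rep$comparison$degenerate)
  # identical functional and anatomical boundaries: degenerate, "no difference"
  same <- lapply(c(70, 70), mk_est)
  rep2 <- boundary_report(same)
  expect_true(rep2$comparison$degenerate)
  expect_equal(rep2$comparison$status, "no difference")
  # single hemisphere: descriptive only
  rep3 <- boundary_report(list(mk_est(68)))
  expect_equal(rep3$comparison$status, "descriptive-only")
})
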