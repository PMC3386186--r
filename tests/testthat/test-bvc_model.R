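test_that("BVC activation is a weighted product of Gaussian tunings", {
  tu <- bvc_tuning(10, 90)
  peak <- bvc_activation(tu, data.frame(alpha = 90, dist = 10, weight = 1))
  expect_equal(peak, 1)
  # opposite direction with narrow angular tuning: essentially silent
  expect_lt(bvc_activation(tu, data.frame(alpha = 270, dist = 10, weight = 1)),
            1e-10)
  # linearity: two half-weight copies equal one full estimate
  est2 <- data.frame(alpha = c(90, 90), dist = c(10, 10), weight = c(0.5, 0.5))
  expect_equal(bvc_activation(tu, est2), peak)
  # angular wrap: 5 deg and 355 deg are symmetric around 0
  tu0 <- bvc_tuning(10, 0)
  expect_equal(bvc_activation(tu0, data.frame(alpha = 5, dist = 10, weight = 1)),
               bvc_activation(tu0, data.frame(alpha = 355, dist = 10, weight = 1)))
  expect_equal(bvc_activation(tu, data.frame(alpha = numeric(0),
                                             dist = numeric(0),
                                             weight = numeric(0))), 0)
  # distance tuning width grows with preferred distance
  expect_gt(bvc_tuning(25, 0)$sigma_rad, bvc_tuning(2, 0)$sigma_rad)
})

test_that("rate maps normalize by occupancy", {
  arena <- build_arena("square_box")
  x <- runif(500, -30, 30); z <- runif(500, -30, 30)
  rm <- accumulate_rate_map(x, z, rep(1, 500), arena, bin_size = 10)
  r <- rm$rate[[1]]
  expect_true(all(r[rm$occupancy > 0] == 1))
  expect_true(all(is.na(r[rm$occupancy == 0])))
  expect_error(accumulate_rate_map(x, z, rep(1, 500), arena, bin_size = 100),
               "bin size")
})

test_that("ground-truth-driven battery fires at the predicted loci", {
  arena <- build_arena("square_box")
  set.seed(11)
  tj <- generate_trajectory(arena, recorded_velocity_stats("square"),
                            duration_s = 600)
  rows <- seq(1, nrow(tj), by = 10)
  batt <- bvc_battery()
  act <- t(vapply(rows, function(i) {
    est <- gt_boundary_estimates(arena, eye_pose(tj$x[i], 3.5, tj$z[i]))
    bvc_activation(batt, est)
  }, numeric(length(batt))))
  colnames(act) <- names(batt)
  rm <- accumulate_rate_map(tj$x[rows], tj$z[rows], act, arena, bin_size = 2)
  # predicted locus: preferred distance in from the wall of the preferred
  # direction (direction 0 = +z/north, 90 = +x/east)
  pred <- function(dir, d) switch(as.character(dir),
    "0"   = c(NA, 31 - d), "90"  = c(31 - d, NA),
    "180" = c(NA, -31 + d), "270" = c(-31 + d, NA))
  for (dir in c(0, 90, 180, 270)) for (d in c(2, 10, 25)) {
    cell <- sprintf("%ddeg_%gcm", dir, d)
    am <- rate_map_argmax(rm, cell, smooth = 1)
    p <- pred(dir, d)
    if (!is.na(p[1])) expect_lt(abs(am["x"] - p[1]), 2 * 2 + 1e-9)
    if (!is.na(p[2])) expect_lt(abs(am["z"] - p[2]), 2 * 2 + 1e-9)
  }
  # diagonal cells fire toward the corresponding corner wall
  am <- rate_map_argmax(rm, "45deg_10cm", smooth = 1)
  expect_gt(am["x"] + am["z"], 20)
})

test_that("cells respond to interior walls of their preferred direction", {
  arena <- build_arena("square_box_interior_wall")
  # east-tuned cell at 2 cm: fires near the east outer wall AND just west
  # of the interior wall (which has wall surface facing west at x = 0)
  xs <- seq(-29, 29, by = 2); z <- 0
  tu <- bvc_tuning(2, 90)
  act <- vapply(xs, function(x) {
    bvc_activation(tu, gt_boundary_estimates(arena, eye_pose(x, 3.5, z)))
  }, numeric(1))
  # local peaks near x = 29 (outer) and x = -2 (interior)
  expect_gt(act[which.min(abs(xs - 29))], 0.5 * max(act))
  expect_gt(act[which.min(abs(xs + 3))], 0.5 * max(act))
  # far from both walls the cell is quiet
  expect_lt(act[which.min(abs(xs + 20))], 0.4 * max(act))
})

test_that("flow-driven rate maps correlate with ground-truth-driven maps", {
  arena <- build_arena("square_box")
  cam <- spherical_camera()
  bank <- template_bank(cam)
  set.seed(21)
  tj <- generate_trajectory(arena, recorded_velocity_stats("square"),
                            duration_s = 240)
  run <- boundary_error_run(arena, tj, bank, subsample = 10,
                            keep_estimates = TRUE)
  rows <- seq_len(nrow(run$frames))
  batt <- bvc_battery()
  act_flow <- t(vapply(rows, function(i) {
    est <- run$estimates[run$estimates$frame == i, , drop = FALSE]
    bvc_activation(batt, est)
  }, numeric(length(batt))))
  act_gt <- t(vapply(rows, function(i) {
    est <- gt_boundary_estimates(arena,
                                 eye_pose(run$frames$x[i], 3.5, run$frames$z[i]))
    bvc_activation(batt, est)
  }, numeric(length(batt))))
  colnames(act_flow) <- colnames(act_gt) <- names(batt)
  rf <- accumulate_rate_map(run$frames$x, run$frames$z, act_flow, arena,
                            bin_size = 4)
  rg <- accumulate_rate_map(run$frames$x, run$frames$z, act_gt, arena,
                            bin_size = 4)
  # in a square box only wall-normal-aligned (cardinal) cells carry signal;
  # diagonal cells are silent in both models, where a Pearson r is
  # undefined noise -- correlate the responsive cells, require silence of
  # the rest
  gt_peak <- vapply(rg$rate, max, numeric(1), na.rm = TRUE)
  responsive <- names(batt)[gt_peak > 0.05 * max(gt_peak)]
  expect_gte(length(responsive), 12)
  cors <- vapply(responsive, function(cell) {
    a <- rf$rate[[cell]]; b <- rg$rate[[cell]]
    ok <- is.finite(a) & is.finite(b)
    suppressWarnings(cor(a[ok], b[ok]))
  }, numeric(1))
  expect_gt(mean(cors > 0.5), 0.8)
  expect_gt(median(cors), 0.5)
  silent <- setdiff(names(batt), responsive)
  mean_act <- vapply(rf$rate, function(m) mean(m, na.rm = TRUE), numeric(1))
  expect_lt(max(mean_act[silent]), 0.3 * max(mean_act[responsive]))
})

test_that("platform cells fire at the drop-off at their preferred range", {
  plat <- build_arena("circular_platform")
  cam <- spherical_camera(400, 200)
  # poses approaching the rim from the center along +x, heading east
  xs <- seq(0, 36, by = 3)
  tu <- bvc_tuning(10, 90)  # east, 10 cm
  act <- vapply(xs, function(x) {
    pose <- eye_pose(x, 3.5, 0, phi = 90)
    fl <- make_flow(plat, pose, self_motion(19, 0), cam)
    est <- dropoff_estimates(detect_dropoff(fl), pose)
    bvc_activation(tu, est)
  }, numeric(1))
  # strongest response when the rim lies ~10 cm east, i.e. x ~ 29.5
  expect_equal(xs[which.max(act)], 30, tolerance = 4)
  expect_gt(max(act), 5 * act[1])
})
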