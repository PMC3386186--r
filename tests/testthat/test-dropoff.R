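test_that("an unbroken ground plane yields no valid detections", {
  cam <- spherical_camera(200, 100)
  plat <- build_arena("circular_platform", diameter = 4000)
  pose <- eye_pose(0, 3.5, 0)
  fl <- make_flow(plat, pose, self_motion(19, 0), cam)
  det <- detect_dropoff(fl)
  # the only speed structure is the smooth 1/D gradient; responses stay at
  # the noise floor relative to a genuine discontinuity
  plat2 <- build_arena("circular_platform")
  fl2 <- make_flow(plat2, pose, self_motion(19, 0), cam)
  det2 <- detect_dropoff(fl2)
  expect_gt(max(det2$response), 5 * max(det$response))
  expect_gt(sum(det2$valid), 0)
})

test_that("a synthetic speed step is detected exactly at its row", {
  cam <- spherical_camera(200, 100)
  fl <- make_flow(build_arena("circular_platform", diameter = 4000),
                  eye_pose(0, 3.5, 0), self_motion(19, 0), cam)
  # overwrite with a hard step in elevation flow speed at a known row
  sp <- matrix(0, cam$n_el, cam$n_az)
  step_row <- 37
  sp[1:step_row, ] <- 50
  fl$dvarphi <- as.vector(sp); fl$dtheta <- 0 * fl$dtheta
  fl$label <- factor(rep("ground", length(fl$dvarphi)),
                     levels = c("ground", "wall", "none"))
  det <- detect_dropoff(fl)
  expect_true(all(det$elevation[det$valid] == cam$el[step_row]))
})

test_that("drop-off distances round-trip through the projection", {
  set.seed(12)
  n <- 1000
  range_true <- runif(n, 2, 300)
  theta <- runif(n, -110, 110)
  h <- 3.5
  elev <- -atan2(h, range_true) * 180 / pi
  back <- dropoff_distance(elev, theta, h = h)
  expect_lt(max(abs(back - range_true)), 1e-6)
  expect_true(is.na(dropoff_distance(5, 0, h = h)))   # above horizon
  expect_equal(dropoff_distance(-45, 0, h = 3.5), 3.5)
})

test_that("tilt is equivalent to rotating the viewing ray", {
  # with tilt gamma, a camera elevation e sees the ground where an untilted
  # camera would at elevation e + gamma (at zero azimuth)
  e <- -20; g <- 30
  expect_equal(dropoff_distance(e, 0, h = 3.5, gamma = g),
               dropoff_distance(e + g, 0, h = 3.5, gamma = 0),
               tolerance = 1e-9)
})

test_that("lowering the validity threshold never loses detections", {
  cam <- spherical_camera(200, 100)
  plat <- build_arena("circular_platform")
  pose <- eye_pose(20, 3.5, 15, phi = 23)
  fl <- make_flow(plat, pose, self_motion(19, 25), cam)
  counts <- sapply(c(0.5, 0.2, 0.1, 0.02), function(thr) {
    sum(detect_dropoff(fl, flow_model_params(dropoff_threshold = thr))$valid)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("platform edges are detected nearby with gaps at distance", {
  cam <- spherical_camera(400, 200)
  plat <- build_arena("circular_platform")
  pose <- eye_pose(20, 3.5, 15, phi = 23)
  fl <- make_flow(plat, pose, self_motion(19, 25), cam)
  det <- detect_dropoff(fl)
  est <- dropoff_estimates(det, pose)
  expect_gt(nrow(est), 50)
  truth <- boundary_distance(plat, pose$x0, pose$z0, est$alpha)
  near <- truth < 40
  expect_gt(sum(near), 20)
  expect_lt(mean(abs(est$dist - truth)[near]), 2)
  # columns pointing at the distant rim are undersampled relative to near
  ang_near <- est$alpha[near]
  expect_lt(sum(det$valid), length(det$valid))
})

test_that("coarse grids trigger the resolution warning", {
  fl <- make_flow(build_arena("circular_platform"), eye_pose(0, 3.5, 0),
                  self_motion(19, 0), small_camera())
  expect_warning(detect_dropoff(fl), "coarse")
})
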