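test_that("plane depths match their closed forms and the mesh oracle", {
  g <- plane_model("ground", d = 3.5)
  expect_equal(plane_depth(g, 0, -90), 3.5)
  expect_equal(plane_depth(g, 0, -30), 7)
  expect_true(is.na(plane_depth(g, 0, 10)))  # above the horizon

  # wall at alpha = 90, d = 11 from pose (20, 3.5, 15): compare against the
  # mesh ray-cast of the square box for wall-labeled nodes
  cam <- small_camera()
  pose <- eye_pose(20, 3.5, 15, phi = 23)
  hit <- ray_cast(build_arena("square_box"), pose, cam, method = "mesh")
  w <- plane_model("wall", d = 11, alpha = 90, pose = pose)
  D <- plane_depth(w, cam$theta, cam$varphi)
  east <- which(hit$label == "wall" & abs(hit$point[, 1] - 31) < 1e-6)
  expect_gt(length(east), 10)
  expect_equal(D[east], hit$distance[east], tolerance = 1e-9)
})

test_that("wall normals follow the stated rotation order", {
  expect_equal(wall_normal(0, 0, 0), c(0, 0, -1))
  for (al in c(0, 45, 160, 300)) for (ph in c(0, 90, 211)) {
    expect_lt(abs(wall_normal(al, 0, ph)[2]), 1e-12)
    expect_equal(sqrt(sum(wall_normal(al, 30, ph)^2)), 1, tolerance = 1e-12)
  }
  # oracle: explicit rotation matrices, tilt about the heading-dependent axis
  rotmat_y <- function(p) {
    p <- p * pi / 180
    rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  }
  al <- 70; ga <- 30; ph <- 40
  tilt <- function(g) {
    g <- g * pi / 180
    rbind(c(1, 0, 0), c(0, cos(g), sin(g)), c(0, -sin(g), cos(g)))
  }
  n_expect <- tilt(-ga) %*% rotmat_y(al - ph) %*% c(0, 0, -1)
  expect_equal(wall_normal(al, ga, ph), c(n_expect), tolerance = 1e-12)
  # swapping head direction before wall direction changes the result when
  # tilted: the tilt axis depends on phi
  swapped <- rotate_rodrigues(
    rotate_rodrigues(rotate_rodrigues(c(0, 0, -1), c(0, 1, 0), -ph),
                     c(cos(ph * pi / 180), 0, -sin(ph * pi / 180)), ga),
    c(0, 1, 0), al)
  expect_gt(max(abs(swapped - wall_normal(al, ga, ph))), 1e-3)
})

test_that("template flow matches analytic flow on an equivalent scene", {
  cam <- small_camera()
  params <- flow_model_params()
  g <- plane_model("ground", d = 3.5)
  tf0 <- template_flow(g, 0, 0, cam, params)
  expect_true(all(tf0$dtheta == 0) && all(tf0$dvarphi == 0))

  # a huge platform is locally an infinite ground plane
  plat <- build_arena("circular_platform", diameter = 4000)
  pose <- eye_pose(0, 3.5, 0)
  fl <- make_flow(plat, pose, self_motion(17, -40), cam, params)
  tf <- template_flow(g, 17, -40, cam, params)
  ok <- fl$label == "ground" & !is.na(tf$depth) & fl$depth < 900
  expect_gt(sum(ok), 100)
  expect_equal(tf$dtheta[ok], fl$dtheta[ok], tolerance = 1e-6)
  expect_equal(tf$dvarphi[ok], fl$dvarphi[ok], tolerance = 1e-6)

  # wall template magnitude decreases monotonically with distance
  pose <- eye_pose(0, 3.5, 0)
  mags <- sapply(c(5, 10, 20, 40), function(d) {
    w <- plane_model("wall", d = d, alpha = 0, pose = pose)
    tf <- template_flow(w, 20, 0, cam)
    i <- which(cam$theta > 0 & cam$theta < 10 & abs(cam$varphi) < 5)[1]
    sqrt(tf$dtheta[i]^2 + tf$dvarphi[i]^2)
  })
  expect_true(all(diff(mags) < 0))
})

test_that("noise-free segmentation is exact and self-motion grid-exact", {
  cam <- spherical_camera()
  # fine segmentation search grids resolve every node
  bank <- template_bank(cam, flow_model_params(seg_alpha_step = 1,
                                               seg_n_dist = 256))
  cases <- list(list(build_arena("square_box"), eye_pose(10, 3.5, 5, phi = 0)),
                list(build_arena("circular_box"), eye_pose(0, 3.5, 0, phi = 0)))
  for (cs in cases) {
    fl <- make_flow(cs[[1]], cs[[2]], self_motion(19, 25), cam)
    seg <- segment_flow(fl, bank, cs[[2]])
    lab <- fl$label != "none"
    expect_identical(as.character(seg[lab]), as.character(fl$label[lab]))
    gset <- which(seg == "ground")
    lv <- estimate_linear_velocity(fl, gset, bank)
    expect_equal(lv$v_est, 19, tolerance = 1e-6)
    rv <- estimate_rotational_velocity(fl, gset, bank, lv$v_est)
    expect_equal(rv$omega_est, 25, tolerance = 1e-6)
  }
})

test_that("segmentation under flow noise stays majority-correct", {
  cam <- spherical_camera()
  bank <- template_bank(cam)
  fl0 <- make_flow(build_arena("square_box"), s1_pose(), s1_motion(), cam)
  set.seed(31)
  accs <- sapply(1:3, function(i) {
    fl <- add_flow_noise(fl0, 5)
    seg <- segment_flow(fl, bank, s1_pose())
    mean((seg == fl$label)[fl$label != "none"])
  })
  expect_true(all(accs > 0.6))
  expect_true(mean(accs) > 0.75)
})

test_that("a pure ground view yields no wall samples", {
  cam <- small_camera()
  plat <- build_arena("circular_platform", diameter = 4000)
  pose <- eye_pose(0, 3.5, 0)
  fl <- make_flow(plat, pose, self_motion(19, 25), cam)
  bank <- template_bank(cam)
  seg <- segment_flow(fl, bank, pose)
  lab <- fl$label != "none"
  expect_true(mean((seg == "ground")[lab]) > 0.99)
})

test_that("the 1D read-out weights a centered window", {
  expect_equal(readout_1d(c(0, 0, 1, 0, 0), 1:5), 3)
  # symmetric plateau of two bins reads out at the midpoint
  expect_equal(readout_1d(c(0, 1, 1, 0), c(1, 2, 3, 4), frac = 0.5), 2.5)
  # dense Gaussian curve: read-out lands within half a grid step of the
  # quadratic-interpolation peak
  x <- seq(0, 50, by = 0.5)
  true_peak <- 23.3
  y <- exp(-(x - true_peak)^2 / 18)
  i <- which.max(y)
  quad <- x[i] + 0.5 * 0.5 * (y[i - 1] - y[i + 1]) /
    (y[i - 1] - 2 * y[i] + y[i + 1])
  expect_lt(abs(readout_1d(y, x) - quad), 0.25)
  expect_warning(readout_1d(rep(1, 5), 1:5), "constant")
})

test_that("the 2D read-out selects the 70 percent region", {
  m <- matrix(0, 3, 4)
  m[2, 3] <- 1; m[1, 1] <- 0.8; m[3, 4] <- 0.5
  est <- readout_2d(m, c(0, 90, 180), c(5, 10, 20, 40))
  expect_identical(nrow(est), 2L)
  expect_true(all(est$weight >= 0.7) && max(est$weight) == 1)
  expect_true(any(est$alpha == 90 & est$dist == 20))
  # uniform surface: every cell is returned with weight 1
  u <- readout_2d(matrix(1, 2, 2), c(0, 90), c(5, 10))
  expect_identical(nrow(u), 4L)
  expect_true(all(u$weight == 1))
  # empty / non-positive surfaces yield no estimates
  expect_identical(nrow(readout_2d(matrix(0, 2, 2), c(0, 90), c(5, 10))), 0L)
})

test_that("the wall matcher self-matches an exact template", {
  cam <- small_camera()
  pose <- eye_pose(0, 3.5, 0, phi = 0)
  params <- flow_model_params(n_dist = 16, alpha_step = 30)
  bank <- template_bank(cam, params)
  al <- bank$alpha_samples[3]; d <- bank$dist_samples[8]
  w <- plane_model("wall", d = d, alpha = al, pose = pose)
  tf <- template_flow(w, 20, 10, cam, params)
  wall_idx <- which(!is.na(tf$depth) & abs(tf$dvarphi) + abs(tf$dtheta) > 1)
  m <- match_speed_direction(tf, wall_idx, bank, pose, 20, 10)
  i <- which(m == max(m), arr.ind = TRUE)
  expect_equal(bank$alpha_samples[i[1]], al)
  expect_equal(bank$dist_samples[i[2]], d)
})

test_that("the C++ matchers agree with the R reference and each other", {
  cam <- small_camera()
  pose <- eye_pose(15, 3.5, -10, phi = 120)
  arena <- build_arena("square_box")
  params <- flow_model_params(n_dist = 12, alpha_step = 45)
  bank <- template_bank(cam, params)
  fl <- make_flow(arena, pose, self_motion(22, 80), cam, params)
  wall_idx <- which(fl$label == "wall")
  me <- match_speed_direction(fl, wall_idx, bank, pose, 22, 80, "exact")
  mr <- r_match_wall2d(fl, wall_idx, bank, pose, 22, 80)
  expect_equal(me, mr, tolerance = 1e-6, ignore_attr = TRUE)

  # the binned accumulation approximates the exact surface
  full_bank <- template_bank(spherical_camera())
  fl2 <- make_flow(arena, pose, self_motion(22, 80), spherical_camera())
  w2 <- which(fl2$label == "wall")
  a <- match_speed_direction(fl2, w2, full_bank, pose, 22, 80, "exact")
  b <- match_speed_direction(fl2, w2, full_bank, pose, 22, 80, "binned")
  expect_gt(cor(as.vector(a), as.vector(b)), 0.999)
  ea <- distance_error(readout_2d(a, full_bank$alpha_samples,
                                  full_bank$dist_samples), pose, arena)
  eb <- distance_error(readout_2d(b, full_bank$alpha_samples,
                                  full_bank$dist_samples), pose, arena)
  expect_lt(abs(mean(ea$error) - mean(eb$error)), 0.25)
})

test_that("degenerate sample sets are reported", {
  cam <- small_camera()
  bank <- template_bank(cam)
  fl <- make_flow(build_arena("square_box"), s1_pose(), s1_motion(), cam)
  expect_error(estimate_linear_velocity(fl, integer(0), bank), "ground")
  expect_error(estimate_rotational_velocity(fl, integer(0), bank, 19), "ground")
  m <- match_speed_direction(fl, integer(0), bank, s1_pose(), 19, 25)
  expect_true(all(m == 0))
})
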