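test_that("arena meshes are labeled, walls vertical, platforms wall-free", {
  circ <- build_arena("circular_box")
  mesh <- arena_mesh(circ)
  wall <- mesh$vertices[mesh$label == "wall", , drop = FALSE]
  # wall triangle normals are orthogonal to the vertical axis
  for (i in seq_len(nrow(wall))) {
    a <- wall[i, 1:3]; b <- wall[i, 4:6]; c <- wall[i, 7:9]
    n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
           (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
           (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
    expect_lt(abs(n[2] / sqrt(sum(n^2))), 1e-9)
  }
  ground <- mesh$vertices[mesh$label == "ground", , drop = FALSE]
  expect_true(all(abs(ground[, c(2, 5, 8)]) < 1e-12))

  sq <- build_arena("square_box")
  expect_identical(nrow(sq$segments), 4L)
  expect_equal(sq$extent, c(62, 62))

  plat <- build_arena("circular_platform")
  expect_identical(nrow(plat$segments), 0L)
  expect_false(any(arena_mesh(plat)$label == "wall"))

  expect_error(build_arena("hexagon"))
})

test_that("ray casting reproduces closed-form distances", {
  cam <- spherical_camera()
  params <- flow_model_params()

  # eye at the center of the circular box: horizontal rays hit at the radius
  circ <- build_arena("circular_box")
  pose <- eye_pose(0, 3.5, 0, phi = 0)
  hit <- ray_cast(circ, pose, cam, params)
  horiz <- which(abs(cam$varphi) < 2 & hit$label == "wall")
  expect_gt(length(horiz), 0)
  expect_true(all(abs(hit$distance[horiz] * cos(cam$varphi[horiz] * pi / 180) - 39.5) < 0.02))

  # square box, ray along +x from (20, 3.5, 15): wall at 11 cm
  sq <- build_arena("square_box")
  pose <- eye_pose(20, 3.5, 15, phi = 90)  # optical axis along +x
  hit <- ray_cast(sq, pose, cam, params)
  i <- which.min(abs(cam$theta) + abs(cam$varphi))
  d_analytic <- 11 / (cos(cam$theta[i] * pi / 180) * cos(cam$varphi[i] * pi / 180))
  expect_equal(hit$distance[i], d_analytic, tolerance = 1e-9)

  # downward rays at zero tilt: ground at h / sin(elevation below horizon)
  pose <- eye_pose(0, 3.5, 0, phi = 0)
  hit <- ray_cast(circ, pose, cam, params)
  down <- which(cam$varphi < -20 & abs(cam$theta) < 30)
  expect_true(all(hit$label[down] == "ground"))
  expect_equal(hit$distance[down],
               3.5 / sin(-cam$varphi[down] * pi / 180), tolerance = 1e-9)
})

test_that("segment and mesh ray casting agree on all four arenas", {
  cam <- small_camera()
  params <- flow_model_params()
  pose <- eye_pose(12, 3.5, -8, phi = 200)
  for (shape in c("circular_box", "square_box", "square_box_interior_wall",
                  "circular_platform")) {
    arena <- build_arena(shape)
    a <- ray_cast(arena, pose, cam, params, method = "segments")
    b <- ray_cast(arena, pose, cam, params, method = "mesh")
    expect_identical(as.character(a$label), as.character(b$label))
    ok <- a$label != "none"
    expect_lt(max(abs(a$distance[ok] - b$distance[ok])), 1e-6)
  }
})

test_that("hit points satisfy the surface constraints", {
  cam <- small_camera()
  arena <- build_arena("square_box_interior_wall")
  pose <- eye_pose(-15, 3.5, 10, phi = 45)
  hit <- ray_cast(arena, pose, cam)
  g <- hit$label == "ground"; w <- hit$label == "wall"
  expect_true(all(abs(hit$point[g, 2]) < 1e-9))
  expect_true(all(hit$point[w, 2] > -1e-9 & hit$point[w, 2] <= 50 + 1e-9))
  # distances equal the euclidean eye-to-point length
  ok <- hit$label != "none"
  d <- sqrt((hit$point[ok, 1] - pose$x0)^2 + (hit$point[ok, 2] - pose$y0)^2 +
            (hit$point[ok, 3] - pose$z0)^2)
  expect_equal(d, hit$distance[ok], tolerance = 1e-9)
})

test_that("poses outside the footprint are rejected", {
  expect_error(ray_cast(build_arena("square_box"), eye_pose(40, 3.5, 0),
                        small_camera()), "outside")
  expect_error(generate_trajectory(build_arena("square_box"),
                                   velocity_stats(10), duration_s = 1,
                                   start = c(100, 0)), "outside")
})

test_that("boundary distances are exact for simple geometry", {
  sq <- build_arena("square_box")
  expect_equal(boundary_distance(sq, 0, 0, c(0, 90, 180, 270)),
               rep(31, 4), tolerance = 1e-9)
  expect_equal(boundary_distance(sq, 20, 15, 90), 11, tolerance = 1e-9)
  circ <- build_arena("circular_box")
  expect_equal(boundary_distance(circ, 0, 0, 123), 39.5, tolerance = 5e-4)  # facet flattening ~0.01 cm
  plat <- build_arena("circular_platform")
  expect_equal(boundary_distance(plat, 10, 0, 90), 29.5, tolerance = 1e-9)
})
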