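# shared fixtures: small grids keep the unit tests fast; acceptance tests
# build their own full-size objects

small_camera <- function() spherical_camera(n_az = 40, n_el = 20)

s1_pose <- function() eye_pose(20, 3.5, 15, phi = 23)
s1_motion <- function() self_motion(19, 25)

make_flow <- function(arena, pose, motion, camera = spherical_camera(),
                      params = flow_model_params()) {
  analytic_flow(camera, pose, motion, ray_cast(arena, pose, camera, params),
                params)
}

# pure-R reference of the wall speed-direction matcher (independent of the
# C++ kernels); used as the oracle on tiny grids
r_match_wall2d <- function(flow, wall_idx, bank, pose, v_est, omega_est) {
  p <- bank$params
  A <- length(bank$alpha_samples); J <- length(bank$dist_samples)
  M <- matrix(0, A, J)
  th <- bank$camera$theta; ph <- bank$camera$varphi
  dth <- flow$dtheta[wall_idx] + omega_est
  r_in <- pmax(sqrt(dth^2 + flow$dvarphi[wall_idx]^2), 1e-6)
  dir_in <- atan2(flow$dvarphi[wall_idx], dth)
  for (ia in seq_len(A)) for (jj in seq_len(J)) {
    pl <- plane_model("wall", d = bank$dist_samples[jj],
                      alpha = bank$alpha_samples[ia], pose = pose)
    D <- plane_depth(pl, th[wall_idx], ph[wall_idx])
    t1 <- (180 / pi) * v_est * bank$s1[wall_idx] / D
    t2 <- (180 / pi) * v_est * bank$s2[wall_idx] / D
    r_t <- pmax(sqrt(t1^2 + t2^2), 1e-6)
    dd <- atan2(t2, t1) - dir_in
    dd <- ((dd + pi) %% (2 * pi)) - pi
    g <- exp(-(log(r_t) - log(r_in))^2 / (2 * p$sigma_logspeed^2)) *
      (exp(-dd^2 / (2 * (p$sigma_direction * pi / 180)^2)) - p$direction_offset)
    M[ia, jj] <- sum(g[!is.na(D)], na.rm = TRUE)
  }
  M
}
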