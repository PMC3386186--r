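#' Curvilinear self-motion
#'
#' Self-motion of the rat eye restricted to forward translation along the
#' optical axis plus yaw rotation about the vertical axis.
#'
#' @param v_z linear velocity along the optical axis in cm/sec.
#' @param omega_y yaw rotational velocity in deg/sec (positive turns the
#'   head toward larger allocentric direction).
#' @return object of class `bvcflow_motion`.
#' @export
self_motion <- function(v_z = 0, omega_y = 0) {
  stopifnot(is.finite(v_z), is.finite(omega_y))
  structure(list(v_z = v_z, omega_y = omega_y), class = "bvcflow_motion")
}

# Spherical flow for arbitrary camera-frame translation (cm/sec) and
# rotation (deg/sec, about camera axes). u: N x 3 unit directions, D depths
# in cm. Returns angular velocities of azimuth/elevation in deg/sec.
# Derivation: a static point X = D u moves with dX/dt = -v - w x X relative
# to the camera; azimuth theta = atan2(x, z), elevation = atan2(y, r) with
# r = sqrt(x^2 + z^2).
flow_from_motion <- function(u, D, v_cam, omega_cam_deg) {
  w <- deg2rad(omega_cam_deg)
  X <- u * D
  x <- X[, 1]; y <- X[, 2]; z <- X[, 3]
  vx <- -v_cam[1] - (w[2] * z - w[3] * y)
  vy <- -v_cam[2] - (w[3] * x - w[1] * z)
  vz <- -v_cam[3] - (w[1] * y - w[2] * x)
  r2 <- x^2 + z^2
  dtheta <- (vx * z - vz * x) / r2
  r <- sqrt(r2)
  rdot <- (x * vx + z * vz) / r
  dvarphi <- (vy * r - y * rdot) / D^2
  list(dtheta = rad2deg(dtheta), dvarphi = rad2deg(dvarphi))
}

#' Analytical spherical optic flow for curvilinear self-motion
#'
#' Evaluates the spherical flow field induced by forward translation `v_z`
#' and yaw rotation `omega_y` given per-node depths (from [ray_cast()]).
#' At zero tilt this reduces to the closed form
#' `dtheta/dt = (v_z / D) sin(theta) / cos(varphi) - omega_y` and
#' `dvarphi/dt = (v_z / D) sin(varphi) cos(theta)`: the rotational part is
#' independent of depth and the translational part scales with `1/D`. With
#' non-zero tilt the rat still translates parallel to the ground, so the
#' motion is expressed in the tilted camera frame before evaluating the
#' general flow equation.
#'
#' @param camera a [spherical_camera()].
#' @param pose a [eye_pose()].
#' @param motion a [self_motion()].
#' @param depths result of [ray_cast()] (per-node `distance` and `label`),
#'   or a list with those elements.
#' @param params a [flow_model_params()].
#' @return object of class `bvcflow_flow`: per-node vectors `dtheta`,
#'   `dvarphi` (deg/sec; 0 at unlabeled nodes), `depth`, `label`, plus the
#'   `camera`, `pose` and `motion` that generated it.
#' @export
#' @examples
#' arena <- build_arena("square_box"); cam <- spherical_camera()
#' pose <- eye_pose(20, 3.5, 15, phi = 23)
#' fl <- analytic_flow(cam, pose, self_motion(19, 25), ray_cast(arena, pose, cam))
#' range(fl$dtheta[fl$label != "none"])
analytic_flow <- function(camera, pose, motion, depths,
                          params = flow_model_params()) {
  D <- depths$distance
  lab <- depths$label
  valid <- lab != "none" & !is.na(D)
  if (any(D[valid] <= 0)) stop("non-positive depth at a labeled node")
  D2 <- pmax(D, params$min_depth)
  u <- camera_directions(camera)
  # camera-frame motion: translation parallel to the ground along the
  # heading, yaw about the world vertical
  g <- deg2rad(pose$gamma)
  v_cam <- motion$v_z * c(0, -sin(g), cos(g))
  w_cam <- motion$omega_y * c(0, cos(g), sin(g))
  fl <- flow_from_motion(u[valid, , drop = FALSE], D2[valid], v_cam, w_cam)
  dtheta <- numeric(length(D)); dvarphi <- numeric(length(D))
  dtheta[valid] <- fl$dtheta; dvarphi[valid] <- fl$dvarphi
  structure(list(dtheta = dtheta, dvarphi = dvarphi, depth = D,
                 label = lab, camera = camera, pose = pose, motion = motion),
            class = "bvcflow_flow")
}

#' @export
print.bvcflow_flow <- function(x, ...) {
  cat(sprintf("<bvcflow_flow> %d x %d nodes (%d ground, %d wall, %d none), v_z = %g cm/s, omega_y = %g deg/s\n",
              x$camera$n_el, x$camera$n_az,
              sum(x$label == "ground"), sum(x$label == "wall"),
              sum(x$label == "none"), x$motion$v_z, x$motion$omega_y))
  invisible(x)
}

#' Add Gaussian noise to a flow field
#'
#' Adds independent zero-mean Gaussian perturbations with standard deviation
#' `sigma_n` (deg/sec) to both angular-velocity components at every labeled
#' node, emulating imperfect flow measurement.
#'
#' @param flow a [analytic_flow()] field.
#' @param sigma_n noise standard deviation in deg/sec (>= 0).
#' @return the perturbed flow field.
#' @export
add_flow_noise <- function(flow, sigma_n) {
  if (!is.numeric(sigma_n) || sigma_n < 0) stop("sigma_n must be >= 0")
  if (sigma_n == 0) return(flow)
  valid <- flow$label != "none"
  n <- sum(valid)
  flow$dtheta[valid] <- flow$dtheta[valid] + stats::rnorm(n, 0, sigma_n)
  flow$dvarphi[valid] <- flow$dvarphi[valid] + stats::rnorm(n, 0, sigma_n)
  flow
}

#' Reshape a per-node flow quantity into an elevation x azimuth matrix
#'
#' @param flow a flow field.
#' @param what one of `"dtheta"`, `"dvarphi"`, `"depth"`, `"speed"`.
#' @return `n_el` x `n_az` matrix (rows: elevation ascending).
#' @export
flow_matrix <- function(flow, what = c("speed", "dtheta", "dvarphi", "depth")) {
  what <- match.arg(what)
  v <- switch(what,
              speed = sqrt(flow$dtheta^2 + flow$dvarphi^2),
              dtheta = flow$dtheta, dvarphi = flow$dvarphi,
              depth = flow$depth)
  matrix(v, flow$camera$n_el, flow$camera$n_az)
}
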