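#' Camera-frame normal vector of a wall plane
#'
#' Builds the unit normal of a vertical wall at allocentric direction
#' `alpha`, expressed in the (possibly tilted) camera frame of a head at
#' allocentric direction `phi`. The reference normal at
#' `alpha = gamma = phi = 0` is `(0, 0, -1)`: a wall straight ahead, facing
#' the eye. The rotations are applied in the order wall direction `alpha`
#' (about the vertical), tilt `-gamma` (about the heading-perpendicular
#' horizontal axis), head direction `-phi` (about the vertical); with this
#' order the tilt axis depends on `phi`, which is why the order of rotations
#' matters whenever `gamma != 0`.
#'
#' @param alpha allocentric direction of the wall in degrees.
#' @param gamma tilt angle in degrees.
#' @param phi allocentric head direction in degrees.
#' @return unit 3-vector in camera coordinates.
#' @export
#' @examples
#' wall_normal(0, 0, 0)          # c(0, 0, -1)
#' wall_normal(90, 0, 0)[2]      # stays horizontal
wall_normal <- function(alpha, gamma = 0, phi = 0) {
  n0 <- c(0, 0, -1)
  n1 <- rotate_rodrigues(n0, c(0, 1, 0), alpha)
  axis <- c(cos(deg2rad(phi)), 0, -sin(deg2rad(phi)))
  n2 <- rotate_rodrigues(n1, axis, gamma)
  rotate_rodrigues(n2, c(0, 1, 0), -phi)
}

#' Plane model in Hessian normal form
#'
#' @param role `"ground"` or `"wall"`.
#' @param d distance from the eye to the plane along the normal, in cm
#'   (eye height for the ground).
#' @param alpha allocentric wall direction in degrees (walls only).
#' @param pose a [eye_pose()] supplying head direction and tilt.
#' @return object of class `bvcflow_plane` with the camera-frame unit
#'   `normal` (pointing from the plane toward the eye), `d`, `role`, `alpha`.
#' @export
plane_model <- function(role = c("ground", "wall"), d, alpha = NA,
                        pose = eye_pose()) {
  role <- match.arg(role)
  stopifnot(d > 0)
  if (role == "ground") {
    # world up, expressed in the camera frame
    n <- c(rot_tilt(-pose$gamma) %*% c(0, 1, 0))
    alpha <- NA_real_
  } else {
    stopifnot(is.finite(alpha))
    n <- wall_normal(alpha, pose$gamma, pose$phi)
  }
  structure(list(normal = n, d = d, role = role, alpha = alpha),
            class = "bvcflow_plane")
}

#' Depth of a plane along viewing directions
#'
#' Hessian-normal-form depth: a point at distance `D` along the unit
#' direction `u(theta, varphi)` lies on the plane when
#' `D = d / (-normal . u)`. For the zero-tilt ground plane this reduces to
#' `D = h / sin(-varphi)`. Directions that are parallel to the plane or see
#' it behind the eye are flagged `NA`.
#'
#' @param plane a [plane_model()].
#' @param theta,varphi viewing angles in degrees (vectorized).
#' @return depths in cm (`NA` where invalid).
#' @export
#' @examples
#' g <- plane_model("ground", d = 3.5)
#' plane_depth(g, 0, -90)   # nadir: 3.5
#' plane_depth(g, 0, -30)   # 3.5 / sin(30 deg) = 7
plane_depth <- function(plane, theta, varphi) {
  th <- deg2rad(theta); ph <- deg2rad(varphi)
  u <- cbind(cos(ph) * sin(th), sin(ph), cos(ph) * cos(th))
  den <- -(u %*% plane$normal)[, 1]
  D <- plane$d / den
  D[den <= 1e-9] <- NA_real_
  D
}

#' Template flow field for a plane hypothesis
#'
#' Evaluates the constrained flow equation: the curvilinear-motion spherical
#' flow with the per-node depth supplied by a plane model instead of the
#' true scene depth. Nodes where the plane is invalid carry zero flow and
#' label `none`.
#'
#' @param plane a [plane_model()].
#' @param v_z,omega_y hypothesized self-motion (cm/sec, deg/sec).
#' @param camera a [spherical_camera()].
#' @param params a [flow_model_params()].
#' @return a `bvcflow_flow` object.
#' @export
template_flow <- function(plane, v_z, omega_y, camera,
                          params = flow_model_params()) {
  D <- plane_depth(plane, camera$theta, camera$varphi)
  lab <- factor(ifelse(is.na(D), "none", as.character(plane$role)),
                levels = c("ground", "wall", "none"))
  valid <- !is.na(D)
  D2 <- pmax(D, params$min_depth)
  u <- camera_directions(camera)
  # Eq-of-motion in the camera frame: curvilinear translation along the
  # optical axis plus yaw about the camera vertical (the plane normal
  # already carries any tilt).
  fl <- flow_from_motion(u[valid, , drop = FALSE], D2[valid],
                         c(0, 0, v_z), c(0, omega_y, 0))
  dtheta <- numeric(length(D)); dvarphi <- numeric(length(D))
  dtheta[valid] <- fl$dtheta; dvarphi[valid] <- fl$dvarphi
  structure(list(dtheta = dtheta, dvarphi = dvarphi, depth = D, label = lab,
                 camera = camera, pose = NULL,
                 motion = self_motion(v_z, omega_y)),
            class = "bvcflow_flow")
}

#' Template bank of the flow-matching model
#'
#' Precomputes everything the matchers need that does not depend on the
#' momentary pose: the self-motion sample grids, the wall direction/distance
#' grids (distances log-spaced), the tuning widths, and the per-node
#' geometric factors of the camera grid. Matching a flow field against the
#' bank touches no arena geometry.
#'
#' The zero-tilt closed forms used by the matchers are, per node with
#' azimuth `theta` and elevation `varphi`:
#' ground depth `D_g = h / sin(-varphi)`; wall depth
#' `D_w = d / (cos(varphi) cos(alpha - phi - theta))`; translational flow
#' factors `s1 = sin(theta) / cos(varphi)` (azimuth) and
#' `s2 = sin(varphi) cos(theta)` (elevation).
#'
#' @param camera a [spherical_camera()].
#' @param params a [flow_model_params()].
#' @return object of class `bvcflow_bank`.
#' @export
#' @examples
#' bank <- template_bank(spherical_camera())
#' length(bank$v_samples); range(bank$dist_samples)
template_bank <- function(camera = spherical_camera(),
                          params = flow_model_params()) {
  v_samples <- seq(params$v_min, params$v_max, length.out = params$n_v)
  omega_samples <- seq(params$omega_min, params$omega_max,
                       length.out = params$n_omega)
  alpha_samples <- seq(0, 360 - params$alpha_step, by = params$alpha_step)
  dist_samples <- exp(seq(log(params$dist_min), log(params$dist_max),
                          length.out = params$n_dist))
  th <- deg2rad(camera$theta); ph <- deg2rad(camera$varphi)
  structure(list(
    camera = camera, params = params,
    v_samples = v_samples, omega_samples = omega_samples,
    alpha_samples = alpha_samples, dist_samples = dist_samples,
    h = params$eye_height,
    s1 = sin(th) / cos(ph),
    s2 = sin(ph) * cos(th),
    cosphi = cos(ph),
    sinphi = sin(ph),
    ground_valid = ph < 0,
    D_ground = ifelse(ph < 0, params$eye_height / sin(-ph), NA_real_)
  ), class = "bvcflow_bank")
}

#' @export
print.bvcflow_bank <- function(x, ...) {
  cat(sprintf("<bvcflow_bank> %d v x %d omega x %d alpha x %d dist templates on %d nodes\n",
              length(x$v_samples), length(x$omega_samples),
              length(x$alpha_samples), length(x$dist_samples),
              length(x$s1)))
  invisible(x)
}
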