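#' Spherical camera model
#'
#' Defines the panoramic sampling grid of the simulated rat eye: azimuth
#' covering 240 degrees and elevation 120 degrees, sampled on a regular,
#' cell-centered grid. Azimuth is measured from the optical axis (z) in the
#' xz-plane, positive to the right; elevation from the azimuth-rotated
#' forward axis, positive up. The default 80 x 40 grid is used for wall
#' estimation; drop-off detection runs on the finer 400 x 200 grid.
#'
#' @param n_az,n_el number of azimuth / elevation samples.
#' @param az_half,el_half half-extent of the field of view in degrees.
#' @return object of class `bvcflow_camera` with the node grids (`az`, `el`)
#'   and per-node vectors `theta`, `varphi` (degrees; elevation varies
#'   fastest, matching `matrix(x, n_el, n_az)` reshaping).
#' @export
#' @examples
#' cam <- spherical_camera()
#' range(cam$theta); length(cam$theta)
spherical_camera <- function(n_az = 80, n_el = 40, az_half = 120, el_half = 60) {
  stopifnot(n_az >= 2, n_el >= 2)
  daz <- 2 * az_half / n_az
  del <- 2 * el_half / n_el
  az <- seq(-az_half + daz / 2, az_half - daz / 2, length.out = n_az)
  el <- seq(-el_half + del / 2, el_half - del / 2, length.out = n_el)
  structure(list(n_az = n_az, n_el = n_el, az = az, el = el,
                 theta = rep(az, each = n_el), varphi = rep(el, times = n_az)),
            class = "bvcflow_camera")
}

#' @export
print.bvcflow_camera <- function(x, ...) {
  cat(sprintf("<bvcflow_camera> %d x %d nodes, azimuth +/-%g deg, elevation +/-%g deg\n",
              x$n_az, x$n_el, max(abs(x$az)) + (x$az[2] - x$az[1]) / 2,
              max(abs(x$el)) + (x$el[2] - x$el[1]) / 2))
  invisible(x)
}

#' Unit viewing directions of the camera grid
#'
#' @param camera a [spherical_camera()].
#' @return N x 3 matrix of camera-frame unit vectors
#'   `(cos(el) sin(az), sin(el), cos(el) cos(az))`.
#' @export
camera_directions <- function(camera) {
  th <- deg2rad(camera$theta); ph <- deg2rad(camera$varphi)
  cbind(cos(ph) * sin(th), sin(ph), cos(ph) * cos(th))
}

#' Eye pose in the arena
#'
#' @param x0,y0,z0 eye position in cm (`y0` is the eye height above ground).
#' @param phi allocentric head direction in degrees (0 = +z, 90 = +x);
#'   wrapped to `[0, 360)`.
#' @param gamma tilt angle in degrees between the optical axis and the
#'   ground plane (positive = looking up).
#' @return object of class `bvcflow_pose`.
#' @export
#' @examples
#' eye_pose(20, 3.5, 15, phi = 23)
eye_pose <- function(x0 = 0, y0 = 3.5, z0 = 0, phi = 0, gamma = 0) {
  stopifnot(y0 > 0, gamma >= -90, gamma <= 90)
  structure(list(x0 = x0, y0 = y0, z0 = z0, phi = wrap_angle(phi, 0),
                 gamma = gamma), class = "bvcflow_pose")
}

#' @export
print.bvcflow_pose <- function(x, ...) {
  cat(sprintf("<bvcflow_pose> (%g, %g, %g) cm, phi = %g deg, gamma = %g deg\n",
              x$x0, x$y0, x$z0, x$phi, x$gamma))
  invisible(x)
}

# rotation about the world y (up) axis; maps +z to (sin psi, 0, cos psi)
rot_y <- function(psi_deg) {
  p <- deg2rad(psi_deg)
  rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
}

# camera pitch: maps the optical axis +z to (0, sin g, cos g), i.e. positive
# gamma elevates the optical axis above the ground plane
rot_tilt <- function(gamma_deg) {
  g <- deg2rad(gamma_deg)
  rbind(c(1, 0, 0), c(0, cos(g), sin(g)), c(0, -sin(g), cos(g)))
}

#' Rotate a vector about an arbitrary axis (Rodrigues formula)
#'
#' @param v 3-vector.
#' @param axis rotation axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return rotated 3-vector.
#' @export
rotate_rodrigues <- function(v, axis, angle_deg) {
  k <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  kxv <- c(k[2] * v[3] - k[3] * v[2],
           k[3] * v[1] - k[1] * v[3],
           k[1] * v[2] - k[2] * v[1])
  v * cos(a) + kxv * sin(a) + k * sum(k * v) * (1 - cos(a))
}

# camera-to-world rotation matrix for a pose
pose_rotation <- function(pose) {
  rot_y(pose$phi) %*% rot_tilt(pose$gamma)
}

#' Cast the camera grid rays into an arena
#'
#' Finds, for every node of the spherical grid, the nearest intersection of
#' the viewing ray with the arena within the maximum sampling distance, and
#' labels it `ground`, `wall` or `none`. The default path intersects the
#' plan-view wall segments and the ground plane in closed form; the `mesh`
#' path intersects the labeled triangle mesh and exists as the slower
#' reference implementation.
#'
#' @param arena a [build_arena()] object.
#' @param pose a [eye_pose()]; must lie inside the arena footprint.
#' @param camera a [spherical_camera()].
#' @param params a [flow_model_params()] (depth limits).
#' @param method `"segments"` (closed-form, default) or `"mesh"`.
#' @return list with per-node `distance` (cm, `NA` when no hit), `label`
#'   (factor levels ground/wall/none) and `point` (N x 3 world hit points).
#' @export
#' @examples
#' hit <- ray_cast(build_arena("square_box"), eye_pose(), spherical_camera())
#' table(hit$label)
ray_cast <- function(arena, pose, camera, params = flow_model_params(),
                     method = c("segments", "mesh")) {
  method <- match.arg(method)
  if (!in_footprint(arena, pose$x0, pose$z0))
    stop("pose lies outside the arena footprint")
  u <- camera_directions(camera) %*% t(pose_rotation(pose))
  eye <- c(pose$x0, pose$y0, pose$z0)
  f <- arena$footprint
  if (method == "segments") {
    res <- cpp_raycast(eye, u, arena$segments, arena$wall_height,
                       if (f$type == "circle") 0L else 1L,
                       if (f$type == "circle") f$r else f$hx,
                       if (f$type == "circle") f$r else f$hz,
                       params$max_depth, params$min_depth)
  } else {
    mesh <- arena_mesh(arena)
    res <- cpp_raycast_mesh(eye, u, mesh$vertices,
                            as.integer(mesh$label == "wall"),
                            params$max_depth, params$min_depth)
  }
  res$label <- factor(c("ground", "wall", "none")[res$label + 1L],
                      levels = c("ground", "wall", "none"))
  res$dirs_world <- u
  res
}
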