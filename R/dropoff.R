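#' Detect drop-offs from flow-speed discontinuities
#'
#' A platform edge produces no wall-type flow; it appears as a sharp drop
#' in flow speed along elevation (near ground moves fast, the void beyond
#' carries no flow). The detector applies a one-dimensional center-surround
#' filter (difference of boxes: one center cell against `surround` cells on
#' each side) to the flow-speed image along the elevation axis of every
#' azimuth column and takes the elevation of the maximum response.
#' Responses below `threshold` times the global maximum are flagged
#' invalid, which suppresses detections at distant edges where the speed
#' discontinuity is weak.
#'
#' @param flow a `bvcflow_flow` field, ideally on the fine 400 x 200 grid
#'   (a coarser grid triggers a resolution warning).
#' @param params a [flow_model_params()] (kernel sizes and threshold).
#' @return data frame with one row per azimuth column: `theta` (deg),
#'   `elevation` (deg at max response), `response`, `valid`.
#' @export
#' @examples
#' arena <- build_arena("circular_platform")
#' cam <- spherical_camera(200, 100)
#' pose <- eye_pose(20, 3.5, 15, phi = 23)
#' fl <- analytic_flow(cam, pose, self_motion(19, 0), ray_cast(arena, pose, cam))
#' det <- detect_dropoff(fl)
#' sum(det$valid) > 0
detect_dropoff <- function(flow, params = flow_model_params()) {
  cam <- flow$camera
  if (cam$n_el < 100)
    warning("coarse elevation grid: drop-off resolution is degraded")
  sp <- flow_matrix(flow, "speed")       # n_el x n_az, 0 where no flow
  cs <- params$dropoff_center
  su <- params$dropoff_surround
  n_el <- cam$n_el
  resp <- matrix(-Inf, n_el, cam$n_az)
  rows <- (su + cs):(n_el - su - cs + 1)
  for (r in rows) {
    center <- colMeans(sp[(r - cs + 1):(r + cs - 1), , drop = FALSE])
    surround <- (colSums(sp[(r - cs - su + 1):(r - cs), , drop = FALSE]) +
                 colSums(sp[(r + cs):(r + cs + su - 1), , drop = FALSE])) / (2 * su)
    resp[r, ] <- center - surround
  }
  best <- apply(resp, 2, which.max)
  mx <- resp[cbind(best, seq_len(cam$n_az))]
  gmax <- max(mx)
  valid <- is.finite(mx) & gmax > 0 & mx > params$dropoff_threshold * gmax
  data.frame(theta = cam$az, elevation = cam$el[best], response = mx,
             valid = valid)
}

#' Ground distance of a detected drop-off elevation
#'
#' Converts a viewing elevation (camera frame) into the horizontal ground
#' distance of the point where that ray meets the ground plane, given the
#' eye height and tilt. Rays at or above the (tilt-corrected) horizon have
#' no finite ground intersection and return `NA`.
#'
#' @param elevation camera-frame elevation in degrees (vectorized).
#' @param theta camera-frame azimuth in degrees (vectorized or scalar).
#' @param h eye height in cm.
#' @param gamma tilt angle in degrees.
#' @return horizontal distances in cm (`NA` where the ray misses the
#'   ground).
#' @export
#' @examples
#' dropoff_distance(-45, 0, h = 3.5)  # 3.5
dropoff_distance <- function(elevation, theta = 0, h = 3.5, gamma = 0) {
  n <- max(length(elevation), length(theta))
  elevation <- rep_len(elevation, n); theta <- rep_len(theta, n)
  th <- deg2rad(theta); ph <- deg2rad(elevation)
  u <- cbind(cos(ph) * sin(th), sin(ph), cos(ph) * cos(th))
  uw <- u %*% t(rot_tilt(gamma))
  out <- rep(NA_real_, n)
  ok <- uw[, 2] < -1e-12
  t <- -h / uw[ok, 2]
  out[ok] <- t * sqrt(uw[ok, 1]^2 + uw[ok, 3]^2)
  out
}

#' Convert drop-off detections into boundary estimates
#'
#' Valid detections become `(alpha, dist, weight)` rows exactly like wall
#' estimates: allocentric direction of the azimuth column, ground distance
#' of the detected elevation, and the normalized filter response as weight.
#'
#' @param detection result of [detect_dropoff()].
#' @param pose the [eye_pose()] that produced the flow field.
#' @return data frame with `alpha`, `dist`, `weight`.
#' @export
dropoff_estimates <- function(detection, pose) {
  d <- detection[detection$valid, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(alpha = numeric(0), dist = numeric(0),
                      weight = numeric(0)))
  dist <- dropoff_distance(d$elevation, d$theta, h = pose$y0,
                           gamma = pose$gamma)
  keep <- is.finite(dist)
  d <- d[keep, , drop = FALSE]; dist <- dist[keep]
  data.frame(alpha = wrap_angle(pose$phi + d$theta, 0), dist = dist,
             weight = d$response / max(d$response))
}
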