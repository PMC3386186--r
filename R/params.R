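#' Model parameters for the flow template and BVC models
#'
#' Collects every numeric tuning constant of the pipeline in one named list:
#' spherical camera layout, template-model sample grids and tuning widths,
#' read-out fractions, boundary-vector-cell tuning, and drop-off detection.
#' All downstream functions take their constants from this object, never from
#' inline literals, so a single call site controls a whole simulation.
#'
#' Units: distances in cm, linear velocities in cm/sec, angles in degrees,
#' angular velocities in deg/sec. The wall-distance grid is logarithmically
#' spaced (close range is resolved at centimeter precision, far range
#' coarsely), matching the ecological argument that nearby obstacles need the
#' finest representation.
#'
#' @param ... named overrides for any default listed below.
#'
#' @return A list of class `bvcflow_params` with elements:
#' \describe{
#'   \item{eye_height}{eye elevation above ground (3.5 cm).}
#'   \item{v_min, v_max, n_v}{linear-velocity sample grid (0..60 cm/sec, 61
#'     samples, i.e. 1 cm/sec steps).}
#'   \item{omega_min, omega_max, n_omega}{yaw-velocity sample grid
#'     (-1000..1000 deg/sec, 401 samples, 5 deg/sec steps; wide enough for
#'     the yaw-rate distribution of foraging rats).}
#'   \item{alpha_step}{allocentric wall-direction grid step (5 deg, 72
#'     samples over 0..355).}
#'   \item{dist_min, dist_max, n_dist}{log-spaced wall-distance grid
#'     (2..250 cm, 64 samples).}
#'   \item{seg_alpha_step, seg_n_dist}{wall-family search grid of the
#'     segmentation stage (30 deg steps, 8 log-spaced distances); coarse by
#'     design so the wall family cannot over-fit noisy ground flow.}
#'   \item{sigma_ground, sigma_wall}{tuning widths (deg/sec) of the
#'     rotation-invariant ground and wall segmentation matchers.}
#'   \item{sigma_speed, sigma_omega}{tuning widths (deg/sec) of the linear
#'     and rotational velocity matchers.}
#'   \item{sigma_logspeed}{width of the log-speed factor of the wall
#'     speed-direction matcher (log deg/sec units).}
#'   \item{sigma_direction, direction_offset}{width (deg) and baseline offset
#'     of the flow-direction factor of the wall matcher.}
#'   \item{readout_frac}{fraction of grid arguments in the 1D read-out
#'     window (0.02).}
#'   \item{readout2d_level}{relative level of the 2D read-out (0.7).}
#'   \item{bvc_sigma0, bvc_beta}{distance tuning width grows linearly with
#'     preferred distance: sigma_rad(D) = bvc_sigma0 * (D / bvc_beta + 1).}
#'   \item{bvc_sigma_ang}{angular tuning width of a BVC (deg).}
#'   \item{min_depth}{depth clamp (cm) protecting the 1/D flow terms.}
#'   \item{max_depth}{maximum ray-cast distance (1000 cm).}
#'   \item{dropoff_center, dropoff_surround}{half-widths (cells) of the
#'     center-surround kernel along elevation.}
#'   \item{dropoff_threshold}{validity threshold as a fraction of the global
#'     maximum filter response.}
#' }
#' @export
#' @examples
#' p <- flow_model_params()
#' p$eye_height
#' flow_model_params(n_dist = 32)$n_dist
flow_model_params <- function(...) {
  p <- list(
    eye_height = 3.5,
    # template-model sample grids
    v_min = 0, v_max = 60, n_v = 61,
    omega_min = -1000, omega_max = 1000, n_omega = 401,
    alpha_step = 5,
    dist_min = 2, dist_max = 250, n_dist = 64,
    # segmentation search grid of the wall family; deliberately coarse so
    # that the (richer) wall family cannot over-fit measurement noise at
    # ground nodes
    seg_alpha_step = 30, seg_n_dist = 8,
    # tuning widths
    sigma_ground = 5, sigma_wall = 5,
    sigma_speed = 5, sigma_omega = 5,
    sigma_logspeed = 0.13,
    sigma_direction = 30, direction_offset = 0.1,
    # read-out
    readout_frac = 0.02,
    readout2d_level = 0.7,
    # boundary vector cell model (Hartley/Burgess convention)
    bvc_sigma0 = 12.2, bvc_beta = 183, bvc_sigma_ang = 11.459,
    # depth handling
    min_depth = 0.5, max_depth = 1000,
    # drop-off detection
    dropoff_center = 1, dropoff_surround = 2,
    dropoff_threshold = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "bvcflow_params")
}

#' @export
print.bvcflow_params <- function(x, ...) {
  cat("<bvcflow_params>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}

# degree-based trigonometry used throughout (angles are degrees at interfaces)
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into a half-open interval
#'
#' @param x angles in degrees.
#' @param lo lower bound of the interval; the result lies in `[lo, lo + 360)`.
#' @return wrapped angles in degrees.
#' @export
wrap_angle <- function(x, lo = -180) {
  ((x - lo) %% 360) + lo
}
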