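#' Velocity statistics of rat locomotion
#'
#' Linear (running) speeds of foraging rats are well described by a
#' Rayleigh distribution and yaw rates by a zero-centered normal
#' distribution; a trajectory simulation is parameterized by the Rayleigh
#' scale `b` and the normal `(mu, sigma)`.
#'
#' @param rayleigh_b Rayleigh scale of linear speed, cm/sec (> 0).
#' @param normal_mu mean yaw rate, deg/sec.
#' @param normal_sigma yaw-rate standard deviation, deg/sec (> 0).
#' @return object of class `bvcflow_stats`.
#' @export
velocity_stats <- function(rayleigh_b, normal_mu = 0, normal_sigma = 340) {
  stopifnot(rayleigh_b > 0, normal_sigma > 0)
  structure(list(rayleigh_b = rayleigh_b, normal_mu = normal_mu,
                 normal_sigma = normal_sigma), class = "bvcflow_stats")
}

#' Velocity statistics fitted to recorded rat trajectories
#'
#' Published fits for open-field recordings: circular environments
#' (Rayleigh b = 16.99 cm/sec, yaw Normal(-2.48, 350.58) deg/sec) and
#' square environments (b = 13.25 cm/sec, Normal(0.62, 337.93) deg/sec).
#' These drive the simulated trajectories for the corresponding arenas.
#'
#' @param environment `"circular"` or `"square"`.
#' @return a [velocity_stats()] object.
#' @export
recorded_velocity_stats <- function(environment = c("circular", "square")) {
  environment <- match.arg(environment)
  if (environment == "circular") velocity_stats(16.99, -2.48, 350.58)
  else velocity_stats(13.25, 0.62, 337.93)
}

#' Draw linear and rotational velocity samples
#'
#' @param stats a [velocity_stats()].
#' @param n number of draws.
#' @return list with `v` (Rayleigh speeds, cm/sec) and `omega` (normal yaw
#'   rates, deg/sec). Uses the R RNG; seed with [set.seed()].
#' @export
sample_velocities <- function(stats, n = 1) {
  list(v = stats$rayleigh_b * sqrt(-2 * log(stats::runif(n))),
       omega = stats::rnorm(n, stats$normal_mu, stats$normal_sigma))
}

#' Generate a simulated rat trajectory
#'
#' Random-walk locomotion at 50 Hz: each 20 ms step draws a Rayleigh linear
#' speed and a normal yaw rate. A deterministic avoidance rule overrides the
#' heading whenever the rat is closer than `wall_margin` (2 cm) to a
#' boundary while heading within 90 degrees of the boundary normal: the
#' heading snaps to the boundary tangent, with the tangent sign chosen to
#' minimize the turn. Steps that would still exit clamp the position to a
#' 0.5 cm clearance, so realized speeds near walls can fall below the drawn
#' speeds (which is also seen as the slightly lower fitted Rayleigh scale of
#' simulated versus drawn speeds). Platform rims act as boundaries for
#' locomotion.
#'
#' The recorded `v` and `omega` columns are the realized step displacement
#' per `dt` and the drawn yaw rate; avoidance turns are modeled as discrete
#' heading resets, not as yaw velocity.
#'
#' @param arena a [build_arena()] object.
#' @param stats a [velocity_stats()].
#' @param duration_s duration in seconds (default 1200 = 20 min).
#' @param dt time step (0.02 s).
#' @param start plan start position (default arena center; shifted to the
#'   middle of the western half when an interior wall runs through the
#'   center).
#' @param phi0 initial head direction, degrees.
#' @param wall_margin avoidance distance, cm.
#' @param clearance minimum distance kept to any boundary, cm.
#' @return data frame of class `bvcflow_trajectory`: `t`, `x`, `z`, `phi`,
#'   `v`, `omega`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- generate_trajectory(build_arena("square_box"),
#'                           recorded_velocity_stats("square"), duration_s = 10)
#' range(tr$x)
generate_trajectory <- function(arena, stats, duration_s = 1200, dt = 0.02,
                                start = NULL, phi0 = 0, wall_margin = 2,
                                clearance = 0.5) {
  if (is.null(start)) {
    start <- c(0, 0)
    iw0 <- arena$interior_wall
    if (!is.null(iw0)) {
      e <- iw0[2, ] - iw0[1, ]
      tt <- max(0, min(1, sum((start - iw0[1, ]) * e) / sum(e^2)))
      if (sqrt(sum((start - iw0[1, ] - tt * e)^2)) < wall_margin)
        start <- c(-arena$extent[1] / 4, 0)
    }
  }
  n <- round(duration_s / dt)
  if (n == 0) {
    out <- data.frame(t = numeric(0), x = numeric(0), z = numeric(0),
                      phi = numeric(0), v = numeric(0), omega = numeric(0))
    class(out) <- c("bvcflow_trajectory", "data.frame")
    return(out)
  }
  if (!in_footprint(arena, start[1], start[2], margin = clearance))
    stop("start position outside the arena footprint")
  draws <- sample_velocities(stats, n)
  x <- numeric(n); z <- numeric(n); phi <- numeric(n); v <- numeric(n)
  cx <- start[1]; cz <- start[2]; cphi <- wrap_angle(phi0, 0)
  iw <- arena$interior_wall
  for (i in seq_len(n)) {
    vi <- draws$v[i]
    cphi <- wrap_angle(cphi + draws$omega[i] * dt, 0)
    nb <- nearest_boundaries(arena, cx, cz, within = wall_margin)
    for (bnd in nb) {
      hd <- c(sin(deg2rad(cphi)), cos(deg2rad(cphi)))
      if (sum(hd * bnd$normal) > 0) {
        # walk parallel to the boundary: tangent with the smaller turn
        tang <- atan2(bnd$normal[1], bnd$normal[2]) * 180 / pi + c(90, -90)
        turn <- wrap_angle(tang - cphi)
        cphi <- wrap_angle(cphi + turn[which.min(abs(turn))], 0)
      }
    }
    nx <- cx + vi * dt * sin(deg2rad(cphi))
    nz <- cz + vi * dt * cos(deg2rad(cphi))
    # clamp to the footprint with clearance
    f <- arena$footprint
    if (f$type == "circle") {
      rr <- sqrt(nx^2 + nz^2)
      if (rr > f$r - clearance) {
        s <- (f$r - clearance) / rr; nx <- nx * s; nz <- nz * s
      }
    } else {
      nx <- min(max(nx, -f$hx + clearance), f$hx - clearance)
      nz <- min(max(nz, -f$hz + clearance), f$hz - clearance)
    }
    if (!is.null(iw) && segments_cross(cx, cz, nx, nz, iw)) {
      nx <- cx; nz <- cz  # blocked by the interior wall
    }
    v[i] <- sqrt((nx - cx)^2 + (nz - cz)^2) / dt
    cx <- nx; cz <- nz
    x[i] <- cx; z[i] <- cz; phi[i] <- cphi
  }
  out <- data.frame(t = seq_len(n) * dt, x = x, z = z, phi = phi,
                    v = v, omega = draws$omega)
  class(out) <- c("bvcflow_trajectory", "data.frame")
  out
}

# does the plan segment (x1,z1)-(x2,z2) cross the interior wall?
segments_cross <- function(x1, z1, x2, z2, iw) {
  p <- c(x1, z1); r <- c(x2 - x1, z2 - z1)
  q <- iw[1, ]; s <- iw[2, ] - iw[1, ]
  den <- r[1] * s[2] - r[2] * s[1]
  if (abs(den) < 1e-12) return(FALSE)
  qp <- q - p
  t <- (qp[1] * s[2] - qp[2] * s[1]) / den
  u <- (qp[1] * r[2] - qp[2] * r[1]) / den
  t >= 0 && t <= 1 && u >= 0 && u <= 1
}

#' Fit velocity statistics to a trajectory
#'
#' Maximum-likelihood Rayleigh scale of the realized speeds,
#' `b = sqrt(mean(v^2) / 2)`, and sample mean/SD of the yaw rates.
#'
#' @param trajectory a [generate_trajectory()] data frame (or any data
#'   frame with `v` and `omega`).
#' @return a [velocity_stats()] object.
#' @export
fit_velocity_stats <- function(trajectory) {
  if (nrow(trajectory) < 2) stop("trajectory too short to fit")
  b <- sqrt(mean(trajectory$v^2) / 2)
  sdo <- stats::sd(trajectory$omega)
  velocity_stats(b, mean(trajectory$omega), max(sdo, 1e-12))
}

#' Write / read a trajectory as a delimited table
#'
#' Tab-separated values with a one-line JSON header (prefixed `#`) naming
#' the arena shape and time step.
#'
#' @param trajectory a trajectory data frame.
#' @param path file path.
#' @param arena optional arena whose shape tag goes into the header.
#' @export
write_trajectory <- function(trajectory, path, arena = NULL) {
  hdr <- jsonlite::toJSON(list(arena = if (is.null(arena)) NA else arena$shape_tag,
                               dt = if (nrow(trajectory) > 1) trajectory$t[2] - trajectory$t[1] else NA,
                               n = nrow(trajectory)), auto_unbox = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(trajectory, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: the trajectory data frame with the header
#'   stored in `attr(, "header")`.
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  hdr <- if (startsWith(first, "#")) jsonlite::fromJSON(sub("^#", "", first)) else NULL
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  class(out) <- c("bvcflow_trajectory", "data.frame")
  attr(out, "header") <- hdr
  out
}
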