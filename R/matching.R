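#' Per-node ground match of the rotation-invariant flow constraint
#'
#' With curvilinear self-motion the yaw rotation moves image features purely
#' in azimuth, so the elevation component of the flow is independent of the
#' rotational velocity and scales with `v / D`. The ground matcher compares
#' the observed elevation flow of each node against the ground-plane
#' template `v * s2 / D_g`, maximized over the bank's linear-velocity
#' samples (the best sample has a closed form: round the implied velocity
#' onto the linear grid).
#'
#' @param flow a `bvcflow_flow` input field.
#' @param bank a [template_bank()] on the same camera grid.
#' @return list with `value` (per-node match in (0, 1]; 0 where the node
#'   cannot be ground or carries no flow) and `best_v` (maximizing velocity
#'   sample, NA where invalid).
#' @export
match_ground <- function(flow, bank) {
  check_grid(flow, bank)
  p <- bank$params
  n <- length(bank$s1)
  value <- numeric(n); best_v <- rep(NA_real_, n)
  idx <- which(flow$label != "none" & bank$ground_valid)
  k <- rad2deg(1) * bank$s2[idx] / bank$D_ground[idx]  # template = v * k
  y <- flow$dvarphi[idx]
  vstep <- (p$v_max - p$v_min) / (length(bank$v_samples) - 1)
  vbest <- ifelse(abs(k) > 1e-12, y / k, NA_real_)
  vbest <- pmin(pmax(round((vbest - p$v_min) / vstep) * vstep + p$v_min,
                     p$v_min), p$v_max)
  resid <- ifelse(is.na(vbest), abs(y), abs(y - vbest * k))
  value[idx] <- exp(-resid^2 / (2 * p$sigma_ground^2))
  best_v[idx] <- vbest
  list(value = value, best_v = best_v)
}

#' Per-node wall match of the rotation-invariant flow constraint
#'
#' Counterpart of [match_ground()] for vertical-wall templates: the
#' elevation flow is compared against `vbar * s2 / D_w(alpha, dist)`, where
#' `vbar` is the arithmetic mean of the linear-velocity samples, maximized
#' over the full allocentric-direction x log-distance grid (closed form per
#' direction by rounding on the log-spaced distance grid).
#'
#' @inheritParams match_ground
#' @param pose a [eye_pose()]; the head direction rotates the wall
#'   templates. Zero tilt is assumed by the closed-form matcher.
#' @return list with `value` (per-node match in (0, 1]; 0 where no flow).
#' @export
match_wall <- function(flow, bank, pose) {
  check_grid(flow, bank)
  p <- bank$params
  n <- length(bank$s1)
  value <- numeric(n)
  idx <- which(flow$label != "none")
  vbar <- mean(bank$v_samples)
  Aw <- rad2deg(1) * vbar * bank$s2[idx]
  wazi <- deg2rad(bank$camera$theta[idx] + pose$phi)
  seg_alpha <- seq(0, 360 - p$seg_alpha_step, by = p$seg_alpha_step)
  seg_dist <- exp(seq(log(p$dist_min), log(p$dist_max),
                      length.out = p$seg_n_dist))
  res <- cpp_wall_seg_residual(flow$dvarphi[idx], Aw, bank$cosphi[idx],
                               wazi, seg_alpha, seg_dist)
  value[idx] <- exp(-res^2 / (2 * p$sigma_wall^2))
  value
}

#' Segment a flow field into wall and ground samples
#'
#' Assigns each labeled node to the surface class whose rotation-invariant
#' template explains its elevation flow best; ties go to ground.
#'
#' @inheritParams match_wall
#' @return factor per node with levels `ground`, `wall`, `none`.
#' @export
#' @examples
#' arena <- build_arena("square_box"); cam <- spherical_camera()
#' pose <- eye_pose(20, 3.5, 15, phi = 23); bank <- template_bank(cam)
#' fl <- analytic_flow(cam, pose, self_motion(19, 25), ray_cast(arena, pose, cam))
#' seg <- segment_flow(fl, bank, pose)
#' mean((seg == fl$label)[fl$label != "none"])  # segmentation accuracy
segment_flow <- function(flow, bank, pose) {
  mg <- match_ground(flow, bank)$value
  mw <- match_wall(flow, bank, pose)
  out <- rep("none", length(mg))
  valid <- flow$label != "none"
  out[valid] <- ifelse(mw[valid] > mg[valid], "wall", "ground")
  factor(out, levels = c("ground", "wall", "none"))
}

#' Weighted 1D read-out of a match curve
#'
#' Returns the match-weighted mean of the arguments inside a window of two
#' percent of all argument values, centered on the curve's maximum (first
#' maximum on ties; even window sizes are widened by one cell to keep the
#' window centered; windows are clipped at the grid boundary).
#'
#' @param values match values.
#' @param args argument grid (same length).
#' @param frac window fraction of the grid (default 0.02).
#' @return scalar estimate.
#' @export
#' @examples
#' readout_1d(c(0, 1, 0), c(1, 2, 3))  # 2
readout_1d <- function(values, args, frac = 0.02) {
  stopifnot(length(values) == length(args), length(values) >= 1)
  if (diff(range(values)) == 0) {
    warning("constant match curve; returning first argmax")
    return(args[1])
  }
  i <- which.max(values)
  w <- ceiling(frac * length(values))
  if (w %% 2 == 0) w <- w + 1
  half <- (w - 1) / 2
  win <- max(1, i - half):min(length(values), i + half)
  sw <- sum(values[win])
  if (sw <= 0) return(args[i])
  sum(values[win] * args[win]) / sw
}

#' 2D read-out of the wall match surface
#'
#' Selects every (direction, distance) cell whose match value lies within
#' 70 percent of the surface maximum and returns each as a boundary
#' estimate, weighted by its value relative to the maximum.
#'
#' @param match2d matrix of match values (directions x distances).
#' @param alpha_samples,dist_samples the grids of the two axes.
#' @param level relative threshold (default 0.7).
#' @return data frame with columns `alpha` (deg), `dist` (cm), `weight`
#'   (in (0, 1], maximum 1); zero rows when the surface is empty.
#' @export
readout_2d <- function(match2d, alpha_samples, dist_samples, level = 0.7) {
  if (length(match2d) == 0 || all(!is.finite(match2d))) {
    return(data.frame(alpha = numeric(0), dist = numeric(0),
                      weight = numeric(0)))
  }
  mx <- max(match2d)
  if (mx <= 0) {
    # degenerate surface: no positive evidence
    return(data.frame(alpha = numeric(0), dist = numeric(0),
                      weight = numeric(0)))
  }
  keep <- which(match2d >= level * mx, arr.ind = TRUE)
  data.frame(alpha = alpha_samples[keep[, 1]],
             dist = dist_samples[keep[, 2]],
             weight = match2d[keep] / mx)
}

#' Estimate the linear velocity from ground samples
#'
#' Accumulates, over the segmented ground nodes, the Gaussian match between
#' the observed elevation flow and the ground template for every
#' linear-velocity sample, then applies the 1D read-out.
#'
#' @inheritParams match_ground
#' @param ground_idx integer indices of the segmented ground nodes.
#' @return list with `v_est` (cm/sec) and `match_v` (curve over the bank's
#'   velocity samples).
#' @export
estimate_linear_velocity <- function(flow, ground_idx, bank) {
  if (length(ground_idx) == 0) stop("empty ground set: degenerate segmentation")
  p <- bank$params
  ok <- ground_idx[bank$ground_valid[ground_idx]]
  if (length(ok) == 0) stop("no ground node below the horizon")
  k <- rad2deg(1) * bank$s2[ok] / bank$D_ground[ok]
  y <- flow$dvarphi[ok]
  resid2 <- (y - k %o% bank$v_samples)^2
  # global shift against underflow; rescales the curve, argmax unchanged
  M <- colSums(exp(-(resid2 - min(resid2)) / (2 * p$sigma_speed^2)))
  list(v_est = readout_1d(M, bank$v_samples, p$readout_frac), match_v = M)
}

#' Estimate the rotational velocity from ground samples
#'
#' Builds ground templates at the estimated linear velocity and matches the
#' full two-component flow with a Gaussian of the Euclidean distance over
#' the rotational-velocity samples, then applies the 1D read-out.
#'
#' @inheritParams estimate_linear_velocity
#' @param v_est linear-velocity estimate (cm/sec).
#' @return list with `omega_est` (deg/sec) and `match_omega` curve.
#' @export
estimate_rotational_velocity <- function(flow, ground_idx, bank, v_est) {
  if (length(ground_idx) == 0) stop("empty ground set: degenerate segmentation")
  p <- bank$params
  ok <- ground_idx[bank$ground_valid[ground_idx]]
  if (length(ok) == 0) stop("no ground node below the horizon")
  invD <- 1 / bank$D_ground[ok]
  a <- flow$dtheta[ok] - rad2deg(1) * v_est * bank$s1[ok] * invD
  b <- flow$dvarphi[ok] - rad2deg(1) * v_est * bank$s2[ok] * invD
  M <- cpp_match_rotation(a, b, bank$omega_samples, p$sigma_omega)
  list(omega_est = readout_1d(M, bank$omega_samples, p$readout_frac),
       match_omega = M)
}

#' Speed-direction match surface over wall direction and distance
#'
#' Perrone-style tuning evaluated over the bank's allocentric-direction x
#' log-distance grid: for every wall hypothesis the template flow (built
#' with the estimated self-motion and the hypothesized wall plane) is
#' compared to the observed flow in polar coordinates, as the product of a
#' Gaussian in the difference of log speeds and a Gaussian in the
#' difference of flow directions (minus a small direction-tuning offset).
#' Contributions are accumulated over the segmented wall nodes.
#'
#' @inheritParams estimate_rotational_velocity
#' @param wall_idx indices of the segmented wall nodes.
#' @param pose a [eye_pose()].
#' @param omega_est rotational-velocity estimate (deg/sec).
#' @param method `"exact"` evaluates every (node, direction, distance)
#'   triple; `"binned"` uses the log-distance accumulation approximation
#'   (fast path for trajectory sweeps).
#' @param log_speed compare log speeds (default) or raw speed differences
#'   (with tuning width `sigma_plain` deg/sec); the raw variant exists for
#'   the matcher ablation.
#' @param sigma_plain tuning width of the raw-speed variant (deg/sec).
#' @return matrix (directions x distances) of match values.
#' @export
match_speed_direction <- function(flow, wall_idx, bank, pose, v_est, omega_est,
                                  method = c("exact", "binned"),
                                  log_speed = TRUE, sigma_plain = 5) {
  method <- match.arg(method)
  p <- bank$params
  A <- length(bank$alpha_samples); J <- length(bank$dist_samples)
  if (length(wall_idx) == 0) return(matrix(0, A, J))
  # derotate: remove the (depth-independent) rotational flow component so
  # that speeds compare the 1/D translational field only; the templates are
  # then pure-translation fields at v_est
  dth <- flow$dtheta[wall_idx] + omega_est
  r_in <- sqrt(dth^2 + flow$dvarphi[wall_idx]^2)
  r_in <- pmax(r_in, 1e-6)
  dir_in <- atan2(flow$dvarphi[wall_idx], dth)
  K1 <- rad2deg(1) * v_est * bank$s1[wall_idx]
  K2 <- rad2deg(1) * v_est * bank$s2[wall_idx]
  wazi <- deg2rad(bank$camera$theta[wall_idx] + pose$phi)
  if (!log_speed) {
    return(cpp_match_wall2d_plain(r_in, dir_in, K1, K2, 0,
                                  bank$cosphi[wall_idx], wazi,
                                  bank$alpha_samples, bank$dist_samples,
                                  sigma_plain,
                                  deg2rad(p$sigma_direction),
                                  p$direction_offset))
  }
  if (method == "exact") {
    cpp_match_wall2d(log(r_in), dir_in, K1, K2, 0,
                     bank$cosphi[wall_idx], wazi,
                     bank$alpha_samples, bank$dist_samples,
                     p$sigma_logspeed, deg2rad(p$sigma_direction),
                     p$direction_offset)
  } else {
    cpp_match_wall2d_binned(log(r_in), dir_in, K1, K2, 0,
                            bank$cosphi[wall_idx], wazi,
                            bank$alpha_samples, bank$dist_samples,
                            p$sigma_logspeed, deg2rad(p$sigma_direction),
                            p$direction_offset, 2L)
  }
}

#' Full per-pose boundary estimation pipeline
#'
#' Runs the four template-model stages on one flow field: wall-ground
#' segmentation, linear-velocity estimation, rotational-velocity
#' estimation, and the speed-direction read-out of wall distance and
#' allocentric direction.
#'
#' @inheritParams match_wall
#' @param method matcher variant passed to [match_speed_direction()].
#' @return object of class `bvcflow_match`: `segmentation`, `v_est`,
#'   `omega_est`, `match_v`, `match_omega`, `match_wall_2d`, and
#'   `wall_estimates` (data frame `alpha`, `dist`, `weight`; zero rows when
#'   no wall is visible).
#' @export
#' @examples
#' arena <- build_arena("square_box"); cam <- spherical_camera()
#' pose <- eye_pose(20, 3.5, 15, phi = 23); bank <- template_bank(cam)
#' fl <- analytic_flow(cam, pose, self_motion(19, 25), ray_cast(arena, pose, cam))
#' est <- estimate_boundaries(fl, bank, pose)
#' est$v_est; est$omega_est; head(est$wall_estimates)
estimate_boundaries <- function(flow, bank, pose,
                                method = c("exact", "binned")) {
  method <- match.arg(method)
  p <- bank$params
  seg <- segment_flow(flow, bank, pose)
  gset <- which(seg == "ground")
  wset <- which(seg == "wall")
  lv <- estimate_linear_velocity(flow, gset, bank)
  rv <- estimate_rotational_velocity(flow, gset, bank, lv$v_est)
  m2 <- match_speed_direction(flow, wset, bank, pose, lv$v_est, rv$omega_est,
                              method = method)
  est <- readout_2d(m2, bank$alpha_samples, bank$dist_samples,
                    p$readout2d_level)
  structure(list(segmentation = seg, v_est = lv$v_est,
                 omega_est = rv$omega_est, match_v = lv$match_v,
                 match_omega = rv$match_omega, match_wall_2d = m2,
                 wall_estimates = est, pose = pose),
            class = "bvcflow_match")
}

#' @export
print.bvcflow_match <- function(x, ...) {
  cat(sprintf("<bvcflow_match> v_est = %.2f cm/s, omega_est = %.2f deg/s, %d wall estimate(s)\n",
              x$v_est, x$omega_est, nrow(x$wall_estimates)))
  invisible(x)
}

check_grid <- function(flow, bank) {
  if (length(flow$dtheta) != length(bank$s1))
    stop("flow field and template bank use different camera grids")
  invisible(TRUE)
}
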