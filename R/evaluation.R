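#' Absolute distance error of boundary estimates
#'
#' For every read-out estimate, the ground-truth distance is the plan-view
#' ray-cast distance from the pose to the nearest boundary along the
#' estimate's allocentric direction; the error is the absolute difference
#' to the estimated distance. Directions that never meet a boundary are
#' skipped (and counted).
#'
#' @param estimates data frame with `alpha`, `dist` (and optionally
#'   `weight`).
#' @param pose a [eye_pose()].
#' @param arena a [build_arena()] object.
#' @return data frame `alpha`, `dist`, `truth`, `error` (cm) for the
#'   evaluable estimates, with the number of skipped estimates in
#'   `attr(, "skipped")`.
#' @export
#' @examples
#' sq <- build_arena("square_box")
#' est <- data.frame(alpha = 90, dist = 30)
#' distance_error(est, eye_pose(), sq)$error  # 1 (true half-width is 31)
distance_error <- function(estimates, pose, arena) {
  if (nrow(estimates) == 0) {
    out <- data.frame(alpha = numeric(0), dist = numeric(0),
                      truth = numeric(0), error = numeric(0),
                      weight = numeric(0))
    attr(out, "skipped") <- 0L
    return(out)
  }
  truth <- boundary_distance(arena, pose$x0, pose$z0, estimates$alpha)
  ok <- is.finite(truth)
  out <- data.frame(alpha = estimates$alpha[ok], dist = estimates$dist[ok],
                    truth = truth[ok],
                    error = abs(estimates$dist[ok] - truth[ok]))
  if (!is.null(estimates$weight)) out$weight <- estimates$weight[ok]
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Spatial map of mean absolute distance errors
#'
#' @param x,z plan positions of the evaluated frames.
#' @param errors per-frame mean absolute errors (cm).
#' @param arena a [build_arena()] object.
#' @param bin_size spatial bin in cm (default 5; coarser than rate maps for
#'   stable per-bin means).
#' @return object of class `bvcflow_errormap`: `xb`, `zb`, `mean_error`
#'   matrix and `count` matrix.
#' @export
error_map <- function(x, z, errors, arena, bin_size = 5) {
  hx <- arena$extent[1] / 2; hz <- arena$extent[2] / 2
  xb <- seq(-hx, hx, by = bin_size); zb <- seq(-hz, hz, by = bin_size)
  if (xb[length(xb)] < hx) xb <- c(xb, hx)
  if (zb[length(zb)] < hz) zb <- c(zb, hz)
  ix <- findInterval(x, xb, rightmost.closed = TRUE)
  iz <- findInterval(z, zb, rightmost.closed = TRUE)
  nx <- length(xb) - 1; nz <- length(zb) - 1
  s <- matrix(0, nx, nz); cnt <- matrix(0, nx, nz)
  for (i in seq_along(x)) {
    s[ix[i], iz[i]] <- s[ix[i], iz[i]] + errors[i]
    cnt[ix[i], iz[i]] <- cnt[ix[i], iz[i]] + 1
  }
  m <- s / cnt; m[cnt == 0] <- NA
  structure(list(xb = xb[-length(xb)] + diff(xb) / 2,
                 zb = zb[-length(zb)] + diff(zb) / 2,
                 mean_error = m, count = cnt, bin_size = bin_size),
            class = "bvcflow_errormap")
}

#' Run the boundary-estimation pipeline along a trajectory
#'
#' For every evaluated frame: cast rays, synthesize the analytical flow for
#' the frame's realized self-motion, optionally perturb it with Gaussian
#' noise, run segmentation / self-motion estimation / wall read-out, and
#' score the distance estimates against ray-cast ground truth.
#'
#' @param arena a [build_arena()] object.
#' @param trajectory a [generate_trajectory()] data frame.
#' @param bank a [template_bank()].
#' @param subsample evaluate every `subsample`-th frame (default 10, i.e.
#'   5 Hz of the 50 Hz trajectory).
#' @param noise_sigma flow noise in deg/sec (0 = analytical flow).
#' @param method matcher variant (`"binned"` fast path by default).
#' @param keep_estimates keep the per-frame estimate tables.
#' @return list with `frames` (data frame: `t`, `x`, `z`, `phi`, `v`,
#'   `omega`, `v_est`, `omega_est`, `n_est`, `mean_error`, `seg_accuracy`),
#'   `mean_error` (mean over all estimates), `n_estimates`, and optionally
#'   `estimates`.
#' @export
boundary_error_run <- function(arena, trajectory, bank,
                               subsample = 10, noise_sigma = 0,
                               method = c("binned", "exact"),
                               keep_estimates = FALSE) {
  method <- match.arg(method)
  p <- bank$params
  cam <- bank$camera
  rows <- seq(1, nrow(trajectory), by = subsample)
  frames <- trajectory[rows, , drop = FALSE]
  n <- nrow(frames)
  v_est <- omega_est <- mean_err <- seg_acc <- rep(NA_real_, n)
  n_est <- integer(n)
  err_sum <- 0; err_n <- 0
  all_est <- if (keep_estimates) vector("list", n) else NULL
  for (i in seq_len(n)) {
    pose <- eye_pose(frames$x[i], p$eye_height, frames$z[i],
                     phi = frames$phi[i])
    hit <- ray_cast(arena, pose, cam, p)
    fl <- analytic_flow(cam, pose, self_motion(frames$v[i], frames$omega[i]),
                        hit, p)
    if (noise_sigma > 0) fl <- add_flow_noise(fl, noise_sigma)
    est <- estimate_boundaries(fl, bank, pose, method = method)
    v_est[i] <- est$v_est; omega_est[i] <- est$omega_est
    lab <- fl$label != "none"
    seg_acc[i] <- mean((est$segmentation == fl$label)[lab])
    de <- distance_error(est$wall_estimates, pose, arena)
    n_est[i] <- nrow(de)
    if (nrow(de) > 0) {
      mean_err[i] <- mean(de$error)
      err_sum <- err_sum + sum(de$error); err_n <- err_n + nrow(de)
    }
    if (keep_estimates) all_est[[i]] <- cbind(frame = i, de)
  }
  out <- list(frames = cbind(frames, v_est = v_est, omega_est = omega_est,
                             n_est = n_est, mean_error = mean_err,
                             seg_accuracy = seg_acc),
              mean_error = if (err_n > 0) err_sum / err_n else NA_real_,
              n_estimates = err_n)
  if (keep_estimates) out$estimates <- do.call(rbind, all_est)
  out
}

#' Compare the log-speed and plain-speed wall matchers at one pose
#'
#' Runs the full pipeline twice on the same flow field, once with the
#' log-speed tuning of the wall matcher and once with the raw
#' speed-difference tuning, and reports the mean absolute distance error of
#' each (the ablation of the logarithmic speed comparison).
#'
#' @param arena,pose,motion scene and self-motion.
#' @param bank a [template_bank()].
#' @param sigma_plain tuning width of the raw-speed matcher, deg/sec.
#' @return list with `log_error`, `plain_error` (cm) and the two estimate
#'   tables.
#' @export
compare_speed_matchers <- function(arena, pose, motion, bank,
                                   sigma_plain = 5) {
  p <- bank$params
  hit <- ray_cast(arena, pose, bank$camera, p)
  fl <- analytic_flow(bank$camera, pose, motion, hit, p)
  seg <- segment_flow(fl, bank, pose)
  gset <- which(seg == "ground"); wset <- which(seg == "wall")
  lv <- estimate_linear_velocity(fl, gset, bank)
  rv <- estimate_rotational_velocity(fl, gset, bank, lv$v_est)
  res <- lapply(c(TRUE, FALSE), function(use_log) {
    m2 <- match_speed_direction(fl, wset, bank, pose, lv$v_est, rv$omega_est,
                                method = "exact", log_speed = use_log,
                                sigma_plain = sigma_plain)
    est <- readout_2d(m2, bank$alpha_samples, bank$dist_samples,
                      p$readout2d_level)
    de <- distance_error(est, pose, arena)
    list(error = mean(de$error), estimates = de)
  })
  list(log_error = res[[1]]$error, plain_error = res[[2]]$error,
       log_estimates = res[[1]]$estimates, plain_estimates = res[[2]]$estimates)
}

#' Run a full simulation experiment
#'
#' Drives the whole pipeline from a single configuration: trajectory
#' generation, boundary estimation along the trajectory, distance-error
#' statistics and maps, fitted velocity statistics, and (optionally)
#' BVC rate maps, written to an output directory with a machine-readable
#' summary.
#'
#' @param config list with elements `arena` (shape tag or arena object),
#'   `stats` (velocity stats; defaults to the recorded fits for the arena
#'   class), `duration_s` (default 1200), `subsample` (default 10),
#'   `noise_sigma` (default 0), `seed`, `bvc` (logical: accumulate rate
#'   maps for the standard battery; default FALSE), `bin_size` rate-map bin
#'   (2), `error_bin` error-map bin (5).
#' @param outdir output directory (created if missing); `NULL` skips
#'   writing.
#' @return list with `trajectory`, `run` (see [boundary_error_run()]),
#'   `fitted_stats`, `error_map`, optional `rate_maps`, and `summary`
#'   (named list of scalar results).
#' @export
run_experiment <- function(config, outdir = NULL) {
  arena <- config$arena
  if (is.character(arena)) arena <- build_arena(arena)
  circ <- arena$footprint$type == "circle"
  stats <- config$stats
  if (is.null(stats))
    stats <- recorded_velocity_stats(if (circ) "circular" else "square")
  if (!is.null(config$seed)) set.seed(config$seed)
  duration <- if (is.null(config$duration_s)) 1200 else config$duration_s
  subsample <- if (is.null(config$subsample)) 10 else config$subsample
  noise <- if (is.null(config$noise_sigma)) 0 else config$noise_sigma
  params <- if (is.null(config$params)) flow_model_params() else config$params
  traj <- generate_trajectory(arena, stats, duration_s = duration)
  bank <- template_bank(spherical_camera(), params)
  run <- boundary_error_run(arena, traj, bank, subsample = subsample,
                            noise_sigma = noise, keep_estimates = TRUE)
  fit <- fit_velocity_stats(traj)
  per_frame <- run$frames
  ok <- is.finite(per_frame$mean_error)
  em <- error_map(per_frame$x[ok], per_frame$z[ok], per_frame$mean_error[ok],
                  arena,
                  bin_size = if (is.null(config$error_bin)) 5 else config$error_bin)
  out <- list(trajectory = traj, run = run, fitted_stats = fit,
              error_map = em)
  if (isTRUE(config$bvc)) {
    battery <- bvc_battery(params)
    act <- t(vapply(seq_len(nrow(per_frame)), function(i) {
      est <- run$estimates[run$estimates$frame == i, , drop = FALSE]
      bvc_activation(battery, est)
    }, numeric(length(battery))))
    colnames(act) <- names(battery)
    out$rate_maps <- accumulate_rate_map(per_frame$x, per_frame$z, act, arena,
                                         bin_size = if (is.null(config$bin_size)) 2 else config$bin_size)
  }
  out$summary <- list(arena = arena$shape_tag,
                      mean_distance_error_cm = run$mean_error,
                      n_estimates = run$n_estimates,
                      fitted_rayleigh_b = fit$rayleigh_b,
                      fitted_omega_mu = fit$normal_mu,
                      fitted_omega_sigma = fit$normal_sigma,
                      mean_seg_accuracy = mean(per_frame$seg_accuracy, na.rm = TRUE))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(traj, file.path(outdir, "trajectory.tsv"), arena)
    utils::write.table(round(em$mean_error, 4),
                       file.path(outdir, "error_map.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(out$summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
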