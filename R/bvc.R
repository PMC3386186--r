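#' Boundary-vector-cell tuning
#'
#' A BVC is tuned to boundaries at a preferred allocentric direction and
#' preferred distance. The radial tuning width grows linearly with the
#' preferred distance, `sigma_rad(D) = sigma0 * (D / beta + 1)` (the
#' standard convention of the BVC model literature); the angular width is
#' constant.
#'
#' @param distance preferred distance in cm (> 0).
#' @param direction preferred allocentric direction in degrees.
#' @param params a [flow_model_params()].
#' @return object of class `bvcflow_bvc` with `distance`, `direction`,
#'   `sigma_rad`, `sigma_ang`.
#' @export
bvc_tuning <- function(distance, direction, params = flow_model_params()) {
  stopifnot(distance > 0)
  structure(list(distance = distance, direction = wrap_angle(direction, 0),
                 sigma_rad = params$bvc_sigma0 * (distance / params$bvc_beta + 1),
                 sigma_ang = params$bvc_sigma_ang), class = "bvcflow_bvc")
}

#' Standard battery of BVC tunings
#'
#' Eight allocentric directions (every 45 degrees from 0 = +z) crossed with
#' preferred distances of 2, 10 and 25 cm.
#'
#' @param params a [flow_model_params()].
#' @param distances,directions override the default grids.
#' @return list of [bvc_tuning()] objects, named `"<direction>deg_<distance>cm"`.
#' @export
bvc_battery <- function(params = flow_model_params(),
                        distances = c(2, 10, 25),
                        directions = seq(0, 315, by = 45)) {
  cells <- list()
  for (d in distances) for (a in directions) {
    cells[[sprintf("%ddeg_%gcm", a, d)]] <- bvc_tuning(d, a, params)
  }
  cells
}

#' BVC activation for a set of boundary estimates
#'
#' Sums, over all read-out estimates `(alpha_k, d_j, w_kj)`, the product of
#' a Gaussian of the distance mismatch (width `sigma_rad`), a Gaussian of
#' the wrapped angular mismatch (width `sigma_ang`) and the normalized
#' match weight.
#'
#' @param tuning a [bvc_tuning()] (or a list of them).
#' @param estimates data frame with `alpha`, `dist`, `weight` (weights
#'   normalized to maximum 1).
#' @return activation in arbitrary units (vector when `tuning` is a list);
#'   0 for an empty estimate list.
#' @export
#' @examples
#' est <- data.frame(alpha = 90, dist = 10, weight = 1)
#' bvc_activation(bvc_tuning(10, 90), est)
bvc_activation <- function(tuning, estimates) {
  if (inherits(tuning, "bvcflow_bvc")) tuning <- list(tuning)
  vapply(tuning, function(tu) {
    if (nrow(estimates) == 0) return(0)
    gd <- exp(-(estimates$dist - tu$distance)^2 / (2 * tu$sigma_rad^2))
    da <- wrap_angle(estimates$alpha - tu$direction)
    ga <- exp(-da^2 / (2 * tu$sigma_ang^2))
    sum(gd * ga * estimates$weight)
  }, numeric(1))
}

#' Ground-truth boundary estimates at a pose
#'
#' The ground-truth-driven BVC input: each boundary surface contributes one
#' estimate in its perpendicular (Hessian) representation — the allocentric
#' direction of the surface normal as seen from the pose and the
#' perpendicular distance to it — with weight 1. A square box therefore
#' yields up to four values, an interior wall one more, and circular
#' boundaries one radial value; this bypasses the flow pipeline and
#' reproduces the classical BVC model input.
#'
#' @param arena a [build_arena()] object.
#' @param pose a [eye_pose()] (only the plan position is used).
#' @return data frame with `alpha` (deg), `dist` (cm), `weight`.
#' @export
gt_boundary_estimates <- function(arena, pose) {
  x <- pose$x0; z <- pose$z0
  alpha <- dist <- numeric(0)
  f <- arena$footprint
  if (f$type == "circle") {
    rr <- sqrt(x^2 + z^2)
    alpha <- if (rr > 1e-9) atan2(x, z) * 180 / pi else 0
    dist <- f$r - rr
  } else {
    segs <- arena$segments
    for (i in seq_len(nrow(segs))) {
      p1 <- c(segs[i, 1], segs[i, 2]); p2 <- c(segs[i, 3], segs[i, 4])
      e <- p2 - p1
      tt <- sum((c(x, z) - p1) * e) / sum(e^2)
      if (tt < -1e-9 || tt > 1 + 1e-9) next  # foot outside the segment
      foot <- p1 + tt * e
      v <- foot - c(x, z)
      d <- sqrt(sum(v^2))
      if (d < 1e-9) next
      alpha <- c(alpha, atan2(v[1], v[2]) * 180 / pi)
      dist <- c(dist, d)
    }
  }
  data.frame(alpha = wrap_angle(alpha, 0), dist = dist,
             weight = rep(1, length(dist)))
}

#' Accumulate occupancy-normalized spatial rate maps
#'
#' Bins the trajectory positions on a square grid over the arena footprint
#' and accumulates, per bin, the summed activation and the occupancy count;
#' the rate is their ratio (NA where the bin was never visited).
#'
#' @param x,z plan positions (cm) of the frames used.
#' @param activations numeric matrix, one row per frame and one column per
#'   cell (or a vector for a single cell).
#' @param arena a [build_arena()] object.
#' @param bin_size bin side length in cm (default 2).
#' @return object of class `bvcflow_ratemap`: list with `xb`, `zb` (bin
#'   centers), `occupancy` matrix and `rate` (list of matrices, one per
#'   cell).
#' @export
accumulate_rate_map <- function(x, z, activations, arena, bin_size = 2) {
  if (is.vector(activations)) activations <- matrix(activations, ncol = 1)
  stopifnot(length(x) == nrow(activations))
  hx <- arena$extent[1] / 2; hz <- arena$extent[2] / 2
  if (bin_size > 2 * hx || bin_size > 2 * hz)
    stop("bin size exceeds the arena extent")
  xb <- seq(-hx, hx, by = bin_size); zb <- seq(-hz, hz, by = bin_size)
  if (xb[length(xb)] < hx) xb <- c(xb, hx)
  if (zb[length(zb)] < hz) zb <- c(zb, hz)
  ix <- findInterval(x, xb, rightmost.closed = TRUE)
  iz <- findInterval(z, zb, rightmost.closed = TRUE)
  nx <- length(xb) - 1; nz <- length(zb) - 1
  occ <- matrix(0, nx, nz)
  for (i in seq_along(x)) occ[ix[i], iz[i]] <- occ[ix[i], iz[i]] + 1
  rate <- lapply(seq_len(ncol(activations)), function(k) {
    s <- matrix(0, nx, nz)
    a <- activations[, k]
    for (i in seq_along(x)) s[ix[i], iz[i]] <- s[ix[i], iz[i]] + a[i]
    out <- s / occ
    out[occ == 0] <- NA
    out
  })
  names(rate) <- colnames(activations)
  structure(list(xb = xb[-length(xb)] + diff(xb) / 2,
                 zb = zb[-length(zb)] + diff(zb) / 2,
                 occupancy = occ, rate = rate, bin_size = bin_size),
            class = "bvcflow_ratemap")
}

#' Location of the rate-map maximum
#'
#' @param ratemap a [accumulate_rate_map()] result.
#' @param cell cell index or name.
#' @param smooth half-width (bins) of a box filter applied before the
#'   argmax; `1` gives the 3 x 3 smoothing conventional for firing-rate
#'   maps, `0` uses the raw map.
#' @return named vector `c(x, z)` of the argmax bin center.
#' @export
rate_map_argmax <- function(ratemap, cell = 1, smooth = 0) {
  r <- ratemap$rate[[cell]]
  if (smooth > 0) {
    n <- nrow(r); k <- ncol(r); sm <- r
    for (i in seq_len(n)) for (j in seq_len(k)) {
      sm[i, j] <- mean(r[max(1, i - smooth):min(n, i + smooth),
                         max(1, j - smooth):min(k, j + smooth)], na.rm = TRUE)
    }
    r <- sm
  }
  i <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(x = ratemap$xb[i[1]], z = ratemap$zb[i[2]])
}
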