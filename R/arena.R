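#' Build a parametric arena
#'
#' Constructs one of the four standard arenas as a labeled triangular mesh
#' plus the plan-view geometry the rest of the pipeline needs (wall segments,
#' footprint, wall height). The world frame is left-handed with x to the
#' right, y up and z forward at head direction 0; the arena is centered on
#' the origin and the ground lies in y = 0.
#'
#' Shapes:
#' \describe{
#'   \item{circular_box}{cylindrical wall of `diameter` (default 79 cm),
#'     meshed as `n_segments` planar facets.}
#'   \item{square_box}{axis-aligned box of `side` x `side` (default 62 cm).}
#'   \item{square_box_interior_wall}{square box with an additional two-sided
#'     interior wall; by default a segment of half the box side, centered on
#'     the origin and running along z, leaving a narrow passage at each end.}
#'   \item{circular_platform}{ground disc of `diameter` with no walls
#'     (drop-off at the rim).}
#' }
#'
#' @param shape one of `"circular_box"`, `"square_box"`,
#'   `"square_box_interior_wall"`, `"circular_platform"`.
#' @param diameter diameter in cm for circular shapes.
#' @param side side length in cm for square shapes; a length-2 vector
#'   gives a rectangular box (x extent, z extent).
#' @param wall_height wall height in cm (50 by default; ignored for the
#'   platform).
#' @param n_segments number of planar facets for circular walls/rims.
#' @param interior_wall 2x2 matrix of plan endpoints (rows `(x, z)`) for the
#'   interior wall; default spans half the box through the center.
#' @return An object of class `bvcflow_arena`: list with `shape_tag`,
#'   `segments` (plan wall segments, one row `(x1, z1, x2, z2)` each),
#'   `footprint` (`circle` with radius or `rect` with half-widths),
#'   `wall_height`, `extent`, and `has_walls`.
#' @export
#' @examples
#' arena <- build_arena("circular_box")
#' arena$footprint$r
build_arena <- function(shape = c("circular_box", "square_box",
                                  "square_box_interior_wall",
                                  "circular_platform"),
                        diameter = 79, side = 62, wall_height = 50,
                        n_segments = 128, interior_wall = NULL) {
  shape <- match.arg(shape)
  stopifnot(diameter > 0, side > 0, wall_height >= 0, n_segments >= 64)

  circle_segments <- function(r, n) {
    th <- seq(0, 2 * pi, length.out = n + 1)
    cbind(r * sin(th[-(n + 1)]), r * cos(th[-(n + 1)]),
          r * sin(th[-1]),       r * cos(th[-1]))
  }
  rect_segments <- function(hx, hz) {
    rbind(c(-hx, -hz,  hx, -hz),
          c( hx, -hz,  hx,  hz),
          c( hx,  hz, -hx,  hz),
          c(-hx,  hz, -hx, -hz))
  }

  if (shape == "circular_box") {
    segs <- circle_segments(diameter / 2, n_segments)
    foot <- list(type = "circle", r = diameter / 2)
    extent <- c(diameter, diameter)
    has_walls <- TRUE
    interior <- NULL
  } else if (shape == "square_box") {
    side <- rep_len(side, 2)  # (x extent, z extent); rectangles allowed
    segs <- rect_segments(side[1] / 2, side[2] / 2)
    foot <- list(type = "rect", hx = side[1] / 2, hz = side[2] / 2)
    extent <- side
    has_walls <- TRUE
    interior <- NULL
  } else if (shape == "square_box_interior_wall") {
    side <- rep_len(side, 2)
    if (is.null(interior_wall)) {
      interior_wall <- rbind(c(0, -side[2] / 4), c(0, side[2] / 4))
    }
    stopifnot(is.matrix(interior_wall), all(dim(interior_wall) == c(2, 2)))
    segs <- rbind(rect_segments(side[1] / 2, side[2] / 2),
                  c(interior_wall[1, ], interior_wall[2, ]))
    foot <- list(type = "rect", hx = side[1] / 2, hz = side[2] / 2)
    extent <- side
    has_walls <- TRUE
    interior <- interior_wall
  } else { # circular_platform
    segs <- matrix(numeric(0), ncol = 4)
    foot <- list(type = "circle", r = diameter / 2)
    extent <- c(diameter, diameter)
    has_walls <- FALSE
    wall_height <- 0
    interior <- NULL
  }
  colnames(segs) <- c("x1", "z1", "x2", "z2")
  structure(list(shape_tag = shape, segments = segs, footprint = foot,
                 wall_height = wall_height, extent = extent,
                 has_walls = has_walls, interior_wall = interior),
            class = "bvcflow_arena")
}

#' @export
print.bvcflow_arena <- function(x, ...) {
  cat(sprintf("<bvcflow_arena> %s, extent %g x %g cm, wall height %g cm, %d wall segment(s)\n",
              x$shape_tag, x$extent[1], x$extent[2], x$wall_height,
              nrow(x$segments)))
  invisible(x)
}

#' Triangular mesh of an arena
#'
#' Expands the plan geometry into labeled 3D triangles: every wall segment
#' becomes two triangles spanning y in `[0, wall_height]` (orthogonal to the
#' ground by construction), and the ground becomes a triangle fan (circular
#' footprint) or two triangles (square footprint) in y = 0.
#'
#' @param arena a [build_arena()] object.
#' @param n_ground number of fan triangles for a circular ground.
#' @return list with `vertices` (n x 9 matrix: the three corners of each
#'   triangle as `(x, y, z)` triples) and `label` (`"ground"` or `"wall"`).
#' @export
arena_mesh <- function(arena, n_ground = 128) {
  tri <- list(); lab <- character(0)
  segs <- arena$segments
  h <- arena$wall_height
  if (nrow(segs) > 0 && h > 0) {
    for (i in seq_len(nrow(segs))) {
      a <- c(segs[i, 1], 0, segs[i, 2]); b <- c(segs[i, 3], 0, segs[i, 4])
      a2 <- a + c(0, h, 0); b2 <- b + c(0, h, 0)
      tri[[length(tri) + 1]] <- c(a, b, b2); lab <- c(lab, "wall")
      tri[[length(tri) + 1]] <- c(a, b2, a2); lab <- c(lab, "wall")
    }
  }
  f <- arena$footprint
  if (f$type == "circle") {
    th <- seq(0, 2 * pi, length.out = n_ground + 1)
    for (i in seq_len(n_ground)) {
      a <- c(f$r * sin(th[i]), 0, f$r * cos(th[i]))
      b <- c(f$r * sin(th[i + 1]), 0, f$r * cos(th[i + 1]))
      tri[[length(tri) + 1]] <- c(0, 0, 0, a, b); lab <- c(lab, "ground")
    }
  } else {
    hx <- f$hx; hz <- f$hz
    tri[[length(tri) + 1]] <- c(-hx, 0, -hz, hx, 0, -hz, hx, 0, hz)
    tri[[length(tri) + 1]] <- c(-hx, 0, -hz, hx, 0, hz, -hx, 0, hz)
    lab <- c(lab, "ground", "ground")
  }
  list(vertices = do.call(rbind, tri), label = lab)
}

#' Test whether plan points lie inside the arena footprint
#'
#' @param arena a [build_arena()] object.
#' @param x,z plan coordinates in cm (vectorized).
#' @param margin shrink the footprint by this clearance in cm.
#' @return logical vector.
#' @export
in_footprint <- function(arena, x, z, margin = 0) {
  f <- arena$footprint
  if (f$type == "circle") {
    sqrt(x^2 + z^2) <= f$r - margin
  } else {
    abs(x) <= f$hx - margin & abs(z) <= f$hz - margin
  }
}

# 2D ray / segment intersection distances.
# Returns the smallest positive t with (x, z) + t * (sin a, cos a) on a wall
# segment (Inf when the ray escapes). Vectorized over `alpha`.
ray_segment_dist <- function(segments, x, z, alpha) {
  dx <- sin(deg2rad(alpha)); dz <- cos(deg2rad(alpha))
  best <- rep(Inf, length(alpha))
  if (nrow(segments) == 0) return(best)
  for (i in seq_len(nrow(segments))) {
    x1 <- segments[i, 1]; z1 <- segments[i, 2]
    x2 <- segments[i, 3]; z2 <- segments[i, 4]
    ex <- x2 - x1; ez <- z2 - z1
    den <- dx * (-ez) + dz * ex           # cross(dir, edge) with z-forward
    s  <- ((x1 - x) * (-ez) + (z1 - z) * ex) / den
    u  <- (dx * (z1 - z) - dz * (x1 - x)) / den
    ok <- is.finite(s) & s > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
    best <- ifelse(ok & s < best, s, best)
  }
  unname(best)
}

#' Ground-truth boundary distance along an allocentric direction
#'
#' Plan-view distance from `(x, z)` to the nearest boundary along direction
#' `alpha` (degrees, measured from +z toward +x). For boxes the boundary is
#' the nearest wall segment; for the platform it is the rim of the ground
#' disc. Directions that never meet a boundary return `Inf`.
#'
#' @param arena a [build_arena()] object.
#' @param x,z plan position in cm.
#' @param alpha allocentric directions in degrees (vectorized).
#' @return distances in cm.
#' @export
#' @examples
#' sq <- build_arena("square_box")
#' boundary_distance(sq, 0, 0, c(0, 90))  # 31 31
boundary_distance <- function(arena, x, z, alpha) {
  stopifnot(in_footprint(arena, x, z))
  if (arena$has_walls) {
    ray_segment_dist(arena$segments, x, z, alpha)
  } else {
    # circle rim: |p + t d| = r
    r <- arena$footprint$r
    dx <- sin(deg2rad(alpha)); dz <- cos(deg2rad(alpha))
    b <- x * dx + z * dz
    disc <- b^2 - (x^2 + z^2 - r^2)
    -b + sqrt(pmax(disc, 0))
  }
}

# Nearest-boundary query used by the trajectory wall-avoidance rule.
# Returns up to two boundary records (distance, outward unit normal pointing
# from the agent toward the boundary) for all boundary entities within
# `within` cm. Platform rims count as boundaries for locomotion.
nearest_boundaries <- function(arena, x, z, within = Inf) {
  out <- list()
  f <- arena$footprint
  if (f$type == "circle") {
    rr <- sqrt(x^2 + z^2)
    d <- f$r - rr
    if (d <= within) {
      n <- if (rr > 1e-9) c(x, z) / rr else c(0, 1)
      out[[length(out) + 1]] <- list(dist = d, normal = n)
    }
  } else {
    dxp <- f$hx - x; dxm <- f$hx + x
    dzp <- f$hz - z; dzm <- f$hz + z
    if (dxp <= within) out[[length(out) + 1]] <- list(dist = dxp, normal = c(1, 0))
    if (dxm <= within) out[[length(out) + 1]] <- list(dist = dxm, normal = c(-1, 0))
    if (dzp <= within) out[[length(out) + 1]] <- list(dist = dzp, normal = c(0, 1))
    if (dzm <= within) out[[length(out) + 1]] <- list(dist = dzm, normal = c(0, -1))
  }
  iw <- arena$interior_wall
  if (!is.null(iw)) {
    p1 <- iw[1, ]; p2 <- iw[2, ]; e <- p2 - p1
    len2 <- sum(e^2)
    t <- max(0, min(1, ((x - p1[1]) * e[1] + (z - p1[2]) * e[2]) / len2))
    q <- p1 + t * e
    v <- c(x, z) - q
    d <- sqrt(sum(v^2))
    if (d <= within && d > 1e-9) {
      out[[length(out) + 1]] <- list(dist = d, normal = -v / d)
    }
  }
  out
}
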