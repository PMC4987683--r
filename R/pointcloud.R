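#' One frame of a segmented GFP point cloud
#'
#' @param time frame time in hours.
#' @param points data.frame with columns `x_um`, `y_um`, `z_um` (finite)
#'   and `intensity` (>= 0).
#' @return An object of class `"point_cloud_frame"`.
#' @export
point_cloud_frame <- function(time, points) {
  points <- as.data.frame(points)
  need <- c("x_um", "y_um", "z_um", "intensity")
  if (!all(need %in% names(points)))
    stop("'points' must have columns x_um, y_um, z_um, intensity",
         call. = FALSE)
  if (nrow(points) > 0) {
    if (!all(is.finite(as.matrix(points[, c("x_um", "y_um", "z_um")]))))
      stop("coordinates must be finite", call. = FALSE)
    if (any(points$intensity < 0))
      stop("intensity must be >= 0", call. = FALSE)
  }
  structure(list(time = time, points = points), class = "point_cloud_frame")
}

#' @export
print.point_cloud_frame <- function(x, ...) {
  cat(sprintf("Point cloud frame at t = %.1f h: %d points\n",
              x$time, nrow(x$points)))
  invisible(x)
}

# Count, for each point, how many OTHER points lie within `radius`
# (Euclidean). Small clouds use chunked dense distances; larger clouds
# are binned on a grid of cell size `radius` so only the 27 surrounding
# cells are compared (identical result, near-linear cost).
neighbor_counts <- function(xyz, radius, chunk = 512L) {
  n <- nrow(xyz)
  if (n == 0L) return(integer(0))
  if (n > 600L) return(neighbor_counts_grid(xyz, radius))
  sq <- rowSums(xyz^2)
  r2 <- radius^2
  counts <- integer(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    idx <- i0:i1
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(xyz[idx, , drop = FALSE], xyz)
    counts[idx] <- as.integer(rowSums(d2 <= r2 + 1e-9)) - 1L   # exclude self
  }
  counts
}

neighbor_counts_grid <- function(xyz, radius) {
  n <- nrow(xyz)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min), "-") / radius)
  span <- apply(cell, 2, max) + 3L   # headroom for +/-1 neighbor offsets
  key <- function(cx, cy, cz) (cx * span[2] + cy) * span[3] + cz
  keys <- key(cell[, 1], cell[, 2], cell[, 3])
  by_cell <- split(seq_len(n), keys)
  lookup <- new.env(hash = TRUE, size = length(by_cell) * 2L)
  for (nm in names(by_cell)) assign(nm, by_cell[[nm]], envir = lookup)
  r2 <- radius^2
  counts <- integer(n)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (nm in names(by_cell)) {
    idx <- by_cell[[nm]]
    c0 <- cell[idx[1], ]
    cand <- unlist(lapply(seq_len(27), function(o) {
      k <- as.character(key(c0[1] + offsets[o, 1], c0[2] + offsets[o, 2],
                            c0[3] + offsets[o, 3]))
      if (exists(k, envir = lookup, inherits = FALSE))
        get(k, envir = lookup) else NULL
    }), use.names = FALSE)
    a <- xyz[idx, , drop = FALSE]
    b <- xyz[cand, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    counts[idx] <- as.integer(rowSums(d2 <= r2 + 1e-9)) - 1L
  }
  counts
}

#' Close-neighbor clutter filter
#'
#' Removes segmentation points with fewer than `min_neighbors` other
#' points within `neighbor_radius` (Euclidean distance in um). Isolated
#' clutter (stray segmentation of debris) has few close neighbors, while
#' genuine reporter-positive regions are dense. The filter is a single
#' pass over the original cloud: neighbor counts are taken on the input,
#' not recomputed as points drop out, so re-applying it to its own output
#' may remove further points.
#'
#' @param frame a [point_cloud_frame()].
#' @param min_neighbors minimal number of neighbors (self excluded) a
#'   point must have to be retained; default 5.
#' @param neighbor_radius neighborhood radius in um; default 40.
#' @return A filtered [point_cloud_frame()]; output points are a subset of
#'   the input points.
#' @export
neighbor_filter <- function(frame, min_neighbors = 5, neighbor_radius = 40) {
  stopifnot(min_neighbors >= 0, neighbor_radius > 0)
  pts <- frame$points
  if (nrow(pts) == 0L) return(frame)
  xyz <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
  keep <- neighbor_counts(xyz, neighbor_radius) >= min_neighbors
  point_cloud_frame(frame$time, pts[keep, , drop = FALSE])
}

#' Bounding-box clutter filter
#'
#' Retains points inside a closed axis-aligned box, removing plate and
#' agar clutter far from the EB. Points exactly on a face are retained.
#'
#' @param frame a [point_cloud_frame()].
#' @param box numeric of length 6: `c(xmin, xmax, ymin, ymax, zmin, zmax)`
#'   in um; each axis must have positive extent.
#' @return A filtered [point_cloud_frame()].
#' @export
bbox_filter <- function(frame, box) {
  stopifnot(is.numeric(box), length(box) == 6L)
  if (box[2] <= box[1] || box[4] <= box[3] || box[6] <= box[5])
    stop("degenerate bounding box: each axis needs positive extent",
         call. = FALSE)
  pts <- frame$points
  keep <- pts$x_um >= box[1] & pts$x_um <= box[2] &
    pts$y_um >= box[3] & pts$y_um <= box[4] &
    pts$z_um >= box[5] & pts$z_um <= box[6]
  point_cloud_frame(frame$time, pts[keep, , drop = FALSE])
}

#' Number of points in a (filtered) frame
#'
#' @param frame a [point_cloud_frame()].
#' @return Non-negative integer point count.
#' @export
count_points <- function(frame) {
  nrow(frame$points)
}

# --- minimal enclosing circle (Welzl) -------------------------------------

circle_from2 <- function(a, b) {
  c(center = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
}

circle_from3 <- function(a, b, c3) {
  d <- 2 * (a[1] * (b[2] - c3[2]) + b[1] * (c3[2] - a[2]) +
              c3[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    # collinear: fall back to the widest pair
    cands <- list(circle_from2(a, b), circle_from2(a, c3), circle_from2(b, c3))
    return(cands[[which.max(vapply(cands, function(z) z[3], numeric(1)))]])
  }
  ux <- (sum(a^2) * (b[2] - c3[2]) + sum(b^2) * (c3[2] - a[2]) +
           sum(c3^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c3[1] - b[1]) + sum(b^2) * (a[1] - c3[1]) +
           sum(c3^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  c(center = ctr, r = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-7) {
  sqrt(sum((p - circ[1:2])^2)) <= circ[3] * (1 + tol) + tol
}

# Iterative move-to-front Welzl; deterministic given input order.
min_enclosing_circle <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(c(pts[1, ], r = 0))
  circ <- circle_from2(pts[1, ], pts[2, ])
  if (n == 2L) return(circ)
  for (i in 3:n) {
    if (in_circle(circ, pts[i, ])) next
    # point i is on the boundary of the new circle
    circ <- circle_from2(pts[1, ], pts[i, ])
    for (j in 2:(i - 1L)) {
      if (in_circle(circ, pts[j, ])) next
      circ <- circle_from2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (!in_circle(circ, pts[k, ]))
          circ <- circle_from3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circ
}

#' EB radius by circumscribed (minimal enclosing) circle
#'
#' Estimates the EB radius as the radius of the minimal enclosing circle
#' of the 2D projection of its outline points, mirroring radius
#' measurement from a single projected image. Invariant to point order
#' and to rigid rotation of the projected cloud.
#'
#' @param points_2d matrix or data.frame with two columns (x, y in um), or
#'   a [point_cloud_frame()] (projected on the xy plane).
#' @return Radius in um (0 for a single point).
#' @export
estimate_radius <- function(points_2d) {
  if (inherits(points_2d, "point_cloud_frame"))
    points_2d <- points_2d$points[, c("x_um", "y_um")]
  pts <- as.matrix(points_2d)
  if (nrow(pts) == 0L) stop("need at least one point", call. = FALSE)
  storage.mode(pts) <- "double"
  unname(min_enclosing_circle(pts[, 1:2, drop = FALSE])[3])
}

#' GFP volume occupancy of an EB
#'
#' The ratio between the total number of segmentation spots and the cube
#' of the EB radius, a proxy for the fraction of the EB volume occupied
#' by reporter-positive cells.
#'
#' @param count filtered GFP point count (>= 0).
#' @param radius EB radius in um (> 0).
#' @return Dimensionless occupancy ratio `count / radius^3`.
#' @export
volume_occupancy <- function(count, radius) {
  stopifnot(count >= 0)
  if (any(radius <= 0)) stop("'radius' must be > 0", call. = FALSE)
  count / radius^3
}

#' Filtered count curve from a sequence of point-cloud frames
#'
#' Applies the bounding-box and close-neighbor filters to each frame and
#' extracts the per-frame filtered point count, producing the count time
#' series used for impulse fitting.
#'
#' @param frames list of [point_cloud_frame()] objects (one EB over time).
#' @param box bounding box passed to [bbox_filter()]; `NULL` to skip.
#' @param min_neighbors,neighbor_radius passed to [neighbor_filter()].
#' @param eb_id identifier for the resulting series.
#' @return An [eb_series()].
#' @export
counts_from_clouds <- function(frames, box = NULL, min_neighbors = 5,
                               neighbor_radius = 40, eb_id = "eb") {
  times <- vapply(frames, function(f) f$time, numeric(1))
  counts <- vapply(frames, function(f) {
    if (!is.null(box)) f <- bbox_filter(f, box)
    f <- neighbor_filter(f, min_neighbors, neighbor_radius)
    count_points(f)
  }, numeric(1))
  eb_series(eb_id, times, counts)
}
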