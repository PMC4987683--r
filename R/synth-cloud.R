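# Orthonormal rotation taking the +z axis onto unit vector `u`.
rotation_to <- function(u) {
  u <- u / sqrt(sum(u^2))
  helper <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- helper - sum(helper * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2, u)
}

# n points uniform on the spherical cap of angular radius `theta` (rad)
# around +z, at unit radius.
runif_cap <- function(n, theta) {
  z <- stats::runif(n, min = cos(theta), max = 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Simulate GFP point-cloud frames for one EB
#'
#' The reporter-positive region is modeled as a contiguous angular cap on
#' the EB's outer spherical shell, centered on the fixed onset locus. The
#' cap's solid angle grows and shrinks with the impulse curve: the
#' covered fraction of the shell is `N(t) / cap_capacity`, so when the
#' point count reaches the cap capacity the cap covers the full shell
#' (angular radius pi). During both spread and recession the cap stays
#' centered on the same locus, mirroring how the signal recedes toward
#' the direction of the original locus. Clutter points are placed outside
#' the EB sphere: a sparse uniform component (removed by the
#' close-neighbor filter) and a small far cluster (removed by the
#' bounding-box filter).
#'
#' @param radius EB shell radius, um (> 0).
#' @param onset_locus unit 3-vector: direction of the onset locus.
#' @param params [impulse_params()] driving the point count.
#' @param times frame times, hours.
#' @param clutter_rate expected clutter points per frame.
#' @param counts optional integer vector (one per frame) of GFP point
#'   counts to place, overriding the noiseless `round(N(t))`; used to
#'   keep cloud frames consistent with an already-simulated count series.
#' @param cap_capacity point count at which the cap covers the whole
#'   shell; defaults to the amplitude `A`.
#' @param shell_sd radial jitter of shell points, um.
#' @param seed optional RNG seed.
#' @return List of [point_cloud_frame()] objects, one per time.
#' @export
gen_point_cloud_series <- function(radius, onset_locus, params, times,
                                   clutter_rate = 20, counts = NULL,
                                   cap_capacity = NULL, shell_sd = 2,
                                   seed = NULL) {
  if (radius <= 0) stop("'radius' must be > 0", call. = FALSE)
  params <- as_impulse_params(params)
  if (is.null(cap_capacity)) cap_capacity <- params$A
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- round(impulse_value(params, times))
  stopifnot(length(counts) == length(times))
  rot <- rotation_to(onset_locus)
  lapply(seq_along(times), function(i) {
    n_gfp <- counts[i]
    gfp <- NULL
    if (n_gfp > 0) {
      frac <- min(n_gfp / cap_capacity, 1)
      theta <- acos(1 - 2 * frac)
      unit <- runif_cap(n_gfp, theta) %*% t(rot)
      rr <- radius + stats::rnorm(n_gfp, sd = shell_sd)
      gfp <- data.frame(x_um = unit[, 1] * rr, y_um = unit[, 2] * rr,
                        z_um = unit[, 3] * rr,
                        intensity = stats::rlnorm(n_gfp, 5, 0.4))
    }
    clut <- NULL
    n_unif <- stats::rpois(1, clutter_rate)
    if (n_unif > 0) {
      # uniform in a (5R)^3 box, rejected from inside 1.1 * radius
      pts <- matrix(stats::runif(3 * n_unif * 3, -2.5 * radius, 2.5 * radius),
                    ncol = 3)
      pts <- pts[sqrt(rowSums(pts^2)) > 1.1 * radius, , drop = FALSE]
      pts <- pts[seq_len(min(nrow(pts), n_unif)), , drop = FALSE]
      if (nrow(pts))
        clut <- data.frame(x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
                           intensity = stats::rlnorm(nrow(pts), 3, 0.4))
    }
    n_far <- stats::rpois(1, clutter_rate / 5)
    if (n_far > 0) {
      ctr <- c(4, 4, 4) * radius
      far <- data.frame(x_um = ctr[1] + stats::rnorm(n_far, sd = 25),
                        y_um = ctr[2] + stats::rnorm(n_far, sd = 25),
                        z_um = ctr[3] + stats::rnorm(n_far, sd = 25),
                        intensity = stats::rlnorm(n_far, 3, 0.4))
      clut <- rbind(clut, far)
    }
    pts <- rbind(gfp, clut)
    if (is.null(pts))
      pts <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        z_um = numeric(0), intensity = numeric(0))
    point_cloud_frame(times[i], pts)
  })
}

#' Simulate an EB outline shell
#'
#' Points distributed uniformly over the whole EB spherical shell,
#' standing in for the EB outline visible in a transmitted-light image;
#' used for radius estimation (the reporter cloud itself is empty before
#' onset).
#'
#' @param radius true EB radius, um.
#' @param n number of outline points.
#' @param shell_sd radial jitter, um.
#' @param time nominal frame time, hours (radius is measured pre-onset,
#'   at 60 h).
#' @param seed optional RNG seed.
#' @return A [point_cloud_frame()].
#' @export
gen_eb_shell <- function(radius, n = 400, shell_sd = 1, time = 60,
                         seed = NULL) {
  if (radius <= 0) stop("'radius' must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  unit <- runif_cap(n, pi)     # full sphere
  rr <- radius + stats::rnorm(n, sd = shell_sd)
  point_cloud_frame(time,
                    data.frame(x_um = unit[, 1] * rr, y_um = unit[, 2] * rr,
                               z_um = unit[, 3] * rr,
                               intensity = stats::rlnorm(n, 2, 0.3)))
}
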