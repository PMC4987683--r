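# Independent brute-force oracles used to validate the optimized paths.

# O(n^2) neighbor filter: keep points with >= k others within r.
oracle_neighbor_keep <- function(xyz, k, r) {
  n <- nrow(xyz)
  keep <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= r) cnt <- cnt + 1L
    }
    keep[i] <- cnt >= k
  }
  keep
}

# O(n^3) minimal enclosing circle: best circle over all pairs (as
# diameter) and all triples (circumcircle) that contains every point.
oracle_mec_radius <- function(pts) {
  n <- nrow(pts)
  contains_all <- function(ctr, r) {
    all(sqrt(rowSums((pts - matrix(ctr, n, 2, byrow = TRUE))^2)) <= r + 1e-7)
  }
  best <- Inf
  if (n == 1L) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if (r < best && contains_all(ctr, r)) best <- r
  }
  if (n >= 3L) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pts[i, ]; b <- pts[j, ]; c3 <- pts[k, ]
      d <- 2 * (a[1] * (b[2] - c3[2]) + b[1] * (c3[2] - a[2]) +
                  c3[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c3[2]) + sum(b^2) * (c3[2] - a[2]) +
               sum(c3^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c3[1] - b[1]) + sum(b^2) * (a[1] - c3[1]) +
               sum(c3^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (r < best && contains_all(c(ux, uy), r)) best <- r
    }
  }
  best
}

# Dense-grid first upward crossing of the impulse curve.
oracle_grid_onset <- function(p, threshold, dt = 1e-3) {
  tt <- seq(p$t1 - 30, detect_peak(p), by = dt)
  v <- impulse_value(p, tt)
  i <- which(v >= threshold)[1]
  if (is.na(i)) NA_real_ else tt[i]
}

# Dense-grid argmax of the impulse curve.
oracle_grid_peak <- function(p, dt = 1e-3) {
  tt <- seq(p$t1 - 5 / p$beta1, p$t2 + 5 / p$beta2, by = dt)
  tt[which.max(impulse_value(p, tt))]
}

make_frame <- function(xyz, time = 0) {
  point_cloud_frame(time, data.frame(x_um = xyz[, 1], y_um = xyz[, 2],
                                     z_um = xyz[, 3],
                                     intensity = rep(1, nrow(xyz))))
}

# Small CT panel built directly (genes x EBs), single "control" group
# unless labels given.
make_panel <- function(ct, groups = NULL) {
  if (is.null(groups)) groups <- rep("control", ncol(ct))
  meta <- data.frame(eb_id = colnames(ct), harvest_h = 100,
                     group = groups)
  expression_panel(ct, meta)
}
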