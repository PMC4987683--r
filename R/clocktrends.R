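#' Percent expression variance explained by a covariate
#'
#' Coefficient of determination (x100) of the simple linear regression of
#' a gene's -ddCt values on a per-EB covariate — developmental age or
#' harvest time. Comparing the two quantifies how much more informative
#' the reporter-defined clock is than wall-clock sampling time. Pairs
#' with missing values are dropped. A constant response has no variance
#' to explain; by convention the result is 0 (with a message).
#'
#' @param y gene -ddCt values per EB.
#' @param x covariate per EB, hours; must not be constant.
#' @return Percent of variance explained, in `[0, 100]`.
#' @export
variance_explained <- function(y, x) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 5L)
    stop("need at least 5 paired observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("covariate is constant; regression undefined", call. = FALSE)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    message("constant response: variance explained set to 0 by convention")
    return(0)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / tss
  min(max(100 * r2, 0), 100)
}

#' Local linear kernel trend of expression along the clock
#'
#' At each grid point `g`, fits a weighted least-squares line to
#' `(x, y)` with Gaussian kernel weights `exp(-(x-g)^2 / (2 bw^2))` and
#' reports the fitted value at `g`. Local linear smoothing reproduces
#' globally linear data exactly at every grid point. Grid points whose
#' effective weight mass (sum of kernel weights) falls below
#' `min_weight` lie outside the data support and are masked (`NA`)
#' rather than extrapolated.
#'
#' @param x covariate (developmental age), hours.
#' @param y gene -ddCt values.
#' @param bandwidth Gaussian kernel SD, hours; default 25 percent of the range
#'   of `x`.
#' @param grid evaluation grid, hours (strictly increasing); default 50
#'   points spanning `x`.
#' @param min_weight minimal summed kernel weight for a grid point.
#' @return data.frame with columns `grid` and `fit` (masked points `NA`).
#' @export
local_linear_trend <- function(x, y, bandwidth = NULL, grid = NULL,
                               min_weight = 1e-3) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("need at least 5 points", call. = FALSE)
  if (is.null(bandwidth)) bandwidth <- 0.25 * diff(range(x))
  if (bandwidth <= 0) stop("'bandwidth' must be > 0", call. = FALSE)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 50)
  if (any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing", call. = FALSE)
  fit <- vapply(grid, function(g) {
    w <- exp(-(x - g)^2 / (2 * bandwidth^2))
    if (sum(w) < min_weight) return(NA_real_)
    xc <- x - g
    sw <- sum(w); swx <- sum(w * xc); swx2 <- sum(w * xc^2)
    swy <- sum(w * y); swxy <- sum(w * xc * y)
    det <- sw * swx2 - swx^2
    if (det < 1e-12 * max(sw^2, 1)) return(swy / sw)  # degenerate: local mean
    (swx2 * swy - swx * swxy) / det                   # intercept at x = g
  }, numeric(1))
  data.frame(grid = grid, fit = fit)
}

#' Sort an expression panel by developmental age
#'
#' Stable ascending sort of the EB columns by DevA (ties keep the input
#' order); EBs without a clock (missing DevA) are appended at the end
#' and flagged.
#'
#' @param panel an [expression_panel()] or `"normalized_panel"` whose
#'   metadata has a `devA_h` column (or supply `devA`).
#' @param devA optional explicit DevA vector overriding the metadata.
#' @return Panel of the same class with columns reordered; metadata gains
#'   a logical `unclocked` column.
#' @export
sort_by_devA <- function(panel, devA = NULL) {
  meta <- panel$metadata
  if (is.null(devA)) devA <- meta$devA_h
  if (is.null(devA)) stop("no DevA available", call. = FALSE)
  mat_name <- if (inherits(panel, "normalized_panel")) "neg_ddct" else "ct"
  n <- ncol(panel[[mat_name]])
  stopifnot(length(devA) == n)
  unclocked <- !is.finite(devA)
  key <- ifelse(unclocked, Inf, devA)
  ord <- order(key)                       # order() is a stable sort
  panel[[mat_name]] <- panel[[mat_name]][, ord, drop = FALSE]
  meta <- meta[ord, , drop = FALSE]
  meta$unclocked <- unclocked[ord]
  panel$metadata <- meta
  panel
}

#' Robustness of cohort timing to the onset threshold
#'
#' Re-runs fitting and onset detection at each candidate threshold and
#' tabulates the cohort timing statistics, reporting the maximal pairwise
#' difference of mean onset. On well-behaved cohorts the mean onset
#' moves by well under 1.5 h across thresholds 300--600 points.
#'
#' @param series list of [eb_series()] objects.
#' @param thresholds onset thresholds to compare, points.
#' @return List with `table` (data.frame: threshold, onset_mean,
#'   onset_sd, n_onset; rows with no detectable EB carry `NA`) and
#'   `max_mean_spread` (hours).
#' @export
threshold_robustness <- function(series, thresholds = c(300, 450, 600)) {
  stopifnot(all(thresholds > 0))
  fits <- lapply(series, fit_impulse, signal_threshold = min(thresholds))
  rows <- lapply(thresholds, function(th) {
    clocks <- lapply(fits, dev_clock, threshold = th)
    onsets <- vapply(clocks, function(cl) cl$onset_time, numeric(1))
    onsets <- onsets[!is.na(onsets)]
    if (length(onsets) == 0L)
      return(data.frame(threshold = th, onset_mean = NA_real_,
                        onset_sd = NA_real_, n_onset = 0L))
    data.frame(threshold = th, onset_mean = mean(onsets),
               onset_sd = if (length(onsets) > 1) stats::sd(onsets) else 0,
               n_onset = length(onsets))
  })
  tab <- do.call(rbind, rows)
  means <- tab$onset_mean[!is.na(tab$onset_mean)]
  spread <- if (length(means) >= 2L) max(means) - min(means) else NA_real_
  list(table = tab, max_mean_spread = spread)
}
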