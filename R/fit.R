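#' Per-EB reporter time series
#'
#' @param eb_id identifier for the EB.
#' @param times strictly increasing frame times in hours (typical spacing
#'   1--2 h).
#' @param counts non-negative filtered GFP point counts, one per frame.
#' @param radius_pre_onset optional EB radius (um) measured before onset.
#' @return An object of class `"eb_series"`.
#' @export
eb_series <- function(eb_id, times, counts, radius_pre_onset = NA_real_) {
  stopifnot(length(times) == length(counts))
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(counts < 0))
    stop("'counts' must be non-negative", call. = FALSE)
  structure(list(eb_id = eb_id, times = as.numeric(times),
                 counts = as.numeric(counts),
                 radius_pre_onset = radius_pre_onset),
            class = "eb_series")
}

#' @export
print.eb_series <- function(x, ...) {
  cat(sprintf("EB series '%s': %d frames, t = [%.1f, %.1f] h, max count %.0f\n",
              as.character(x$eb_id), length(x$times), min(x$times),
              max(x$times), max(x$counts)))
  invisible(x)
}

# Interpolated first/last crossing of `level` by the raw counts; NA if never.
raw_crossing <- function(times, counts, level, first = TRUE) {
  above <- counts >= level
  if (!any(above)) return(NA_real_)
  if (first) {
    i <- which(above)[1L]
    if (i == 1L) return(times[1L])
    i0 <- i - 1L
  } else {
    i <- which(above)[length(which(above))]
    if (i == length(times)) return(times[length(times)])
    i0 <- i
    i <- i + 1L
    # falling edge: interpolate between last-above and next frame
    return(times[i0] + (times[i] - times[i0]) *
             (counts[i0] - level) / max(counts[i0] - counts[i], 1e-9))
  }
  times[i0] + (times[i] - times[i0]) *
    (level - counts[i0]) / max(counts[i] - counts[i0], 1e-9)
}

impulse_rss <- function(par, times, counts) {
  v <- par[["A"]] * logistic(par[["beta1"]] * (times - par[["t1"]])) *
    logistic(-par[["beta2"]] * (times - par[["t1"]] - par[["dt"]]))
  sum((counts - v)^2)
}

#' Least-squares fit of the impulse model to a count curve
#'
#' Fits the five-parameter impulse model to per-frame filtered GFP point
#' counts by least squares (Levenberg--Marquardt with box constraints,
#' falling back to `L-BFGS-B` on the residual sum of squares). The fit is
#' used to smooth measurement and processing noise before event detection.
#'
#' Initialization: `A0 = max(counts)`; `t1`/`t2` start at the first/last
#' raw half-maximum crossings; both rates start at `4 / rise time`
#' (25th--75th percent raw crossing interval) and are constrained to
#' `(1e-3, 10)` per hour. `t2` is parametrized as `t1 + dt` with
#' `dt >= 0.1` h, so `t1 < t2` holds structurally.
#'
#' Series whose maximum count never reaches `signal_threshold` carry no
#' usable event signal and are flagged `status = "no_signal"` with `NA`
#' parameters rather than fitted.
#'
#' @param s an [eb_series()] (or a list with `times` and `counts`).
#' @param signal_threshold minimal max count for a series to be considered
#'   to carry signal (default 300, the onset threshold).
#' @return An object of class `"impulse_fit"`: list with `params`
#'   ([impulse_params()] or `NULL`), `rss`, `status` one of
#'   `"ok"`, `"no_signal"`, `"not_converged"`, plus `eb_id`.
#' @export
fit_impulse <- function(s, signal_threshold = 300) {
  times <- s$times; counts <- s$counts
  if (length(times) < 8L)
    stop("need at least 8 frames to fit the impulse model", call. = FALSE)
  eb_id <- if (!is.null(s$eb_id)) s$eb_id else NA
  if (max(counts) < signal_threshold) {
    return(structure(list(eb_id = eb_id, params = NULL, rss = NA_real_,
                          status = "no_signal"), class = "impulse_fit"))
  }
  A0 <- max(counts)
  half <- A0 / 2
  t10 <- raw_crossing(times, counts, half, first = TRUE)
  t20 <- raw_crossing(times, counts, half, first = FALSE)
  if (is.na(t10)) t10 <- times[which.max(counts)] - 5
  if (is.na(t20) || t20 <= t10) t20 <- t10 + 5
  q1 <- raw_crossing(times, counts, 0.25 * A0, first = TRUE)
  q3 <- raw_crossing(times, counts, 0.75 * A0, first = TRUE)
  rise <- if (is.na(q1) || is.na(q3) || q3 <= q1) 4 else q3 - q1
  b0 <- min(max(4 / rise, 1e-2), 9)
  start <- c(A = A0, beta1 = b0, beta2 = b0, t1 = t10, dt = t20 - t10)
  lower <- c(A = 1, beta1 = 1e-3, beta2 = 1e-3,
             t1 = times[1L] - 100, dt = 0.1)
  upper <- c(A = 5 * A0, beta1 = 10, beta2 = 10,
             t1 = times[length(times)] + 100,
             dt = diff(range(times)) + 200)
  rss0 <- impulse_rss(start, times, counts)

  fitted <- NULL
  status <- "ok"
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * (1 / (1 + exp(-beta1 * (times - t1)))) *
        (1 / (1 + exp(beta2 * (times - t1 - dt)))),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fitted <- stats::coef(fit)
  } else {
    opt <- tryCatch(
      stats::optim(start, impulse_rss, times = times, counts = counts,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) {
      status <- "not_converged"
      fitted <- start
    } else fitted <- opt$par
  }
  rss <- impulse_rss(fitted, times, counts)
  if (rss > rss0) {           # never accept a fit worse than its start
    fitted <- start
    rss <- rss0
    if (status == "ok") status <- "not_converged"
  }
  p <- impulse_params(A = unname(fitted[["A"]]),
                      beta1 = unname(fitted[["beta1"]]),
                      beta2 = unname(fitted[["beta2"]]),
                      t1 = unname(fitted[["t1"]]),
                      t2 = unname(fitted[["t1"]] + fitted[["dt"]]))
  structure(list(eb_id = eb_id, params = p, rss = rss, status = status),
            class = "impulse_fit")
}

#' @export
print.impulse_fit <- function(x, ...) {
  cat(sprintf("Impulse fit (%s), status: %s", as.character(x$eb_id),
              x$status))
  if (!is.null(x$params))
    cat(sprintf(", rss = %.4g\n", x$rss)) else cat("\n")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Per-EB developmental clock from a fitted impulse curve
#'
#' Combines onset detection (threshold crossing on the fitted curve) and
#' peak detection into a per-EB clock record.
#'
#' @param fit an `"impulse_fit"` from [fit_impulse()].
#' @param threshold onset threshold in points (default 300).
#' @return An object of class `"dev_clock"`: list with `eb_id`,
#'   `onset_time`, `peak_time`, `onset_to_peak` (hours, `NA` when
#'   undetected), `threshold`, `fit`.
#' @export
dev_clock <- function(fit, threshold = 300) {
  onset <- peak <- NA_real_
  if (!is.null(fit$params) && fit$status != "no_signal") {
    onset <- detect_onset(fit$params, threshold)
    peak <- detect_peak(fit$params)
    if (is.na(onset)) peak <- NA_real_    # no event without threshold crossing
  }
  structure(list(eb_id = fit$eb_id, onset_time = onset, peak_time = peak,
                 onset_to_peak = peak - onset, threshold = threshold,
                 fit = fit),
            class = "dev_clock")
}

#' Fit a cohort of EB series and build their clocks
#'
#' @param series list of [eb_series()] objects.
#' @param threshold onset threshold in points.
#' @return List of `"dev_clock"` objects, one per series.
#' @export
fit_cohort <- function(series, threshold = 300) {
  lapply(series, function(s)
    dev_clock(fit_impulse(s, signal_threshold = threshold), threshold))
}

#' Cohort timing statistics
#'
#' Summarizes onset and onset-to-peak timing over the EBs of a cohort with
#' detected events. EBs without a detected onset are excluded; EBs whose
#' recording ended before peak may contribute an onset but no
#' onset-to-peak interval, so `n_peak` can be smaller than `n_onset`.
#'
#' @param clocks list of `"dev_clock"` objects.
#' @return List with `onset_mean`, `onset_sd`, `onset_range` (length-2),
#'   `onset_to_peak_mean`, `onset_to_peak_sd`, `n_onset`, `n_peak`.
#' @export
cohort_timing_stats <- function(clocks) {
  if (length(clocks) == 0L) stop("empty cohort", call. = FALSE)
  onsets <- vapply(clocks, function(cl) cl$onset_time, numeric(1))
  otp <- vapply(clocks, function(cl) cl$onset_to_peak, numeric(1))
  onsets <- onsets[!is.na(onsets)]
  otp <- otp[!is.na(otp)]
  if (length(onsets) == 0L)
    stop("no EB in the cohort has a detected onset", call. = FALSE)
  list(onset_mean = mean(onsets),
       onset_sd = if (length(onsets) > 1L) stats::sd(onsets) else 0,
       onset_range = range(onsets),
       onset_to_peak_mean = if (length(otp)) mean(otp) else NA_real_,
       onset_to_peak_sd = if (length(otp) > 1L) stats::sd(otp) else
         if (length(otp) == 1L) 0 else NA_real_,
       n_onset = length(onsets), n_peak = length(otp))
}

#' Correlation of a kinetic quantity with EB size
#'
#' Pearson correlation (with a two-sided test) between a per-EB quantity
#' (onset time, slope, amplitude, ...) and the pre-onset EB radius, used
#' to ask whether reporter kinetics depend on EB size.
#'
#' @param values numeric vector of per-EB values.
#' @param radii matching pre-onset radii in um; must not be constant.
#' @return List with `r` (Pearson correlation) and `p_value` (two-sided).
#' @export
size_dependence <- function(values, radii) {
  keep <- is.finite(values) & is.finite(radii)
  values <- values[keep]; radii <- radii[keep]
  if (length(values) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(radii) == 0)
    stop("radii are constant; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(values, radii, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
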