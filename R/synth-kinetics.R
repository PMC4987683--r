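#' Synthetic cohort configuration
#'
#' Describes one simulated experiment of co-seeded EBs. Defaults are the
#' within-experiment conditions of the baseline (unperturbed) experiment:
#' reporter onset at 83.3 +/- 3.7 h after seeding, onset-to-peak interval
#' 12.8 +/- 2.2 h, EB radius 113 +/- 19 um truncated to 81--176 um, and a
#' peak amplitude scale of 3000 segmentation points. Frames are taken
#' every 1.5 h between 60 and 120 h.
#'
#' @param n_ebs number of EBs in the cohort.
#' @param onset_mean,onset_sd reporter onset time distribution, hours.
#' @param onset_to_peak_mean,onset_to_peak_sd onset-to-peak interval
#'   distribution, hours.
#' @param radius_mean,radius_sd,radius_bounds EB radius distribution (um);
#'   draws are truncated to `radius_bounds`.
#' @param amplitude_scale typical peak point count.
#' @param amplitude_density amplitude cap density `c` in points/um^3: the
#'   peak amplitude is `min(A_free, c * radius^3)`, so only EBs smaller
#'   than about 100 um are amplitude-limited by their size.
#' @param frame_interval imaging interval, hours (1--2 h typical).
#' @param t_start,t_end imaging window, hours.
#' @param noise_model `"poisson"` (variance = mean, the default for
#'   counts of segmented objects), `"gaussian"`, or `"none"`.
#' @param noise_scale SD for the gaussian noise model (ignored otherwise).
#' @param clutter_rate expected clutter points per frame.
#' @param perturbation one of `"control"`, `"chir_long"`,
#'   `"chir_short_early"`, `"chir_short_late"`, `"bmp4"`.
#' @param seed integer RNG seed making the cohort reproducible.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ebs = 50,
                          onset_mean = 83.3, onset_sd = 3.7,
                          onset_to_peak_mean = 12.8, onset_to_peak_sd = 2.2,
                          radius_mean = 113, radius_sd = 19,
                          radius_bounds = c(81, 176),
                          amplitude_scale = 3000,
                          amplitude_density = 3e-3,
                          frame_interval = 1.5,
                          t_start = 60, t_end = 120,
                          noise_model = c("poisson", "gaussian", "none"),
                          noise_scale = 30,
                          clutter_rate = 20,
                          perturbation = c("control", "chir_long",
                                           "chir_short_early",
                                           "chir_short_late", "bmp4"),
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  perturbation <- match.arg(perturbation)
  stopifnot(n_ebs >= 1, onset_sd >= 0, radius_sd >= 0,
            onset_to_peak_sd >= 0, frame_interval > 0,
            amplitude_scale > 0, amplitude_density > 0, clutter_rate >= 0)
  if (radius_bounds[1] >= radius_bounds[2])
    stop("radius_bounds[1] must be < radius_bounds[2]", call. = FALSE)
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  structure(list(n_ebs = as.integer(n_ebs),
                 onset_mean = onset_mean, onset_sd = onset_sd,
                 onset_to_peak_mean = onset_to_peak_mean,
                 onset_to_peak_sd = onset_to_peak_sd,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 radius_bounds = radius_bounds,
                 amplitude_scale = amplitude_scale,
                 amplitude_density = amplitude_density,
                 frame_interval = frame_interval,
                 t_start = t_start, t_end = t_end,
                 noise_model = noise_model, noise_scale = noise_scale,
                 clutter_rate = clutter_rate,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Configuration for a signaling-perturbation experiment
#'
#' Builds a [cohort_config()] for the perturbation experiment design:
#' the matched control has mean reporter onset at 70 h, while early
#' activation of canonical Wnt (CHIR 24--72 h) or Bmp4 treatment shifts
#' mean onset to 50 h. Short CHIR pulses (2--4 h) leave reporter kinetics
#' unchanged and act on gene expression only. The imaging window starts
#' earlier (30 h) to cover the shifted onsets.
#'
#' @param perturbation perturbation preset name.
#' @param ... further arguments passed to [cohort_config()].
#' @return A `"cohort_config"`.
#' @export
perturbation_config <- function(perturbation = c("control", "chir_long",
                                                 "chir_short_early",
                                                 "chir_short_late", "bmp4"),
                                ...) {
  perturbation <- match.arg(perturbation)
  onset_mean <- switch(perturbation,
                       chir_long = 50, bmp4 = 50,
                       70)
  args <- list(...)
  defaults <- list(onset_mean = onset_mean, t_start = 30, t_end = 100,
                   n_ebs = 30, perturbation = perturbation)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(cohort_config, args)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Cohort config: %d EBs (%s), onset %.1f +/- %.1f h, onset-to-peak %.1f +/- %.1f h,\n  radius %.0f +/- %.0f um in [%.0f, %.0f], frames every %.2g h on [%.0f, %.0f], %s noise, seed %d\n",
    x$n_ebs, x$perturbation, x$onset_mean, x$onset_sd,
    x$onset_to_peak_mean, x$onset_to_peak_sd, x$radius_mean, x$radius_sd,
    x$radius_bounds[1], x$radius_bounds[2], x$frame_interval, x$t_start,
    x$t_end, x$noise_model, x$seed))
  invisible(x)
}

# Onset (threshold crossing) and peak times of a curve with t1 = 0,
# t2 = delta.
rel_events <- function(delta, A, beta1, beta2, threshold) {
  p <- impulse_params(A, beta1, beta2, 0, delta)
  onset <- detect_onset(p, threshold)
  if (is.na(onset)) return(NULL)
  list(onset = onset, peak = detect_peak(p))
}

#' Impulse parameters realizing given onset and onset-to-peak times
#'
#' Inverts the impulse model's event map: finds `t1`, `t2` such that the
#' curve with amplitude `A` and rates `beta1`, `beta2` crosses
#' `threshold` points (rising flank) exactly at `onset` and peaks
#' `onset_to_peak` hours later. Used by the cohort generator so that the
#' simulated event-time distributions are the designed ones. If the
#' requested interval is below the smallest achievable for the given
#' rates, the smallest achievable is used (attribute `clamped = TRUE`).
#'
#' @param onset target onset time, hours.
#' @param onset_to_peak target onset-to-peak interval, hours.
#' @param A,beta1,beta2 remaining impulse parameters.
#' @param threshold onset threshold in points.
#' @return An [impulse_params()] object (possibly with attribute
#'   `clamped`).
#' @export
solve_impulse_times <- function(onset, onset_to_peak, A,
                                beta1 = 0.7, beta2 = 0.35, threshold = 300) {
  if (A <= threshold)
    stop("amplitude must exceed the onset threshold", call. = FALSE)
  gap <- function(delta) {
    ev <- rel_events(delta, A, beta1, beta2, threshold)
    if (is.null(ev)) return(NA_real_)
    (ev$peak - ev$onset) - onset_to_peak
  }
  d_lo <- 0.2
  while (is.na(gap(d_lo)) && d_lo < 500) d_lo <- d_lo * 2
  if (is.na(gap(d_lo)))
    stop("cannot realize an onset with these parameters", call. = FALSE)
  clamped <- FALSE
  if (gap(d_lo) >= 0) {
    delta <- d_lo                       # requested interval not achievable
    clamped <- TRUE
  } else {
    d_hi <- max(2 * d_lo, 40)
    while (gap(d_hi) < 0 && d_hi < 2000) d_hi <- d_hi * 2
    delta <- stats::uniroot(gap, c(d_lo, d_hi), tol = 1e-6)$root
  }
  ev <- rel_events(delta, A, beta1, beta2, threshold)
  p <- impulse_params(A, beta1, beta2, onset - ev$onset,
                      onset - ev$onset + delta)
  if (clamped) attr(p, "clamped") <- TRUE
  p
}

#' Simulate a reporter count curve from the impulse model
#'
#' Forward model of the fitting stage: evaluates the impulse curve at the
#' requested frame times and adds counting noise. Poisson noise
#' (variance = mean) reflects counts of segmented objects; the gaussian
#' option adds `N(0, noise_scale)` and rounds; `"none"` returns the exact
#' model values.
#'
#' @param params an [impulse_params()] object.
#' @param times strictly increasing frame times, hours.
#' @param noise_model `"poisson"`, `"gaussian"` or `"none"`.
#' @param noise_scale gaussian SD in points.
#' @param eb_id identifier for the series.
#' @param seed optional RNG seed.
#' @return An [eb_series()].
#' @export
gen_impulse_series <- function(params, times,
                               noise_model = c("poisson", "gaussian", "none"),
                               noise_scale = 30, eb_id = "eb", seed = NULL) {
  params <- as_impulse_params(params)
  noise_model <- match.arg(noise_model)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mu <- impulse_value(params, times)
  counts <- switch(noise_model,
    none = mu,
    poisson = stats::rpois(length(mu), lambda = mu),
    gaussian = pmax(0, round(mu + stats::rnorm(length(mu), sd = noise_scale))))
  eb_series(eb_id, times, counts)
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate a synthetic EB cohort
#'
#' Draws per-EB latent event times (onset, onset-to-peak), radii and
#' amplitudes from the configured distributions, solves for impulse
#' parameters realizing them, and simulates the per-frame count series
#' (and, optionally, 3D point-cloud frames). Onset times and radii are
#' drawn independently; the amplitude is capped at
#' `amplitude_density * radius^3` so only small EBs (below roughly 100
#' um) show an amplitude--size correlation. The result is deterministic
#' given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param clouds logical: also generate per-EB point-cloud frame lists
#'   (slower). Cloud point counts follow the same noisy counts as the
#'   series, so both views of one EB agree.
#' @param beta1_mean,beta2_mean typical rise/decline rates (per hour),
#'   jittered log-normally by 10 percent per EB.
#' @return List with `series` (list of [eb_series()]), `clouds` (list of
#'   frame lists, or `NULL`), `truth` (data.frame of per-EB latents:
#'   onset, onset-to-peak, radius, amplitude, rates, `t1`, `t2`), and
#'   `config`.
#' @export
gen_cohort <- function(config, clouds = FALSE,
                       beta1_mean = 0.7, beta2_mean = 0.35) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_ebs
  onset <- stats::rnorm(n, config$onset_mean, config$onset_sd)
  otp <- stats::rnorm(n, config$onset_to_peak_mean, config$onset_to_peak_sd)
  radius <- rtruncnorm1(n, config$radius_mean, config$radius_sd,
                        config$radius_bounds[1], config$radius_bounds[2])
  A_free <- stats::rlnorm(n, log(config$amplitude_scale), 0.2)
  A <- pmin(A_free, config$amplitude_density * radius^3)
  beta1 <- stats::rlnorm(n, log(beta1_mean), 0.1)
  beta2 <- stats::rlnorm(n, log(beta2_mean), 0.1)
  locus <- matrix(stats::rnorm(3 * n), ncol = 3)
  locus <- locus / sqrt(rowSums(locus^2))
  times <- seq(config$t_start, config$t_end, by = config$frame_interval)

  series <- vector("list", n)
  cloud_list <- if (clouds) vector("list", n) else NULL
  truth <- data.frame(eb_id = sprintf("eb%02d", seq_len(n)),
                      onset_true = onset, onset_to_peak_true = otp,
                      radius_um = radius, A = A,
                      beta1 = beta1, beta2 = beta2,
                      t1 = NA_real_, t2 = NA_real_)
  for (i in seq_len(n)) {
    p <- solve_impulse_times(onset[i], otp[i], A[i], beta1[i], beta2[i])
    truth$t1[i] <- p$t1; truth$t2[i] <- p$t2
    # record the achieved interval if the requested one was clamped
    if (isTRUE(attr(p, "clamped")))
      truth$onset_to_peak_true[i] <- detect_peak(p) - detect_onset(p)
    s <- gen_impulse_series(p, times, config$noise_model,
                            config$noise_scale,
                            eb_id = truth$eb_id[i])
    s$radius_pre_onset <- radius[i]
    series[[i]] <- s
    if (clouds) {
      cloud_list[[i]] <- gen_point_cloud_series(
        radius = radius[i], onset_locus = locus[i, ], params = p,
        times = times, clutter_rate = config$clutter_rate,
        counts = s$counts)
    }
  }
  list(series = series, clouds = cloud_list, truth = truth, config = config)
}
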