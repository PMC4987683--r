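# CSV / YAML interchange for the pipeline's standard tables.

#' Write / read per-EB count series
#'
#' Long-format CSV with columns `eb_id`, `time_h`, `count`.
#'
#' @param series list of [eb_series()] objects.
#' @param path CSV file path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a list of [eb_series()].
#' @export
write_series_csv <- function(series, path) {
  tabs <- lapply(series, function(s)
    data.frame(eb_id = s$eb_id, time_h = s$times, count = s$counts))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$eb_id), function(d)
    eb_series(d$eb_id[1], d$time_h, d$count))
}

#' Write / read a point-cloud frame sequence
#'
#' CSV with columns `time_h`, `x_um`, `y_um`, `z_um`, `intensity`.
#'
#' @param frames list of [point_cloud_frame()] objects.
#' @param path CSV file path.
#' @return `write_cloud_csv` returns `path` invisibly; `read_cloud_csv`
#'   returns a list of frames ordered by time.
#' @export
write_cloud_csv <- function(frames, path) {
  tabs <- lapply(frames, function(f) {
    if (nrow(f$points) == 0L) return(NULL)
    cbind(time_h = f$time, f$points)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cloud_csv
#' @export
read_cloud_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$time_h), function(d)
    point_cloud_frame(d$time_h[1],
                      d[, c("x_um", "y_um", "z_um", "intensity")]))
}

#' Write / read a CT matrix with metadata
#'
#' The CT matrix CSV has genes as rows and EB ids as columns, empty cells
#' marking failed reactions; the metadata CSV has one row per EB.
#'
#' @param panel an [expression_panel()].
#' @param ct_path,metadata_path CSV file paths.
#' @return `write_panel_csv` returns invisibly; `read_panel_csv` returns
#'   an [expression_panel()].
#' @export
write_panel_csv <- function(panel, ct_path, metadata_path) {
  utils::write.csv(panel$ct, ct_path, row.names = TRUE, na = "")
  utils::write.csv(panel$metadata, metadata_path, row.names = FALSE)
  invisible(ct_path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(ct_path, metadata_path) {
  ct <- utils::read.csv(ct_path, row.names = 1, check.names = FALSE)
  ct <- as.matrix(ct)
  meta <- utils::read.csv(metadata_path)
  expression_panel(ct, meta)
}

#' Read a cohort configuration from a YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; nested sections are
#' flattened (e.g. `noise: {model: poisson, scale: 30}` maps to
#' `noise_model`, `noise_scale`).
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$noise)) {
    raw$noise_model <- raw$noise$model %||% raw$noise_model
    raw$noise_scale <- raw$noise$scale %||% raw$noise_scale
    raw$noise <- NULL
  }
  if (!is.null(raw$radius_bounds)) raw$radius_bounds <-
    as.numeric(unlist(raw$radius_bounds))
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(cohort_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate fitted clocks
#'
#' Flattens a list of `"dev_clock"` objects into the fits/clock table
#' written by the pipeline (`eb_id`, impulse parameters, `rss`,
#' `onset_h`, `peak_h`, `status`).
#'
#' @param clocks list of `"dev_clock"` objects from [fit_cohort()].
#' @return data.frame with one row per EB.
#' @export
clock_table <- function(clocks) {
  do.call(rbind, lapply(clocks, function(cl) {
    p <- cl$fit$params
    data.frame(eb_id = as.character(cl$eb_id),
               A = if (is.null(p)) NA_real_ else p$A,
               beta1 = if (is.null(p)) NA_real_ else p$beta1,
               beta2 = if (is.null(p)) NA_real_ else p$beta2,
               t1 = if (is.null(p)) NA_real_ else p$t1,
               t2 = if (is.null(p)) NA_real_ else p$t2,
               rss = cl$fit$rss, onset_h = cl$onset_time,
               peak_h = cl$peak_time, status = cl$fit$status)
  }))
}
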