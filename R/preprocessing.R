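#' Filter admissions by ventilation duration and discharge status
#'
#' Retains exactly the admissions ventilated for at least 24 hours that
#' were discharged alive from the ICU; input order is preserved.
#'
#' @param records Data frame with columns `admission_id`, `vent_hours`,
#'   `discharged_alive` (logical or 0/1), or a list of such records.
#' @param min_vent_hours Minimum ventilation duration in hours (default 24).
#' @return The retained subset, same type as the input.
#' @export
#' @examples
#' recs <- data.frame(admission_id = 1:3, vent_hours = c(30, 10, 30),
#'                    discharged_alive = c(TRUE, TRUE, FALSE))
#' filter_admissions(recs)
filter_admissions <- function(records, min_vent_hours = 24) {
  as_df <- is.data.frame(records)
  df <- if (as_df) records else {
    do.call(rbind, lapply(records, function(r) {
      data.frame(admission_id = r$admission_id, vent_hours = r$vent_hours,
                 discharged_alive = r$discharged_alive)
    }))
  }
  if (length(records) == 0L || nrow(df) == 0L) return(records)
  for (col in c("vent_hours", "discharged_alive")) {
    if (!col %in% names(df)) {
      stop("admission record(s) missing field ", col)
    }
    bad <- is.na(df[[col]])
    if (any(bad)) {
      stop("admission(s) missing ", col, ": ",
           paste(df$admission_id[bad], collapse = ", "))
    }
  }
  keep <- df$vent_hours >= min_vent_hours & as.logical(df$discharged_alive)
  if (as_df) records[keep, , drop = FALSE] else records[keep]
}

#' Support-vector-regression configuration for temporal resampling
#'
#' @param kernel SVR kernel (`"radial"` default; `"linear"` for affine
#'   series).
#' @param cost Regularization constant C (default 10).
#' @param epsilon Epsilon-insensitive tube width (default 0.01).
#' @param gamma RBF kernel width; `NULL` lets the fitter use 1/dim.
#' @return List of class `svr_config`.
#' @export
svr_config <- function(kernel = "radial", cost = 10, epsilon = 0.01,
                       gamma = NULL) {
  structure(list(kernel = kernel, cost = cost, epsilon = epsilon,
                 gamma = gamma), class = "svr_config")
}

#' Resample an irregular measurement series onto the 10-minute grid
#'
#' Fits a support-vector regression of value on measurement time, then
#' evaluates the fit on the regular grid `{0, step, 2 step, ...}` spanning
#' the stay. Values beyond the last observation are the regression's own
#' prediction (no special extrapolation rule). A series with fewer than two
#' points falls back to constant fill with a warning.
#'
#' @param series List with fields `points` (data frame `t_minutes`,
#'   `value`) or a data frame with those columns.
#' @param duration Stay duration in minutes; defaults to the last
#'   observation time.
#' @param step Grid step in minutes (default 10).
#' @param cfg An [svr_config()].
#' @return Data frame with columns `t_index` (minutes, multiples of `step`)
#'   and `value`.
#' @export
#' @examples
#' pts <- data.frame(t_minutes = c(0, 17, 45, 60), value = c(1, 2.7, 5.5, 7))
#' resample_series(pts, duration = 60, cfg = svr_config(kernel = "linear"))
resample_series <- function(series, duration = NULL, step = 10,
                            cfg = svr_config()) {
  pts <- if (is.data.frame(series)) series else series$points
  if (is.null(duration)) duration <- max(pts$t_minutes)
  grid <- seq(0, floor(duration / step) * step, by = step)
  if (nrow(pts) < 2L) {
    warning("fewer than 2 measurement points; constant fill")
    fill <- if (nrow(pts) == 1L) pts$value[1L] else NA_real_
    return(data.frame(t_index = grid, value = rep(fill, length(grid))))
  }
  if (diff(range(pts$value)) < 1e-12) {
    # constant series: the regression is the constant itself
    return(data.frame(t_index = grid, value = rep(pts$value[1L],
                                                  length(grid))))
  }
  args <- list(x = matrix(pts$t_minutes, ncol = 1), y = pts$value,
               type = "eps-regression", kernel = cfg$kernel,
               cost = cfg$cost, epsilon = cfg$epsilon, scale = TRUE)
  if (!is.null(cfg$gamma)) args$gamma <- cfg$gamma
  fit <- do.call(e1071::svm, args)
  vals <- as.numeric(predict(fit, matrix(grid, ncol = 1)))
  data.frame(t_index = grid, value = vals)
}

#' Resample every feature series of an admission to the 10-minute grid
#'
#' Applies [resample_series()] independently per feature and joins the
#' results into a wide state table.
#'
#' @param measurements Data frame `admission_id, feature_name, t_minutes,
#'   value` for one admission.
#' @param duration Stay duration in minutes (default: last observation over
#'   all features).
#' @param step Grid step in minutes.
#' @param cfg An [svr_config()].
#' @return Wide data frame: `admission_id`, `t_index`, one column per
#'   feature.
#' @export
resample_admission <- function(measurements, duration = NULL, step = 10,
                               cfg = svr_config()) {
  if (is.null(duration)) duration <- max(measurements$t_minutes)
  feats <- unique(measurements$feature_name)
  grid <- seq(0, floor(duration / step) * step, by = step)
  out <- data.frame(admission_id = measurements$admission_id[1L],
                    t_index = grid)
  for (f in feats) {
    pts <- measurements[measurements$feature_name == f,
                        c("t_minutes", "value"), drop = FALSE]
    out[[f]] <- resample_series(pts, duration = duration, step = step,
                                cfg = cfg)$value
  }
  out
}
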