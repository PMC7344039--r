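#' Trajectory CSV column order
#'
#' One row per 10-minute step: admission id, step index, the 13 state
#' features, the recorded (clinician) composite action, and the transition
#' reward. The reward column is optional on input.
#'
#' @return Character vector of column names.
#' @export
trajectory_columns <- function() {
  c("admission_id", "t_index", state_features(), "vent_action", "sed_bin",
    "reward_total")
}

#' Flatten a cohort to a single trajectory data frame
#'
#' @param cohort An `icu_cohort` or a single `icu_trajectory`.
#' @return Data frame in [trajectory_columns()] order.
#' @export
cohort_to_df <- function(cohort) {
  if (inherits(cohort, "icu_trajectory")) cohort <- list(cohort)
  df <- do.call(rbind, lapply(cohort, function(tr) tr$df))
  cols <- intersect(trajectory_columns(), names(df))
  df[, cols, drop = FALSE]
}

#' Strata sidecar table for a cohort
#'
#' @param cohort An `icu_cohort`.
#' @return Data frame with columns `admission_id`, `stratum`.
#' @export
cohort_strata <- function(cohort) {
  data.frame(admission_id = vapply(cohort, function(tr) tr$admission_id,
                                   numeric(1)),
             stratum = vapply(cohort, function(tr) tr$stratum, character(1)),
             stringsAsFactors = FALSE)
}

#' Write / read the trajectory CSV
#'
#' @param x Cohort, trajectory, or trajectory data frame.
#' @param path Output file.
#' @return `write_trajectory_csv`: `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- if (is.data.frame(x)) x else cohort_to_df(x)
  cols <- intersect(trajectory_columns(), names(df))
  write.csv(df[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return `read_trajectory_csv`: a trajectory data frame (reward column
#'   `NA`-filled if absent).
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(trajectory_columns(), "reward_total")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("trajectory CSV lacks required columns: ",
         paste(missing, collapse = ", "))
  }
  if (!"reward_total" %in% names(df)) df$reward_total <- NA_real_
  df[, trajectory_columns(), drop = FALSE]
}

#' Rebuild an `icu_cohort` from a trajectory data frame
#'
#' Intubation events are recounted from the ventilation-status sequence;
#' the expert flag is taken from the strata sidecar when supplied
#' (admissions labeled `expert`), otherwise `FALSE`.
#'
#' @param df Trajectory data frame (as from [read_trajectory_csv()]).
#' @param strata Optional sidecar data frame (`admission_id`, `stratum`).
#' @return An `icu_cohort`.
#' @export
df_to_cohort <- function(df, strata = NULL) {
  ids <- unique(df$admission_id)
  out <- lapply(ids, function(id) {
    d <- df[df$admission_id == id, , drop = FALSE]
    d <- d[order(d$t_index), , drop = FALSE]
    vs <- d$vent_status
    n_intub <- 1L + sum(vs[-1] == 1 & vs[-length(vs)] == 0)
    expert <- FALSE
    if (!is.null(strata)) {
      s <- strata$stratum[match(id, strata$admission_id)]
      expert <- isTRUE(s == "expert")
    }
    tr <- structure(list(admission_id = id, df = d, expert = expert,
                         n_intubations = n_intub, stratum = NA_character_),
                    class = "icu_trajectory")
    tr$stratum <- trajectory_stratum(tr)
    tr
  })
  structure(out, class = "icu_cohort")
}
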