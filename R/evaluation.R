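#' Greedy policy actions of a trained model on raw states
#'
#' Applies the model's stored input scaler, then the actor's greedy
#' (argmax-probability, lowest-index tie-break) decision.
#'
#' @param model A `sac_model`.
#' @param test An `icu_cohort`, trajectory data frame, or `transition_set`.
#' @return List with integer vectors `pred` (0-based predicted classes) and
#'   `labels` (recorded clinician classes).
#' @export
predict_actions <- function(model, test) {
  ts <- if (inherits(test, "transition_set")) test else
    build_transitions(test, model$cfg$stage)
  if (length(ts$labels) == 0L) stop("empty test set")
  S <- scaler_apply(model$scaler, ts$S)
  list(pred = greedy_action(model$theta, S), labels = ts$labels)
}

#' Accuracy rate of a learned policy against clinician actions
#'
#' Fraction of test states at which the greedy learned action equals the
#' clinician's recorded action.
#'
#' @inheritParams predict_actions
#' @return Fraction in \[0, 1\].
#' @export
accuracy_rate <- function(model, test) {
  p <- predict_actions(model, test)
  mean(p$pred == p$labels)
}

#' Mean squared error of predicted sedative doses
#'
#' Maps the predicted and recorded dose bins through `dose_map` and
#' averages the squared differences. The default map places the four bins
#' on a unit-spaced dose grid (0, 1, 2, 3 dose units).
#'
#' @inheritParams predict_actions
#' @param dose_map Numeric vector of length 4: dose value of bins 0..3.
#' @return Mean squared dose error (>= 0).
#' @export
dose_mse <- function(model, test, dose_map = 0:3) {
  if (model$cfg$stage != "sed") stop("dose_mse applies to the sedation stage")
  p <- predict_actions(model, test)
  mean((dose_map[p$pred + 1L] - dose_map[p$labels + 1L])^2)
}

#' First episode at which a learning-curve metric crosses a threshold
#'
#' "Converged to the threshold" means the metric reaches it and stays at or
#' above it for `patience` consecutive episodes (or through the end of the
#' curve if fewer remain).
#'
#' @param curve Learning-curve data frame with an `episode` column.
#' @param metric Curve column to monitor (default `"ar"`).
#' @param threshold Crossing level.
#' @param patience Sustain window in episodes (default 3).
#' @param direction `">="` (default) or `"<="` for metrics that decrease.
#' @return Episode number of the first sustained crossing, or
#'   `NA_integer_` when never reached.
#' @export
#' @examples
#' cv <- data.frame(episode = 1:5, ar = c(0.2, 0.96, 0.5, 0.97, 0.99))
#' episodes_to_threshold(cv, "ar", 0.95)  # 4
episodes_to_threshold <- function(curve, metric = "ar", threshold,
                                  patience = 3, direction = ">=") {
  if (nrow(curve) == 0L) stop("empty learning curve")
  v <- curve[[metric]]
  ok <- if (direction == ">=") v >= threshold else v <= threshold
  ok[is.na(ok)] <- FALSE
  n <- length(ok)
  for (i in seq_len(n)) {
    win <- i:min(n, i + patience - 1L)
    if (all(ok[win])) return(curve$episode[i])
  }
  NA_integer_
}

#' Stratified evaluation report
#'
#' Accuracy rate (and dose MSE for the sedation stage) on the whole test
#' cohort and on each stratum (expert / single intubation / multiple
#' intubation).
#'
#' @param model A `sac_model`.
#' @param cohort Test `icu_cohort`.
#' @param dose_map Bin-to-dose map for [dose_mse()].
#' @return Data frame with one row per stratum (plus `overall`): columns
#'   `stratum`, `n_admissions`, `n_transitions`, `ar`, `mse`.
#' @export
eval_report <- function(model, cohort, dose_map = 0:3) {
  strata <- c(list(overall = cohort), stratify(cohort))
  rows <- lapply(names(strata), function(nm) {
    sub <- strata[[nm]]
    if (length(sub) == 0L) {
      return(data.frame(stratum = nm, n_admissions = 0L, n_transitions = 0L,
                        ar = NA_real_, mse = NA_real_))
    }
    ts <- build_transitions(sub, model$cfg$stage)
    p <- predict_actions(model, ts)
    mse <- if (model$cfg$stage == "sed") {
      mean((dose_map[p$pred + 1L] - dose_map[p$labels + 1L])^2)
    } else NA_real_
    data.frame(stratum = nm, n_admissions = length(sub),
               n_transitions = length(p$pred),
               ar = mean(p$pred == p$labels), mse = mse)
  })
  do.call(rbind, rows)
}

#' Compare training runs episode-by-episode and by stratum
#'
#' Aligns the learning curves of two or more runs (models or run
#' directories written by the command-line driver) and tabulates
#' per-stratum accuracy/MSE. When several runs share an algorithm label
#' (e.g. the same algorithm over different seeds), per-episode medians
#' across those runs are reported as well.
#'
#' @param runs Named list of `sac_model`s, or character vector of run
#'   directories containing `curve.csv` and `model.json`.
#' @param cohort Optional test cohort for the stratified table.
#' @return List with `curves` (long data frame `run, episode, mean_q, ar,
#'   mse, critic_loss`), `medians` (per-episode medians by algorithm), and
#'   `strata` (stratified table; `NULL` without a cohort).
#' @export
compare_runs <- function(runs, cohort = NULL) {
  if (is.character(runs)) {
    dirs <- runs
    runs <- lapply(dirs, load_run)
    names(runs) <- basename(dirs)
  }
  if (length(runs) < 2L) stop("need at least two runs to compare")
  stages <- vapply(runs, function(m) m$cfg$stage, character(1))
  if (length(unique(stages)) != 1L) {
    stop("runs mix MDP stages: ", paste(unique(stages), collapse = ", "))
  }
  if (is.null(names(runs)) || any(names(runs) == "")) {
    names(runs) <- paste0("run", seq_along(runs))
  }
  curves <- do.call(rbind, lapply(names(runs), function(nm) {
    cbind(run = nm, algorithm = runs[[nm]]$cfg$algorithm, runs[[nm]]$curve)
  }))
  med <- do.call(rbind, lapply(split(curves, curves$algorithm), function(d) {
    agg <- lapply(split(d, d$episode), function(e) {
      data.frame(algorithm = e$algorithm[1L], episode = e$episode[1L],
                 ar = median(e$ar), mse = median(e$mse),
                 mean_q = median(e$mean_q))
    })
    do.call(rbind, agg)
  }))
  rownames(med) <- NULL
  strata <- NULL
  if (!is.null(cohort)) {
    strata <- do.call(rbind, lapply(names(runs), function(nm) {
      cbind(run = nm, eval_report(runs[[nm]], cohort))
    }))
  }
  list(curves = curves, medians = med, strata = strata)
}

#' Plot SAC-vs-AC learning curves to a PNG file
#'
#' @param comparison Result of [compare_runs()].
#' @param metric Curve column to draw.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_comparison <- function(comparison, metric = "ar", path) {
  cv <- comparison$curves
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  runs <- unique(cv$run)
  cols <- grDevices::hcl.colors(max(3L, length(runs)), "Dark 3")
  rng <- range(cv[[metric]], na.rm = TRUE)
  plot(NA, xlim = range(cv$episode), ylim = rng, xlab = "episode",
       ylab = metric, main = paste("learning curves:", metric))
  for (i in seq_along(runs)) {
    d <- cv[cv$run == runs[i], ]
    graphics::lines(d$episode, d[[metric]], col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = runs, col = cols[seq_along(runs)],
                   lwd = 2, bty = "n")
  invisible(path)
}
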