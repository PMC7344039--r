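#' The bundled synthetic benchmark cohort
#'
#' 200 admissions from [simulate_cohort()] under the default simulator
#' conditions; the companion of the SAC-vs-AC comparison experiments.
#'
#' @param seed Cohort seed (default 100).
#' @param n_admissions Cohort size (default 200).
#' @return An `icu_cohort`.
#' @export
benchmark_cohort <- function(seed = 100, n_admissions = 200) {
  simulate_cohort(simulator_config(n_admissions = n_admissions, seed = seed))
}

#' SAC-vs-AC benchmark over multiple training seeds
#'
#' On one fixed synthetic cohort, trains the supervised actor-critic
#' (\eqn{\epsilon = 0.5}) and the plain actor-critic per seed on both MDP
#' stages, then summarizes convergence speed (episodes until the held-out
#' accuracy rate first sustains `ar_threshold`) and the final sedation dose
#' MSE, as medians over seeds. A run that never reaches the threshold
#' counts as `Inf` episodes.
#'
#' @param seeds Training seeds (default 1:5).
#' @param cohort_seed Seed of the shared cohort (default 100).
#' @param n_admissions Cohort size (default 200).
#' @param n_episodes Episodes per training run (default 40).
#' @param ar_threshold Accuracy-rate convergence threshold (default 0.95).
#' @param epsilon SAC blend weight (default 0.5).
#' @param patience Sustain window for the crossing rule (default 3).
#' @return List with `per_seed` (one row per seed x algorithm) and
#'   `summary` (medians by algorithm: `episodes_to_ar`, `final_ar`,
#'   `final_mse`).
#' @export
run_benchmark <- function(seeds = 1:5, cohort_seed = 100, n_admissions = 200,
                          n_episodes = 40, ar_threshold = 0.95,
                          epsilon = 0.5, patience = 3) {
  cohort <- benchmark_cohort(cohort_seed, n_admissions)
  ts_vent <- build_transitions(cohort, "vent")
  ts_sed <- build_transitions(cohort, "sed")
  rows <- list()
  for (s in seeds) {
    for (alg in c("SAC", "AC")) {
      eps <- if (alg == "SAC") epsilon else 0
      mv <- train_policy(ts_vent, train_config(
        algorithm = alg, epsilon = eps, n_episodes = n_episodes, seed = s,
        stage = "vent"))
      ms <- train_policy(ts_sed, train_config(
        algorithm = alg, epsilon = eps, n_episodes = n_episodes, seed = s,
        stage = "sed"))
      e2t <- episodes_to_threshold(mv$curve, "ar", ar_threshold,
                                   patience = patience)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, algorithm = alg,
        episodes_to_ar = ifelse(is.na(e2t), Inf, e2t),
        final_ar = mv$curve$ar[n_episodes],
        final_mse = ms$curve$mse[n_episodes])
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_seed, per_seed$algorithm),
    function(d) data.frame(algorithm = d$algorithm[1L],
                           episodes_to_ar = median(d$episodes_to_ar),
                           final_ar = median(d$final_ar),
                           final_mse = median(d$final_mse))))
  rownames(summary) <- NULL
  list(per_seed = per_seed, summary = summary)
}
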