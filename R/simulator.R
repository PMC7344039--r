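#' Per-vital read-out anchors of the simulator
#'
#' Each monitored vital is an affine read-out of a scalar latent health
#' `h` in \[0, 1\]: `value = sick + h * (healthy - sick) + noise`. The
#' `healthy` anchor is the midpoint of the vital's normal range; the `sick`
#' anchor lies outside the range on the clinically relevant side (tachypnea,
#' tachycardia, acidosis, high PEEP/FiO2/pressures, hypoxemia,
#' hypotension).
#'
#' @param cfg A [reward_config()] supplying the normal ranges.
#' @return Data frame with columns `vital`, `sick`, `healthy`.
#' @export
vital_anchors <- function(cfg = reward_config()) {
  rg <- cfg$ranges
  mid <- vapply(rg, mean, numeric(1))
  sick <- c(resp_rate = 38, heart_rate = 135, art_ph = 7.15, peep = 14,
            spo2 = 85, fio2 = 0.9, pao2 = 55, plateau_p = 38,
            mean_airway_p = 22, mean_nibp = 52)
  sick <- sick[names(rg)]
  data.frame(vital = names(rg), sick = unname(sick), healthy = unname(mid),
             stringsAsFactors = FALSE)
}

#' Reconstruct a latent health score from an observed state
#'
#' Inverts the simulator's affine read-out per vital and averages: each
#' vital contributes `(value - sick) / (healthy - sick)`, clamped to
#' \[0, 1.2\]. Deterministic in the state; this is the score the synthetic
#' clinician acts on.
#'
#' @param state Named numeric vector (or matrix with vital columns).
#' @param anchors Anchor table from [vital_anchors()].
#' @return Scalar score (or vector, one per matrix row), roughly in
#'   \[0, 1\].
#' @export
health_score <- function(state, anchors = vital_anchors()) {
  if (is.matrix(state) || is.data.frame(state)) {
    V <- as.matrix(state[, anchors$vital, drop = FALSE])
  } else {
    V <- matrix(as.numeric(state[anchors$vital]), nrow = 1)
  }
  Z <- sweep(V, 2, anchors$sick, "-")
  Z <- sweep(Z, 2, anchors$healthy - anchors$sick, "/")
  Z <- pmin(pmax(Z, 0), 1.2)
  out <- rowMeans(Z)
  if (length(out) == 1L) out[[1L]] else out
}

#' Synthetic clinician labeling policy
#'
#' @param wean_threshold Health score at or above which the clinician takes
#'   the patient off the ventilator (default 0.6).
#' @param sed_breakpoints Three strictly increasing health-score
#'   breakpoints partitioning \[0, 1\] into the four sedative bins
#'   (default `c(0.25, 0.45, 0.7)`).
#' @param hysteresis Margin below `wean_threshold` before an already-weaned
#'   patient is reintubated (default 0.1). Clinicians do not flap a patient
#'   on and off the ventilator over read-out noise; the margin makes the
#'   policy stable while remaining a deterministic function of the
#'   13-dimensional state (ventilation status is a state feature).
#' @return List of class `clinician_policy`.
#' @export
clinician_policy_config <- function(wean_threshold = 0.6,
                                    sed_breakpoints = c(0.25, 0.45, 0.7),
                                    hysteresis = 0.1) {
  if (length(sed_breakpoints) != 3L || any(diff(sed_breakpoints) <= 0)) {
    stop("sed_breakpoints must be 3 strictly increasing scalars")
  }
  if (hysteresis < 0) stop("hysteresis must be non-negative")
  structure(list(wean_threshold = wean_threshold,
                 sed_breakpoints = sed_breakpoints,
                 hysteresis = hysteresis),
            class = "clinician_policy")
}

#' Deterministic clinician action for a state
#'
#' The clinician reconstructs the health score from the observed vitals and
#' (i) weans if and only if the score is at or above `wean_threshold` when
#' the patient is ventilated, or above `wean_threshold - hysteresis` when
#' the patient is already off the ventilator (otherwise keeps/places the
#' patient on the ventilator); and (ii) doses sedation by score interval:
#' sicker patients get deeper sedation, so a score below the first
#' breakpoint maps to bin 3 (deepest) and a score at or above the last
#' maps to bin 0 (no/minimal sedation). A score exactly at a breakpoint or
#' threshold belongs to the upper (healthier) interval.
#'
#' @param state Patient state (13-dim named numeric).
#' @param pol A [clinician_policy_config()].
#' @param anchors Anchor table from [vital_anchors()].
#' @return A `composite_action`.
#' @export
#' @examples
#' clinician_policy(example_state(), clinician_policy_config())
clinician_policy <- function(state, pol = clinician_policy_config(),
                             anchors = vital_anchors()) {
  score <- health_score(state, anchors)
  thr <- if (state[["vent_status"]] == 0) {
    pol$wean_threshold - pol$hysteresis
  } else {
    pol$wean_threshold
  }
  vent <- as.integer(score >= thr)
  sed <- 3L - findInterval(score, pol$sed_breakpoints)
  composite_action(vent, sed)
}

#' Simulator configuration
#'
#' Parameters of the synthetic ICU cohort generator. Each admission evolves
#' a scalar latent health by a mean-reverting recovery process; the
#' monitored vitals are affine read-outs plus Gaussian noise
#' ([vital_anchors()]); action labels come from the deterministic
#' [clinician_policy()] corrupted with probability `clinician_noise`
#' (uniform over the 8 composite actions); weaning while latent health is
#' below the wean threshold triggers, with probability
#' `reintubation_prob_if_early`, a health setback that leads the clinician
#' to reintubate.
#'
#' @param n_admissions Number of admissions to simulate.
#' @param seed Integer RNG seed; the cohort is fully reproducible given it.
#' @param mean_stay Mean stay length in 10-minute steps (default 144 =
#'   24 h).
#' @param latent_recovery_rate Mean-reversion rate of latent health per
#'   step (default 0.02).
#' @param vital_noise_sd Read-out noise, as a fraction of each vital's
#'   sick-to-healthy span (default 0.05).
#' @param clinician_noise Probability that a recorded action label deviates
#'   (uniformly) from the deterministic policy, for non-expert admissions
#'   (default 0.01, about one deviation per 17 hours of charting).
#' @param reintubation_prob_if_early Probability that weaning below the
#'   latent threshold is followed by deterioration and reintubation
#'   (default 0.7).
#' @param expert_fraction Fraction of admissions recorded with zero label
#'   noise; these are flagged `expert` (default 0.25).
#' @param sed_calm Per-bin fractional reduction of vital noise under deeper
#'   sedation (default 0.12).
#' @param sed_drag Per-bin fractional slow-down of recovery under deeper
#'   sedation (default 0.08).
#' @param discharge_after Stay ends (ICU discharge) once the patient has
#'   remained off the ventilator for this many consecutive steps (default
#'   36 = 6 h), or at the drawn stay length, whichever is first.
#' @param reward_cfg A [reward_config()].
#' @param policy A [clinician_policy_config()].
#' @return List of class `simulator_config`.
#' @export
simulator_config <- function(n_admissions = 200,
                             seed = 1,
                             mean_stay = 144,
                             latent_recovery_rate = 0.02,
                             vital_noise_sd = 0.05,
                             clinician_noise = 0.01,
                             reintubation_prob_if_early = 0.7,
                             expert_fraction = 0.25,
                             sed_calm = 0.12,
                             sed_drag = 0.08,
                             discharge_after = 36,
                             reward_cfg = reward_config(),
                             policy = clinician_policy_config()) {
  stopifnot(n_admissions >= 1)
  probs <- c(clinician_noise, reintubation_prob_if_early, expert_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_admissions = as.integer(n_admissions),
                 seed = as.integer(seed), mean_stay = mean_stay,
                 latent_recovery_rate = latent_recovery_rate,
                 vital_noise_sd = vital_noise_sd,
                 clinician_noise = clinician_noise,
                 reintubation_prob_if_early = reintubation_prob_if_early,
                 expert_fraction = expert_fraction,
                 sed_calm = sed_calm, sed_drag = sed_drag,
                 discharge_after = as.integer(discharge_after),
                 reward_cfg = reward_cfg, policy = policy),
            class = "simulator_config")
}

#' Simulate a labeled synthetic ICU cohort
#'
#' Generates `cfg$n_admissions` admission trajectories at a 10-minute step.
#' Every admission starts ventilated (the admission intubation counts as
#' the first intubation event). At each step the recorded action is the
#' clinician policy's, or with probability `clinician_noise` a uniform
#' random composite action (never for expert admissions). The ventilation
#' component of the applied action sets the next ventilation status;
#' sedation modulates vital noise and recovery speed. Rewards are filled in
#' by [annotate_rewards()].
#'
#' @param cfg A [simulator_config()].
#' @return List of `icu_trajectory` objects (class `icu_cohort`). Each
#'   trajectory holds `admission_id`, a per-step data frame `df`, logical
#'   `expert`, intubation-event count `n_intubations`, and `stratum`.
#' @export
#' @examples
#' coh <- simulate_cohort(simulator_config(n_admissions = 3, seed = 7))
#' length(coh)
simulate_cohort <- function(cfg = simulator_config()) {
  stopifnot(inherits(cfg, "simulator_config"))
  set.seed(cfg$seed)
  anchors <- vital_anchors(cfg$reward_cfg)
  n_exp <- round(cfg$expert_fraction * cfg$n_admissions)
  expert_flags <- rep(FALSE, cfg$n_admissions)
  if (n_exp > 0) expert_flags[seq_len(n_exp)] <- TRUE
  cohort <- vector("list", cfg$n_admissions)
  for (i in seq_len(cfg$n_admissions)) {
    cohort[[i]] <- simulate_admission(i, expert_flags[i], cfg, anchors)
  }
  structure(cohort, class = "icu_cohort")
}

simulate_admission <- function(admission_id, expert, cfg, anchors) {
  L <- max(36L, round(rlnorm(1, log(cfg$mean_stay), 0.35)))
  h <- runif(1, 0.05, 0.35)
  weight <- round(min(150, max(40, rnorm(1, 80, 15))), 1)
  age <- round(min(95, max(18, rnorm(1, 65, 15))), 1)
  span <- anchors$healthy - anchors$sick
  nvit <- nrow(anchors)
  vent <- 1L
  noise_p <- if (expert) 0 else cfg$clinician_noise
  setback_in <- -1L  # countdown to a scheduled deterioration; <0 = none
  calm <- 1          # sedation carried from the previous step damps noise
  off_streak <- 0L   # consecutive steps off the ventilator (discharge rule)

  action_grid <- all_actions()
  cols <- c("admission_id", "t_index", state_features(), "vent_action",
            "sed_bin")
  M <- matrix(NA_real_, L + 1L, length(cols), dimnames = list(NULL, cols))
  for (t in 0:L) {
    vit <- anchors$sick + h * span +
      rnorm(nvit, 0, calm * cfg$vital_noise_sd * abs(span))
    state <- c(setNames(vit, anchors$vital), weight = weight, age = age,
               vent_status = as.numeric(vent))
    act <- if (noise_p > 0 && runif(1) < noise_p) {
      action_grid[[sample.int(8L, 1L)]]
    } else {
      clinician_policy(state, cfg$policy, anchors)
    }
    M[t + 1L, ] <- c(admission_id, t, state, act$vent, act$sed_bin)
    off_streak <- if (vent == 0L) off_streak + 1L else 0L
    if (t == L || off_streak >= cfg$discharge_after) {
      M <- M[seq_len(t + 1L), , drop = FALSE]
      break
    }

    # apply ventilation decision: action 1 = off ventilator next step
    new_vent <- 1L - act$vent
    early_wean <- vent == 1L && act$vent == 1L && h < cfg$policy$wean_threshold
    if (early_wean && runif(1) < cfg$reintubation_prob_if_early) {
      setback_in <- sample(2:10, 1L)
    }
    if (setback_in == 0L) h <- max(0, h - 0.35)
    if (setback_in >= 0L) setback_in <- setback_in - 1L
    # latent recovery: mean-reverting toward full health, slowed by sedation
    drag <- 1 - cfg$sed_drag * act$sed_bin
    h <- h + cfg$latent_recovery_rate * (1 - h) * drag + rnorm(1, 0, 0.005)
    h <- min(1, max(0, h))
    calm <- 1 - cfg$sed_calm * act$sed_bin
    vent <- new_vent
  }
  df <- annotate_rewards(as.data.frame(M), cfg$reward_cfg)
  vs <- df$vent_status
  n_intub <- 1L + sum(vs[-1] == 1 & vs[-length(vs)] == 0)
  traj <- structure(list(admission_id = admission_id, df = df,
                         expert = expert, n_intubations = n_intub,
                         stratum = NA_character_),
                    class = "icu_trajectory")
  traj$stratum <- trajectory_stratum(traj)
  traj
}

trajectory_stratum <- function(traj) {
  if (isTRUE(traj$expert)) "expert"
  else if (traj$n_intubations >= 2L) "multiple_intubation"
  else "single_intubation"
}

#' Partition a cohort into the three test strata
#'
#' Precedence: admissions recorded with zero label noise form the `expert`
#' stratum; of the rest, those with two or more intubation events (the
#' admission intubation plus at least one reintubation) are
#' `multiple_intubation`, the remainder `single_intubation`. The partition
#' is exhaustive and disjoint.
#'
#' @param cohort An `icu_cohort` (list of `icu_trajectory`).
#' @return Named list of three cohorts: `expert`, `single_intubation`,
#'   `multiple_intubation`.
#' @export
stratify <- function(cohort) {
  strata <- vapply(cohort, trajectory_stratum, character(1))
  out <- lapply(c(expert = "expert", single_intubation = "single_intubation",
                  multiple_intubation = "multiple_intubation"),
                function(s) structure(cohort[strata == s], class = "icu_cohort"))
  out
}

#' @export
print.icu_trajectory <- function(x, ...) {
  cat(sprintf("<icu_trajectory admission %s: %d steps, %d intubation(s), %s%s>\n",
              x$admission_id, nrow(x$df) - 1L, x$n_intubations, x$stratum,
              if (x$expert) ", expert" else ""))
  invisible(x)
}

#' @export
print.icu_cohort <- function(x, ...) {
  n <- vapply(x, function(tr) nrow(tr$df) - 1L, integer(1))
  cat(sprintf("<icu_cohort: %d admissions, %d transitions>\n",
              length(x), sum(n)))
  invisible(x)
}
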