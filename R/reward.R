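#' Reward configuration
#'
#' The per-transition reward decomposes as
#' \deqn{r = r^{vitals} + r^{vent\,off} + r^{vent\,on}}
#' where `r_vitals` rewards physiological stability (the fraction of
#' monitored vitals inside their normal range after the transition, scaled
#' by `w_vitals`), `r_vent_off` scores a weaning decision (+`bonus_success`
#' if the patient is not reintubated within `reintubation_window` steps,
#' −`penalty_failure` if reintubation follows), and `r_vent_on` charges
#' `cost_per_step` for every step still spent on the ventilator.
#'
#' @param w_vitals Weight on the in-range fraction (unitless, default 1).
#' @param bonus_success Bonus for a wean not followed by reintubation within
#'   the window (default 10).
#' @param penalty_failure Penalty when reintubation follows within the
#'   window (default 10; applied with a negative sign).
#' @param reintubation_window Look-ahead window in 10-minute steps
#'   (default 288 = 48 h).
#' @param cost_per_step Cost per 10-minute step on the ventilator
#'   (default 0.5).
#' @param ranges Named list of `c(lo, hi)` normal ranges, one per monitored
#'   vital. The defaults cover the 10 monitored vitals (weight and age are
#'   demographics, not vitals, and are not scored).
#' @return List of class `reward_config`.
#' @export
#' @examples
#' cfg <- reward_config(cost_per_step = 0.25)
#' names(cfg$ranges)
reward_config <- function(w_vitals = 1,
                          bonus_success = 10,
                          penalty_failure = 10,
                          reintubation_window = 288,
                          cost_per_step = 0.5,
                          ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- list(
      resp_rate     = c(12, 25),     # breaths/min
      heart_rate    = c(60, 100),    # beats/min
      art_ph        = c(7.35, 7.45),
      peep          = c(0, 8),       # cmH2O
      spo2          = c(94, 100),    # %
      fio2          = c(0.21, 0.5),  # fraction
      pao2          = c(75, 150),    # mmHg
      plateau_p     = c(5, 30),      # cmH2O
      mean_airway_p = c(5, 15),      # cmH2O
      mean_nibp     = c(70, 105)     # mmHg
    )
  }
  ok <- vapply(ranges, function(x) length(x) == 2L && all(is.finite(x)) &&
                 x[1] <= x[2], logical(1))
  if (!all(ok)) stop("each range must be a finite c(lo, hi) with lo <= hi")
  structure(list(w_vitals = w_vitals, bonus_success = bonus_success,
                 penalty_failure = penalty_failure,
                 reintubation_window = as.integer(reintubation_window),
                 cost_per_step = cost_per_step, ranges = ranges),
            class = "reward_config")
}

#' Fraction of monitored vitals inside their normal ranges
#'
#' @param state Named numeric state vector (must contain every vital named
#'   in `cfg$ranges`).
#' @param cfg A [reward_config()].
#' @return Fraction in \[0, 1\].
#' @export
in_range_fraction <- function(state, cfg = reward_config()) {
  nm <- names(cfg$ranges)
  missing <- setdiff(nm, names(state))
  if (length(missing) > 0L) {
    stop("state lacks vitals configured in reward ranges: ",
         paste(missing, collapse = ", "))
  }
  v <- as.numeric(state[nm])
  if (any(!is.finite(v))) stop("non-finite vital values in state")
  lo <- vapply(cfg$ranges, `[`, numeric(1), 1L)
  hi <- vapply(cfg$ranges, `[`, numeric(1), 2L)
  mean(v >= lo & v <= hi)
}

#' Decomposed reward for one transition
#'
#' @param state State before the action (must contain `vent_status`).
#' @param action A `composite_action` (or list with `vent`, `sed_bin`).
#' @param next_state State after the transition.
#' @param cfg A [reward_config()].
#' @param reintubated Logical: was the patient reintubated within
#'   `cfg$reintubation_window` steps after this transition? Only consulted
#'   when the transition is a weaning event (ventilated and `vent` action =
#'   wean). When scoring a stored trajectory use [annotate_rewards()], which
#'   derives this flag by look-ahead.
#' @return List of class `reward_breakdown` with fields `r_vitals`,
#'   `r_vent_off`, `r_vent_on`, `total` (`total` is the exact sum).
#' @export
#' @examples
#' s <- example_state(); cfg <- reward_config()
#' compute_reward(s, composite_action(1, 0), example_state(0), cfg)
compute_reward <- function(state, action, next_state, cfg = reward_config(),
                           reintubated = FALSE) {
  if (any(!is.finite(as.numeric(state))) ||
      any(!is.finite(as.numeric(next_state)))) {
    stop("non-finite state values")
  }
  r_vitals <- cfg$w_vitals * in_range_fraction(next_state, cfg)
  weaning <- state[["vent_status"]] == 1 && action$vent == 1
  r_vent_off <- if (weaning) {
    if (isTRUE(reintubated)) -cfg$penalty_failure else cfg$bonus_success
  } else 0
  r_vent_on <- if (next_state[["vent_status"]] == 1) -cfg$cost_per_step else 0
  structure(list(r_vitals = r_vitals, r_vent_off = r_vent_off,
                 r_vent_on = r_vent_on,
                 total = r_vitals + r_vent_off + r_vent_on),
            class = "reward_breakdown")
}

#' Annotate a trajectory data frame with decomposed rewards
#'
#' Scores every transition (consecutive row pair) of a single-admission
#' trajectory. The reintubation flag for a weaning event is derived by
#' look-ahead: reintubation means `vent_status` switching 0 to 1 within
#' `cfg$reintubation_window` steps after the wean.
#'
#' @param df Trajectory data frame for one admission (rows ordered by
#'   `t_index`, columns as in [write_trajectory_csv()]).
#' @param cfg A [reward_config()].
#' @return `df` with columns `r_vitals`, `r_vent_off`, `r_vent_on`,
#'   `reward_total` filled for rows 1..n−1 (the last row carries no
#'   transition and gets `NA`).
#' @export
annotate_rewards <- function(df, cfg = reward_config()) {
  n <- nrow(df)
  vs <- df$vent_status
  # step indices (relative to row) at which a 0->1 intubation event occurs
  reintub_at <- which(vs[-1] == 1 & vs[-n] == 0)  # event happens entering row i+1
  r_vitals <- r_off <- r_on <- rep(NA_real_, n)
  nm <- names(cfg$ranges)
  lo <- vapply(cfg$ranges, `[`, numeric(1), 1L)
  hi <- vapply(cfg$ranges, `[`, numeric(1), 2L)
  V <- as.matrix(df[, nm, drop = FALSE])
  in_rng <- sweep(V, 2, lo, ">=") & sweep(V, 2, hi, "<=")
  frac <- rowMeans(in_rng)
  for (i in seq_len(n - 1L)) {
    r_vitals[i] <- cfg$w_vitals * frac[i + 1L]
    weaning <- vs[i] == 1 && df$vent_action[i] == 1
    if (weaning) {
      win <- reintub_at[reintub_at > i & reintub_at <= i + cfg$reintubation_window]
      r_off[i] <- if (length(win) > 0L) -cfg$penalty_failure else cfg$bonus_success
    } else {
      r_off[i] <- 0
    }
    r_on[i] <- if (vs[i + 1L] == 1) -cfg$cost_per_step else 0
  }
  df$r_vitals <- r_vitals
  df$r_vent_off <- r_off
  df$r_vent_on <- r_on
  df$reward_total <- r_vitals + r_off + r_on
  df
}

#' Discounted return of a reward sequence or trajectory
#'
#' \eqn{\sum_t \gamma^t r_t} over the transitions of a trajectory.
#'
#' @param traj Either a numeric vector of per-step rewards, a trajectory
#'   data frame with a `reward_total` column, or an `icu_trajectory`.
#' @param gamma Discount factor in \[0, 1\].
#' @return Scalar return.
#' @export
#' @examples
#' discounted_return(c(2, -1, 4), gamma = 0.5)  # 2.5
discounted_return <- function(traj, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("gamma must be a scalar in [0, 1]")
  }
  r <- if (is.numeric(traj)) {
    traj
  } else if (inherits(traj, "icu_trajectory")) {
    traj$df$reward_total
  } else if (is.data.frame(traj)) {
    traj$reward_total
  } else {
    stop("traj must be a numeric vector, data frame, or icu_trajectory")
  }
  r <- r[!is.na(r)]
  if (length(r) == 0L) return(0)
  sum(gamma^(seq_along(r) - 1L) * r)
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat(sprintf("reward: vitals=%.4f vent_off=%.2f vent_on=%.2f total=%.4f\n",
              x$r_vitals, x$r_vent_off, x$r_vent_on, x$total))
  invisible(x)
}
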