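# central finite-difference gradient of a scalar function of mlp params
numeric_grad <- function(f, params, eps = 1e-6) {
  g <- params
  for (nm in c("W1", "b1", "W2", "b2")) {
    arr <- params[[nm]]
    garr <- arr
    for (i in seq_along(arr)) {
      p_hi <- params; p_hi[[nm]][i] <- arr[i] + eps
      p_lo <- params; p_lo[[nm]][i] <- arr[i] - eps
      garr[i] <- (f(p_hi) - f(p_lo)) / (2 * eps)
    }
    g[[nm]] <- garr
  }
  g
}

# worst relative disagreement between analytic and numeric gradients
grad_rel_err <- function(ga, gn) {
  worst <- 0
  for (nm in c("W1", "b1", "W2", "b2")) {
    err <- abs(ga[[nm]] - gn[[nm]]) / pmax(abs(gn[[nm]]), 1)
    worst <- max(worst, err)
  }
  worst
}

# the blended actor objective as a scalar, for finite differencing:
# (1-eps) * mean(td * log pi(a|s)) - eps * mean(-log pi(label|s))
blended_objective <- function(params, S, actions, td, labels, eps_blend) {
  P <- actor_forward(params, S)
  n <- nrow(S)
  lp_a <- log(P[cbind(seq_len(n), actions + 1L)])
  lp_l <- log(P[cbind(seq_len(n), labels + 1L)])
  (1 - eps_blend) * mean(td * lp_a) + eps_blend * mean(lp_l)
}

# small cohort for training tests (short stays keep the suite fast)
tiny_cohort <- function(n = 20, seed = 5, noise = 0.01, mean_stay = 40) {
  simulate_cohort(simulator_config(
    n_admissions = n, seed = seed, mean_stay = mean_stay,
    clinician_noise = noise))
}

# a hand-set patient state: exactly 5 of the 10 monitored vitals in range
# (resp_rate, art_ph, spo2, pao2, mean_nibp in; the others out)
half_in_range_state <- function(vent_status = 1) {
  patient_state(
    resp_rate = 18, heart_rate = 120, art_ph = 7.40, peep = 12, spo2 = 97,
    fio2 = 0.8, pao2 = 90, plateau_p = 34, mean_airway_p = 18,
    mean_nibp = 80, weight = 80, age = 60, vent_status = vent_status)
}
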