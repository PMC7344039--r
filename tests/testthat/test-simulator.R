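test_that("the simulator is deterministic given its seed", {
  cfg <- simulator_config(n_admissions = 5, seed = 17, mean_stay = 40)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulator_config(n_admissions = 5, seed = 18,
                                         mean_stay = 40))
  expect_false(identical(cohort_to_df(a), cohort_to_df(c2)))
})

test_that("with zero label noise every recorded action is the policy's", {
  coh <- simulate_cohort(simulator_config(n_admissions = 6, seed = 3,
                                          mean_stay = 40,
                                          clinician_noise = 0))
  pol <- clinician_policy_config()
  for (tr in coh) {
    for (i in seq_len(nrow(tr$df))) {
      st <- as.numeric(tr$df[i, state_features()])
      names(st) <- state_features()
      act <- clinician_policy(st, pol)
      expect_equal(tr$df$vent_action[i], act$vent)
      expect_equal(tr$df$sed_bin[i], act$sed_bin)
    }
  }
})

test_that("clinician policy is monotone in health with a documented tie rule", {
  pol <- clinician_policy_config(wean_threshold = 0.6,
                                 sed_breakpoints = c(0.25, 0.45, 0.7))
  anchors <- vital_anchors()
  state_at <- function(h, vent = 1) {
    v <- anchors$sick + h * (anchors$healthy - anchors$sick)
    st <- c(setNames(v, anchors$vital), weight = 80, age = 60,
            vent_status = vent)
    st
  }
  hs <- seq(0, 1, by = 0.01)
  wean <- vapply(hs, function(h) clinician_policy(state_at(h), pol)$vent,
                 integer(1))
  expect_true(all(diff(wean) >= 0))  # raising health never revokes weaning
  bins <- vapply(hs, function(h) clinician_policy(state_at(h), pol)$sed_bin,
                 integer(1))
  expect_true(all(diff(bins) <= 0))  # deeper sedation only when sicker

  # exact breakpoint goes to the upper (healthier) interval; unit anchors
  # make the score reconstruction exact so the boundary is hit precisely
  unit_anchors <- data.frame(vital = anchors$vital, sick = 0, healthy = 1)
  state_exact <- function(h, vent = 1) {
    c(setNames(rep(h, nrow(anchors)), anchors$vital), weight = 80,
      age = 60, vent_status = vent)
  }
  expect_equal(clinician_policy(state_exact(0.45), pol, unit_anchors)$sed_bin,
               1L)
  expect_equal(clinician_policy(state_exact(0.6), pol, unit_anchors)$vent, 1L)
  expect_equal(clinician_policy(state_exact(0.59), pol, unit_anchors)$vent, 0L)
  # far above all breakpoints: wean, minimal sedation
  top <- clinician_policy(state_at(1), pol)
  expect_equal(top$vent, 1L)
  expect_equal(top$sed_bin, 0L)
})

test_that("strata form a true partition with the documented precedence", {
  coh <- simulate_cohort(simulator_config(n_admissions = 40, seed = 9,
                                          mean_stay = 60))
  st <- stratify(coh)
  expect_named(st, c("expert", "single_intubation", "multiple_intubation"))
  expect_equal(sum(lengths(st)), length(coh))
  ids <- unname(unlist(lapply(st, function(s) vapply(s, function(tr)
    tr$admission_id, numeric(1)))))
  expect_equal(sort(ids), sort(vapply(coh, function(tr) tr$admission_id,
                                      numeric(1))))
  for (tr in st$multiple_intubation) expect_gte(tr$n_intubations, 2L)
  for (tr in st$expert) expect_true(tr$expert)

  # an all-expert cohort lands entirely in the expert stratum
  cohE <- simulate_cohort(simulator_config(n_admissions = 10, seed = 2,
                                           mean_stay = 40,
                                           expert_fraction = 1))
  expect_equal(length(stratify(cohE)$expert), 10L)
})

test_that("no early-wean reintubation and clean labels give no repeat intubations", {
  coh <- simulate_cohort(simulator_config(
    n_admissions = 60, seed = 21, mean_stay = 60, clinician_noise = 0,
    expert_fraction = 0, reintubation_prob_if_early = 0))
  st <- stratify(coh)
  expect_equal(length(st$multiple_intubation), 0L)
})

test_that("cohorts recover: in-range fraction rises over the stay", {
  coh <- simulate_cohort(simulator_config(n_admissions = 200, seed = 14))
  cfg <- reward_config()
  lo <- vapply(cfg$ranges, `[`, numeric(1), 1L)
  hi <- vapply(cfg$ranges, `[`, numeric(1), 2L)
  early <- late <- numeric(length(coh))
  for (i in seq_along(coh)) {
    df <- coh[[i]]$df
    n <- nrow(df)
    q <- max(2L, floor(n / 4))
    V <- as.matrix(df[, names(cfg$ranges)])
    frac <- rowMeans(sweep(V, 2, lo, ">=") & sweep(V, 2, hi, "<="))
    early[i] <- mean(frac[1:q])
    late[i] <- mean(frac[(n - q + 1):n])
  }
  expect_gt(mean(late), mean(early) + 0.2)
})
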