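Package: icusac
Title: Supervised Actor-Critic Learning for ICU Ventilation Weaning and
    Sedative Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline reinforcement learning for two intensive-care decision
    problems: weaning a patient from mechanical ventilation and choosing a
    discretized sedative (propofol) dose. Implements a supervised actor-critic
    in which the actor's policy-gradient objective is blended with a
    behavior-cloning term toward recorded clinician actions, alongside the
    plain actor-critic baseline, temporal-difference critic updates with a
    target network, and small feed-forward function approximators with
    analytically derived gradients. Ships a synthetic patient-trajectory
    simulator that emulates the statistical structure of an ICU cohort
    (latent recovery process, vital-sign read-outs, intubation and
    reintubation events, a deterministic-plus-noise clinician labeling
    policy), cohort filtering and support-vector-regression resampling of
    irregular measurements onto a 10-minute grid, and an evaluation harness
    for accuracy rate, dose mean-squared error, convergence speed, and
    stratified comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
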