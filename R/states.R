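#' Names of the 12 physiological/ventilator state features
#'
#' The patient state is these 12 features plus `vent_status` (is the patient
#' currently on mechanical ventilation), giving a 13-dimensional vector.
#'
#' @return Character vector of length 12.
#' @export
#' @examples
#' physio_features()
physio_features <- function() {
  c("resp_rate", "heart_rate", "art_ph", "peep", "spo2", "fio2",
    "pao2", "plateau_p", "mean_airway_p", "mean_nibp", "weight", "age")
}

#' Names of the full 13-dimensional patient state
#'
#' @return Character vector of length 13 (`physio_features()` plus
#'   `vent_status`).
#' @export
state_features <- function() c(physio_features(), "vent_status")

#' Construct a patient state vector
#'
#' A patient state is a named numeric vector of length 13: the 12
#' physiological/ventilator features and a binary ventilation status.
#'
#' @param ... Named feature values; every name in [state_features()] must be
#'   supplied (individually or via a single named vector/list).
#' @return Named numeric vector of length 13 with class `patient_state`.
#' @export
#' @examples
#' s <- patient_state(resp_rate = 18, heart_rate = 80, art_ph = 7.4,
#'   peep = 5, spo2 = 97, fio2 = 0.3, pao2 = 90, plateau_p = 18,
#'   mean_airway_p = 10, mean_nibp = 85, weight = 80, age = 65,
#'   vent_status = 1)
patient_state <- function(...) {
  vals <- list(...)
  if (length(vals) == 1L && is.null(names(vals)) || (length(vals) == 1L &&
      (is.list(vals[[1L]]) || length(vals[[1L]]) > 1L))) {
    vals <- as.list(vals[[1L]])
  }
  feats <- state_features()
  missing <- setdiff(feats, names(vals))
  if (length(missing) > 0L) {
    stop("patient_state(): missing features: ", paste(missing, collapse = ", "))
  }
  s <- vapply(vals[feats], as.numeric, numeric(1))
  validate_state(s)
  structure(s, class = "patient_state")
}

validate_state <- function(s) {
  if (length(s) != 13L) stop("patient state must have exactly 13 entries")
  if (any(!is.finite(s))) stop("patient state contains non-finite values")
  if (!s[["vent_status"]] %in% c(0, 1)) stop("vent_status must be 0 or 1")
  invisible(s)
}

#' Augment a patient state with the ventilation action (sedation-stage state)
#'
#' The sedation MDP conditions the dose choice on the ventilation decision,
#' so its state is the 13-dimensional patient state with the binary
#' ventilation action appended as a 14th coordinate named `vent_action`.
#'
#' @param s Patient state (named numeric of length 13).
#' @param vent_action Binary ventilation action (0 = keep on ventilator,
#'   1 = wean).
#' @return Named numeric vector of length 14.
#' @export
#' @examples
#' s <- example_state()
#' length(build_sedation_state(s, 1))
build_sedation_state <- function(s, vent_action) {
  if (length(s) != 13L) stop("expected a 13-dimensional patient state")
  if (!vent_action %in% c(0, 1)) stop("vent_action must be 0 or 1")
  out <- c(as.numeric(s), as.numeric(vent_action))
  names(out) <- c(state_features(), "vent_action")
  out
}

#' A stable example patient state (all vitals in their normal ranges)
#'
#' Convenience fixture: a ventilated patient whose 10 monitored vitals all
#' sit at the midpoint of the default normal ranges.
#'
#' @param vent_status Ventilation status for the returned state.
#' @return A `patient_state`.
#' @export
example_state <- function(vent_status = 1) {
  rg <- reward_config()$ranges
  mid <- vapply(rg, function(x) mean(x), numeric(1))
  patient_state(c(as.list(mid), list(weight = 80, age = 65,
                                     vent_status = vent_status)))
}
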