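#' Construct a composite ICU action
#'
#' An action pairs the binary ventilation decision (0 = keep the patient on
#' the ventilator, 1 = wean) with one of four discretized sedative
#' (propofol) dose bins. The joint space therefore has exactly 8 elements.
#'
#' @param vent 0 or 1.
#' @param sed_bin Integer in 0..3.
#' @return List with fields `vent` and `sed_bin`, class `composite_action`.
#' @export
#' @examples
#' composite_action(0, 2)
composite_action <- function(vent, sed_bin) {
  if (!vent %in% c(0, 1)) stop("vent must be 0 or 1")
  if (!sed_bin %in% 0:3) stop("sed_bin must be in 0..3")
  structure(list(vent = as.integer(vent), sed_bin = as.integer(sed_bin)),
            class = "composite_action")
}

#' All 8 composite actions
#'
#' @return List of the 8 `composite_action`s, vent-major order
#'   ((0,0), (0,1), ..., (1,3)).
#' @export
all_actions <- function() {
  out <- list()
  for (v in 0:1) for (b in 0:3) out[[length(out) + 1L]] <- composite_action(v, b)
  out
}

#' One-hot encode a label list against an ordered vocabulary
#'
#' Each category gets its own register bit; exactly one bit is active per
#' row, at the vocabulary index of the label.
#'
#' @param labels Vector of labels (character or factor or integer).
#' @param vocabulary Ordered vector of all categories.
#' @return Integer matrix, `length(labels)` rows by `length(vocabulary)`
#'   columns; row sums are all 1.
#' @export
#' @examples
#' one_hot(c("red", "yellow", "blue"), c("blue", "yellow", "red"))
one_hot <- function(labels, vocabulary) {
  if (anyDuplicated(vocabulary)) stop("vocabulary has duplicate entries")
  idx <- match(labels, vocabulary)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("labels not in vocabulary: ", paste(bad, collapse = ", "))
  }
  m <- matrix(0L, nrow = length(labels), ncol = length(vocabulary))
  m[cbind(seq_along(idx), idx)] <- 1L
  colnames(m) <- as.character(vocabulary)
  m
}

#' Decode a one-hot matrix back to vocabulary labels
#'
#' @param m One-hot matrix as produced by [one_hot()].
#' @param vocabulary Ordered vector of categories (defaults to `colnames(m)`).
#' @return Vector of labels.
#' @export
one_hot_decode <- function(m, vocabulary = colnames(m)) {
  vocabulary[max.col(m, ties.method = "first")]
}

#' One-hot encode a composite action
#'
#' Ventilation and sedative components are encoded separately: a length-2
#' block (index 1 = keep, index 2 = wean) and a length-4 block (index 1 =
#' bin 0, ..., index 4 = bin 3). Exactly one bit is active in each block.
#'
#' @param action A `composite_action`.
#' @return List with `vent` (length-2 0/1 vector) and `sed` (length-4 0/1
#'   vector).
#' @export
#' @examples
#' encode_action(composite_action(0, 2))
encode_action <- function(action) {
  if (!inherits(action, "composite_action")) {
    action <- composite_action(action$vent, action$sed_bin)
  }
  vent <- integer(2); vent[action$vent + 1L] <- 1L
  sed <- integer(4); sed[action$sed_bin + 1L] <- 1L
  list(vent = vent, sed = sed)
}

#' Decode one-hot vent/sed blocks back to a composite action
#'
#' @param enc List with `vent` (length 2) and `sed` (length 4) one-hot
#'   vectors.
#' @return A `composite_action`.
#' @export
decode_action <- function(enc) {
  if (sum(enc$vent == 1L) != 1L || sum(enc$sed == 1L) != 1L) {
    stop("each one-hot block must have exactly one active bit")
  }
  composite_action(which.max(enc$vent) - 1L, which.max(enc$sed) - 1L)
}

#' @export
print.composite_action <- function(x, ...) {
  cat(sprintf("<action vent=%s sed_bin=%d>\n",
              c("keep", "wean")[x$vent + 1L], x$sed_bin))
  invisible(x)
}
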