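# Step directions and dance sequences.
#
# A step direction is one of UP/DOWN/LEFT/RIGHT, encoded "U","D","L","R".
# On a four-panel dance mat these correspond to the arrow panels and, on the
# presentation side, to the keyboard keys W, S, A, D. A dance sequence is an
# ordered pattern of directions (default length 6, usable 3-7) and is the
# unit of sequence learning.

#' @rdname dance_sequence
#' @format `STEP_DIRECTIONS`: the closed set of step codes.
#' @export
STEP_DIRECTIONS <- c(UP = "U", DOWN = "D", LEFT = "L", RIGHT = "R")

#' Keyboard key registered for each step direction
#' @format named character vector, direction code -> key label.
#' @export
STEP_KEYS <- c(U = "W", D = "S", L = "A", R = "D")

# Clockwise quarter-turn of the mat: LEFT->UP, UP->RIGHT, RIGHT->DOWN, DOWN->LEFT.
.ROTATE_CW <- c(L = "U", U = "R", R = "D", D = "L")

#' Dance sequences
#'
#' `dance_sequence()` builds a sequence of step directions from a compact
#' string (`"LRUDRL"`) or a character vector of step codes.
#'
#' @param steps character scalar like `"LRUDRL"`, or a character vector of
#'   codes from `STEP_DIRECTIONS`.
#' @return a `dance_sequence`: a character vector of step codes.
#' @examples
#' dance_sequence("LRUDRL")
#' rotate_sequence(dance_sequence("LRUDRL"), 1)  # "UDRLDU"
#' @export
dance_sequence <- function(steps) {
  if (inherits(steps, "dance_sequence")) steps <- unclass(steps)
  if (is.character(steps) && length(steps) == 1L && nchar(steps) > 1L) {
    steps <- strsplit(steps, "")[[1L]]
  }
  steps <- toupper(as.character(steps))
  if (length(steps) < 1L) {
    stop_invalid("a dance sequence needs at least one step")
  }
  bad <- setdiff(steps, STEP_DIRECTIONS)
  if (length(bad)) {
    stop_invalid("invalid step direction(s): %s (use U, D, L, R)",
                 paste(unique(bad), collapse = ", "))
  }
  structure(steps, class = "dance_sequence")
}

#' @export
format.dance_sequence <- function(x, ...) paste(unclass(x), collapse = "")

#' @export
print.dance_sequence <- function(x, ...) {
  cat("<dance_sequence> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.dance_sequence <- function(x, ...) format(x)

#' Rotate a sequence by quarter turns of the mat
#'
#' Applies the clockwise direction map (LEFT->UP, UP->RIGHT, RIGHT->DOWN,
#' DOWN->LEFT) `quarter_turns` times to every step. Rotation produces a
#' positionally different but structurally identical sequence, the basis of
#' the counterbalancing scheme.
#'
#' @param seq a [dance_sequence()].
#' @param quarter_turns integer; reduced modulo 4 (negative allowed).
#' @return the rotated `dance_sequence`, same length.
#' @export
rotate_sequence <- function(seq, quarter_turns) {
  seq <- dance_sequence(seq)
  k <- as.integer(quarter_turns) %% 4L
  steps <- unclass(seq)
  for (i in seq_len(k)) steps <- unname(.ROTATE_CW[steps])
  dance_sequence(steps)
}

#' Build the rotation-counterbalance set of two base sequences
#'
#' Both base sequences are rotated through all four quarter turns, giving
#' eight counterbalanced sequences; participants practice the same sequence
#' structure at different mat positions.
#'
#' @param seqA,seqB base [dance_sequence()]s of equal length.
#' @return a named list of 8 sequences, ordered `A0, B0, A1, B1, ... A3, B3`
#'   (letter = base sequence, digit = quarter turns).
#' @export
build_counterbalance_set <- function(seqA, seqB) {
  seqA <- dance_sequence(seqA)
  seqB <- dance_sequence(seqB)
  if (length(seqA) != length(seqB)) {
    stop_invalid("base sequences must have equal length (%d vs %d)",
                 length(seqA), length(seqB))
  }
  out <- list()
  for (k in 0:3) {
    out[[sprintf("A%d", k)]] <- rotate_sequence(seqA, k)
    out[[sprintf("B%d", k)]] <- rotate_sequence(seqB, k)
  }
  strs <- vapply(out, format, character(1))
  if (anyDuplicated(strs)) {
    dup <- strs[duplicated(strs)][1L]
    pair <- names(strs)[strs == dup]
    stop_invalid(
      "degenerate counterbalance set: %s and %s both give %s",
      pair[1L], pair[2L], dup
    )
  }
  out
}

#' Deterministically assign a participant their sequence pair
#'
#' Participant `i` practices both base sequences rotated by `i mod 4`
#' quarter turns, so consecutive participants cycle through the whole
#' counterbalance set.
#'
#' @param cb_set the list from [build_counterbalance_set()].
#' @param participant_index non-negative integer.
#' @return list of two sequences `(A, B)` at the participant's rotation.
#' @export
assign_participant_pair <- function(cb_set, participant_index) {
  stopifnot(participant_index >= 0)
  k <- as.integer(participant_index) %% 4L
  list(A = cb_set[[sprintf("A%d", k)]], B = cb_set[[sprintf("B%d", k)]])
}
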