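#' Health states of the daily-cycle model
#'
#' The model tracks hospitalized patients through five mutually exclusive
#' health states: the normal ward (`WARD`, the sole initial state), an
#' in-hospital complication state (`COMPLICATION`), intensive care (`ICU`),
#' post-discharge survival (`DISCHARGED`) and death (`DEAD`, absorbing).
#'
#' @return Character vector of the five state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("WARD", "COMPLICATION", "ICU", "DISCHARGED", "DEAD")
}

#' @rdname health_states
#' @return `alive_states()`: the four non-absorbing labels.
#' @export
alive_states <- function() {
  setdiff(health_states(), "DEAD")
}

#' Default structural transition mask
#'
#' Boolean 5x5 matrix of which daily transitions are structurally allowed.
#' Ward patients may stay, develop a complication, be transferred to the ICU,
#' be discharged, or die. Complication patients may additionally recover back
#' to the ward. ICU patients may return to the ward or the complication state
#' but are not discharged directly. Discharged patients may remain out of
#' hospital, be readmitted non-electively (to the ward) or die. Death is
#' absorbing. The mask is an input everywhere a matrix is validated or
#' calibrated, so alternative structural readings are expressible.
#'
#' @return 5x5 logical matrix with state labels as dimnames.
#' @export
#' @examples
#' default_mask()["DISCHARGED", ]
default_mask <- function() {
  s <- health_states()
  m <- matrix(FALSE, 5, 5, dimnames = list(s, s))
  m["WARD", c("WARD", "COMPLICATION", "ICU", "DISCHARGED", "DEAD")] <- TRUE
  m["COMPLICATION", c("COMPLICATION", "WARD", "ICU", "DISCHARGED", "DEAD")] <- TRUE
  m["ICU", c("ICU", "WARD", "COMPLICATION", "DEAD")] <- TRUE
  m["DISCHARGED", c("DISCHARGED", "WARD", "DEAD")] <- TRUE
  m["DEAD", "DEAD"] <- TRUE
  m
}
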