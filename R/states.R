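#' Health-state space for the cohort model
#'
#' The base model uses four health states -- \code{stable}, \code{recurrence},
#' \code{metastasis} and \code{death} -- with death absorbing. The state order
#' is fixed and shared by every transition matrix, occupancy trace and utility
#' set, so that vectors and matrices line up by position as well as by name.
#'
#' @param states Character vector of state labels, in model order.
#' @param absorbing Character vector naming the absorbing states; must be a
#'   subset of \code{states}.
#' @return An object of class \code{state_space}: a character vector of state
#'   labels with an \code{absorbing} attribute.
#' @examples
#' state_space()
#' @export
state_space <- function(states = c("stable", "recurrence", "metastasis", "death"),
                        absorbing = "death") {
  states <- as.character(states)
  if (anyDuplicated(states)) {
    stop("state labels must be unique", call. = FALSE)
  }
  if (length(states) < 2L) {
    stop("a state space needs at least two states", call. = FALSE)
  }
  if (!all(absorbing %in% states)) {
    stop("absorbing states must be among the state labels", call. = FALSE)
  }
  structure(states, absorbing = as.character(absorbing), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", paste(unclass(x), collapse = " -> "), "\n")
  cat("Absorbing:  ", paste(attr(x, "absorbing"), collapse = ", "), "\n")
  invisible(x)
}

absorbing_states <- function(space) attr(space, "absorbing")

# Default four-state space used throughout the base analysis.
default_states <- function() state_space()

# Match a labelled object (matrix dimnames or vector names) against a state
# space; unknown labels are an error, order is normalised to model order.
check_state_labels <- function(labels, space, what = "state") {
  unknown <- setdiff(labels, unclass(space))
  if (length(unknown)) {
    stop(sprintf("unknown %s label(s): %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
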