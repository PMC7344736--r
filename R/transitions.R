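#' Transition count tables
#'
#' A transition count table records, for one study arm, the number of observed
#' annual from-state to to-state transitions. Counts are nonnegative integers;
#' rows for absorbing states (death) must be all zero, since no transitions
#' out of death are ever observed.
#'
#' @param counts A square numeric matrix of nonnegative integers with rows =
#'   from-state and columns = to-state, dimnames matching the state space, or
#'   an unnamed matrix in model state order.
#' @param arm Arm name (free text), carried as an attribute.
#' @param space A \code{\link{state_space}}.
#' @return An object of class \code{transition_counts} (an integer matrix with
#'   \code{arm} and \code{space} attributes).
#' @examples
#' cnt <- transition_counts(rbind(
#'   stable     = c(58, 3, 9, 8),
#'   recurrence = c(3, 0, 0, 0),
#'   metastasis = c(9, 0, 0, 0),
#'   death      = c(0, 0, 0, 0)), arm = "control")
#' rowSums(cnt)
#' @export
transition_counts <- function(counts, arm = "", space = state_space()) {
  counts <- as.matrix(counts)
  ns <- length(space)
  if (!all(dim(counts) == ns)) {
    stop(sprintf("counts must be a %dx%d matrix", ns, ns), call. = FALSE)
  }
  counts <- align_state_dimnames(counts, space)
  if (any(is.na(counts))) stop("counts must not contain NA", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  for (a in absorbing_states(space)) {
    if (any(counts[a, ] != 0)) {
      stop(sprintf("transitions out of absorbing state '%s' are not allowed", a),
           call. = FALSE)
    }
  }
  storage.mode(counts) <- "integer"
  structure(counts, arm = arm, space = space,
            class = c("transition_counts", "matrix", "array"))
}

#' @export
print.transition_counts <- function(x, ...) {
  arm <- attr(x, "arm")
  cat("Transition counts", if (nzchar(arm)) sprintf("(arm: %s)", arm), "\n")
  print(bare_matrix(x))
  invisible(x)
}

#' Read a transition count table from delimited text
#'
#' Two layouts are supported. \emph{Long}: a header \code{from_state,
#' to_state, count} (an optional \code{arm} column must be constant).
#' \emph{Wide}: a labelled square grid, first column holding the from-state
#' labels and the remaining column names the to-states.
#'
#' @param path Path to a delimited text file.
#' @param format \code{"long"} or \code{"wide"}.
#' @param arm Arm name; defaults to the file's \code{arm} column (long format)
#'   or the file name.
#' @param sep Field separator, default comma.
#' @param space A \code{\link{state_space}}.
#' @return A \code{\link{transition_counts}} object.
#' @export
read_counts <- function(path, format = c("long", "wide"), arm = NULL,
                        sep = ",", space = state_space()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) stop("empty counts file: ", path, call. = FALSE)
  ns <- length(space)
  cnt <- matrix(0L, ns, ns, dimnames = list(unclass(space), unclass(space)))
  if (format == "long") {
    need <- c("from_state", "to_state", "count")
    if (!all(need %in% names(df))) {
      stop("long format needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    check_state_labels(df$from_state, space, "from_state")
    check_state_labels(df$to_state, space, "to_state")
    if (anyDuplicated(df[c("from_state", "to_state")])) {
      stop("duplicate (from_state, to_state) cell in ", path, call. = FALSE)
    }
    if (!is.numeric(df$count) || any(abs(df$count - round(df$count)) > 1e-8)) {
      stop("counts must be integers", call. = FALSE)
    }
    if (is.null(arm)) {
      arm <- if ("arm" %in% names(df)) unique(df$arm) else basename(path)
      if (length(arm) != 1L) stop("multiple arms in one file", call. = FALSE)
    }
    cnt[cbind(df$from_state, df$to_state)] <- as.integer(df$count)
  } else {
    from <- as.character(df[[1L]])
    check_state_labels(from, space, "from_state")
    check_state_labels(names(df)[-1L], space, "to_state")
    if (anyDuplicated(from)) stop("duplicate from_state row", call. = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m) || any(abs(m - round(m)) > 1e-8)) {
      stop("counts must be integers", call. = FALSE)
    }
    cnt[from, colnames(m)] <- as.integer(round(m))
    if (is.null(arm)) arm <- basename(path)
  }
  transition_counts(cnt, arm = arm, space = space)
}

#' Estimate a transition matrix from observed counts
#'
#' Each row of the transition matrix is the row of counts divided by its row
#' total (the maximum-likelihood multinomial estimate). Absorbing rows become
#' unit vectors onto themselves. A non-absorbing row with zero observed
#' transitions is set to a self-loop, with a warning, so the chain stays
#' well-defined without inventing mortality.
#'
#' @param counts A \code{\link{transition_counts}} object (or a matrix
#'   acceptable to its constructor).
#' @return A \code{\link{transition_matrix}} with \code{source = "estimated"}.
#' @examples
#' cnt <- transition_counts(rbind(
#'   stable     = c(58, 3, 9, 8),
#'   recurrence = c(3, 0, 0, 0),
#'   metastasis = c(9, 0, 0, 0),
#'   death      = c(0, 0, 0, 0)), arm = "control")
#' estimate_transition_matrix(cnt)
#' @export
estimate_transition_matrix <- function(counts) {
  if (!inherits(counts, "transition_counts")) counts <- transition_counts(counts)
  space <- attr(counts, "space")
  states <- unclass(space)
  abso <- absorbing_states(space)
  tot <- rowSums(counts)
  if (all(tot[setdiff(states, abso)] == 0)) {
    stop("no observed transitions in any non-absorbing row", call. = FALSE)
  }
  p <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  for (s in states) {
    if (s %in% abso) {
      p[s, s] <- 1
    } else if (tot[s] > 0) {
      p[s, ] <- counts[s, ] / tot[s]
    } else {
      warning(sprintf("row '%s' has no observed transitions; set to self-loop", s),
              call. = FALSE)
      p[s, s] <- 1
    }
  }
  new_transition_matrix(p, source = "estimated", space = space,
                        arm = attr(counts, "arm"))
}

#' Transition matrices
#'
#' Construct a row-stochastic transition matrix from explicit probabilities,
#' e.g. printed (rounded) values from a publication. Rows whose sum differs
#' from 1 by at most \code{slack} (default 0.01, three-decimal rounding slack)
#' are renormalised with a message; a larger deviation is an error. Absorbing
#' rows are forced to exact unit vectors.
#'
#' @param probs Square numeric matrix of probabilities in [0, 1]; dimnames as
#'   in \code{\link{transition_counts}}.
#' @param arm Optional arm name.
#' @param space A \code{\link{state_space}}.
#' @param slack Maximum tolerated absolute deviation of a row sum from 1
#'   before renormalisation is refused.
#' @return An object of class \code{transition_matrix} with
#'   \code{source = "literal"}; rows sum to 1 within 1e-9.
#' @examples
#' transition_matrix(rbind(
#'   stable     = c(0.744, 0.038, 0.115, 0.103),
#'   recurrence = c(1, 0, 0, 0),
#'   metastasis = c(1, 0, 0, 0),
#'   death      = c(0, 0, 0, 1)), arm = "control")
#' @export
transition_matrix <- function(probs, arm = "", space = state_space(),
                              slack = 0.01) {
  probs <- as.matrix(probs)
  ns <- length(space)
  if (!all(dim(probs) == ns)) {
    stop(sprintf("probs must be a %dx%d matrix", ns, ns), call. = FALSE)
  }
  probs <- align_state_dimnames(probs, space)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (a in absorbing_states(space)) {
    probs[a, ] <- 0
    probs[a, a] <- 1
  }
  rs <- rowSums(probs)
  off <- abs(rs - 1) > 1e-9
  if (any(abs(rs - 1) > slack)) {
    bad <- rownames(probs)[abs(rs - 1) > slack]
    stop(sprintf("row sum of '%s' deviates from 1 by more than %g",
                 paste(bad, collapse = ", "), slack), call. = FALSE)
  }
  if (any(off)) {
    message("renormalising row(s) ", paste(rownames(probs)[off], collapse = ", "),
            " to sum to 1 (printed-value rounding)")
    probs[off, ] <- probs[off, , drop = FALSE] / rs[off]
  }
  new_transition_matrix(probs, source = "literal", space = space, arm = arm)
}

new_transition_matrix <- function(p, source, space, arm = "") {
  stopifnot(max(abs(rowSums(p) - 1)) <= 1e-9)
  structure(p, source = source, space = space, arm = arm,
            class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  arm <- attr(x, "arm")
  cat(sprintf("Transition matrix (%s%s)\n", attr(x, "source"),
              if (nzchar(arm)) paste0(", arm: ", arm) else ""))
  print(round(bare_matrix(x), digits))
  invisible(x)
}

# Strip class and bookkeeping attributes, keeping dim/dimnames.
bare_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  y
}

# Fill in or normalise dimnames against the state space; labelled rows or
# columns may come in any order, unlabelled ones are taken in model order.
align_state_dimnames <- function(m, space) {
  states <- unclass(space)
  if (is.null(rownames(m))) rownames(m) <- states
  if (is.null(colnames(m))) colnames(m) <- states
  check_state_labels(rownames(m), space)
  check_state_labels(colnames(m), space)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate state labels in matrix dimnames", call. = FALSE)
  }
  m[states, states, drop = FALSE]
}

is_stochastic <- function(m, tol = 1e-9) {
  is.matrix(m) && nrow(m) == ncol(m) && all(m >= -tol) &&
    max(abs(rowSums(m) - 1)) <= tol
}
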