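#' Configuration for a synthetic patient cohort
#'
#' Describes one arm of a synthetic registry: arm size, the true annual
#' transition matrix, a fixed follow-up length, and a two-component gamma
#' cost model (a main component every patient incurs, plus a second component
#' -- e.g. a second chemotherapy line or the trastuzumab course -- incurred
#' with probability \code{second_fraction}).
#'
#' @param arm_name Arm label.
#' @param n_patients Number of patients (>= 1).
#' @param matrix True \code{\link{transition_matrix}} generating the annual
#'   state sequence.
#' @param follow_up_years Fixed follow-up length in years (default 8, the
#'   cohort's mean follow-up).
#' @param cost_main \code{c(mean, sd)} of the main gamma cost component (EUR).
#' @param cost_second \code{c(mean, sd)} of the second component, or NULL.
#' @param second_fraction Probability a patient incurs the second component.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(arm_name, n_patients, matrix, follow_up_years = 8,
                          cost_main = c(0, 0), cost_second = NULL,
                          second_fraction = 0) {
  stopifnot(inherits(matrix, "transition_matrix"))
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (second_fraction < 0 || second_fraction > 1) {
    stop("second_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(cost_main < 0) || (!is.null(cost_second) && any(cost_second < 0))) {
    stop("cost parameters must be nonnegative", call. = FALSE)
  }
  structure(list(arm_name = arm_name, n_patients = as.integer(n_patients),
                 matrix = matrix, follow_up_years = as.integer(follow_up_years),
                 cost_main = cost_main, cost_second = cost_second,
                 second_fraction = second_fraction),
            class = "cohort_config")
}

# Gamma draw parameterised by mean and sd; sd = 0 degenerates to the mean.
rgamma_moments <- function(n, mean, sd) {
  if (sd == 0 || mean == 0) return(rep(mean, n))
  stats::rgamma(n, shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Simulate patient-level state histories
#'
#' Every patient starts in the stable state; each subsequent annual state is
#' drawn from the true matrix row of the current state. A patient's history
#' stops at death or at the end of follow-up; no state ever follows death.
#' Per-patient total cost is a main gamma draw plus, with probability
#' \code{second_fraction}, a second-component gamma draw.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class \code{patient_histories}: list with
#'   \code{histories} (list of per-patient state-label vectors, year 0
#'   first), \code{costs} (per-patient total EUR) and \code{arm}.
#' @examples
#' inp <- trastuzumab_inputs()
#' cfg <- cohort_config("control", 30,
#'                      estimate_transition_matrix(inp$counts$control),
#'                      cost_main = inp$cost_components$control$main,
#'                      cost_second = inp$cost_components$control$second,
#'                      second_fraction = inp$cost_components$control$second_fraction)
#' coh <- simulate_cohort(cfg, seed = 1)
#' coh$histories[[1]]
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(config$matrix)
  states <- rownames(m)
  start <- states[1L]
  death <- absorbing_states(attr(config$matrix, "space"))[1L]
  n <- config$n_patients
  yrs <- config$follow_up_years

  # vectorised year-by-year simulation over all still-alive patients
  hist_mat <- matrix(NA_character_, n, yrs + 1L)
  hist_mat[, 1L] <- start
  cum <- t(apply(m, 1L, cumsum))
  for (y in seq_len(yrs)) {
    cur <- hist_mat[, y]
    alive <- which(!is.na(cur) & cur != death)
    if (!length(alive)) break
    u <- stats::runif(length(alive))
    idx <- match(cur[alive], states)
    nxt <- max.col(cum[idx, , drop = FALSE] >= u, ties.method = "first")
    hist_mat[alive, y + 1L] <- states[nxt]
  }
  histories <- lapply(seq_len(n), function(i) {
    h <- hist_mat[i, ]
    h[!is.na(h)]
  })
  costs <- rgamma_moments(n, config$cost_main[1L], config$cost_main[2L])
  if (!is.null(config$cost_second) && config$second_fraction > 0) {
    takes <- stats::runif(n) < config$second_fraction
    costs[takes] <- costs[takes] +
      rgamma_moments(sum(takes), config$cost_second[1L], config$cost_second[2L])
  }
  structure(list(histories = histories, costs = costs, arm = config$arm_name,
                 space = attr(config$matrix, "space")),
            class = "patient_histories")
}

#' @export
print.patient_histories <- function(x, ...) {
  len <- lengths(x$histories)
  cat(sprintf("Synthetic cohort '%s': %d patients, %d-%d recorded years\n",
              x$arm, length(x$histories), min(len), max(len)))
  cat(sprintf("Mean total cost: %.2f EUR\n", mean(x$costs)))
  invisible(x)
}

#' @export
as.data.frame.patient_histories <- function(x, ...) {
  n <- length(x$histories)
  len <- lengths(x$histories)
  data.frame(patient_id = rep(sprintf("P%04d", seq_len(n)), len),
             year = unlist(lapply(len, function(k) seq_len(k) - 1L)),
             state = unlist(x$histories),
             stringsAsFactors = FALSE)
}

#' Tabulate observed transitions from patient histories
#'
#' Counts consecutive (from-state, to-state) pairs across all patients,
#' yielding the transition count table that
#' \code{\link{estimate_transition_matrix}} consumes. Death is never a source
#' state; a history that continues after death is malformed.
#'
#' @param histories A \code{\link{simulate_cohort}} result, or a bare list of
#'   state-label vectors.
#' @param space A \code{\link{state_space}} (taken from \code{histories} when
#'   available).
#' @param arm Arm label for the resulting table.
#' @return A \code{\link{transition_counts}} object.
#' @export
tabulate_transitions <- function(histories, space = NULL, arm = NULL) {
  if (inherits(histories, "patient_histories")) {
    if (is.null(space)) space <- histories$space
    if (is.null(arm)) arm <- histories$arm
    histories <- histories$histories
  }
  if (is.null(space)) space <- state_space()
  if (is.null(arm)) arm <- ""
  if (!length(histories)) stop("no histories supplied", call. = FALSE)
  states <- unclass(space)
  death <- absorbing_states(space)
  cnt <- matrix(0L, length(states), length(states),
                dimnames = list(states, states))
  for (h in histories) {
    check_state_labels(h, space)
    if (length(h) < 2L) next
    from <- h[-length(h)]
    if (any(from %in% death)) {
      stop("malformed history: state recorded after death", call. = FALSE)
    }
    to <- h[-1L]
    for (k in seq_along(from)) {
      cnt[from[k], to[k]] <- cnt[from[k], to[k]] + 1L
    }
  }
  transition_counts(cnt, arm = arm, space = space)
}
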