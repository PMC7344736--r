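#' Utility weights per health state
#'
#' EQ-5D utility weights applied to state occupancy when accumulating QALYs.
#' Base-case values: stable 0.620, recurrence 0.767, metastasis 0.692, death 0.
#' Optional treatment-phase disutility deductions (-0.215 for stable and
#' recurrence, -0.0519 for metastasis) can be switched off (default), applied
#' to the first cycle only, or to every cycle.
#'
#' @param stable,recurrence,metastasis,death Per-state utilities in [-1, 1];
#'   death is 0 by QALY convention.
#' @param deduction_stable_recurrence,deduction_metastasis Disutility
#'   deductions (negative values) applied per \code{deduction_mode}.
#' @param deduction_mode \code{"off"}, \code{"first_cycle"} or
#'   \code{"all_cycles"}.
#' @return An object of class \code{utility_set}.
#' @examples
#' utility_set()
#' @export
utility_set <- function(stable = 0.620, recurrence = 0.767, metastasis = 0.692,
                        death = 0,
                        deduction_stable_recurrence = -0.215,
                        deduction_metastasis = -0.0519,
                        deduction_mode = c("off", "first_cycle", "all_cycles")) {
  deduction_mode <- match.arg(deduction_mode)
  u <- c(stable = stable, recurrence = recurrence,
         metastasis = metastasis, death = death)
  if (any(u < -1 | u > 1)) stop("utilities must lie in [-1, 1]", call. = FALSE)
  structure(list(utilities = u,
                 deductions = c(stable = deduction_stable_recurrence,
                                recurrence = deduction_stable_recurrence,
                                metastasis = deduction_metastasis,
                                death = 0),
                 deduction_mode = deduction_mode),
            class = "utility_set")
}

#' @export
print.utility_set <- function(x, ...) {
  cat("Utility set (deduction mode:", x$deduction_mode, ")\n")
  print(x$utilities)
  invisible(x)
}

# Effective utility vector at cycle t (0-based), honouring the deduction mode.
effective_utilities <- function(utilities, t) {
  u <- utilities$utilities
  mode <- utilities$deduction_mode
  if (mode == "all_cycles" || (mode == "first_cycle" && t == 0L)) {
    u <- u + utilities$deductions
  }
  u
}

#' Discounting specification
#'
#' Per-cycle discount rates for costs and QALYs; the base case discounts both
#' at 3% per annual cycle.
#'
#' @param cost,qaly Nonnegative per-cycle discount rates.
#' @return An object of class \code{discount_spec}.
#' @export
discount_spec <- function(cost = 0.03, qaly = 0.03) {
  if (cost < 0 || qaly < 0) stop("discount rates must be >= 0", call. = FALSE)
  structure(list(cost = cost, qaly = qaly), class = "discount_spec")
}

#' Time-horizon specification
#'
#' Either a fixed number of cycles (base case: 20 annual cycles) or a
#' "lifetime" horizon, operationalised as running until at least
#' \code{1 - epsilon} of the cohort is absorbed in death, capped at
#' \code{cap} cycles.
#'
#' @param mode \code{"fixed"} or \code{"lifetime"}.
#' @param n_cycles Number of cycles for the fixed mode.
#' @param epsilon Residual living mass tolerated at the end of a lifetime run.
#' @param cap Hard upper bound on lifetime cycles.
#' @return An object of class \code{horizon_spec}.
#' @export
horizon_spec <- function(mode = c("fixed", "lifetime"), n_cycles = 20,
                         epsilon = 0.001, cap = 100) {
  mode <- match.arg(mode)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)", call. = FALSE)
  structure(list(mode = mode, n_cycles = as.integer(n_cycles),
                 epsilon = epsilon, cap = as.integer(cap)),
            class = "horizon_spec")
}

#' Treatment strategy
#'
#' Bundles an arm's transition matrix with its cost model: a one-time upfront
#' cost applied at cycle 0 (undiscounted) plus optional per-state annual costs
#' accumulated along the trace. The base-case analysis uses upfront costs only.
#'
#' @param name Strategy name.
#' @param matrix A \code{\link{transition_matrix}}.
#' @param upfront_cost Nonnegative one-time cost (EUR) at cycle 0.
#' @param state_cost Named nonnegative per-state annual cost vector (EUR);
#'   default all zero.
#' @param cost_sd Standard deviation of the upfront cost, used by the
#'   probabilistic sensitivity analysis (gamma sampling); NA disables sampling.
#' @param n_patients Number of patients the arm's data came from (metadata).
#' @return An object of class \code{strategy}.
#' @export
strategy <- function(name, matrix, upfront_cost, state_cost = NULL,
                     cost_sd = NA_real_, n_patients = NA_integer_) {
  stopifnot(inherits(matrix, "transition_matrix"))
  space <- attr(matrix, "space")
  if (is.null(state_cost)) {
    state_cost <- stats::setNames(rep(0, length(space)), unclass(space))
  } else {
    check_state_labels(names(state_cost), space)
    full <- stats::setNames(rep(0, length(space)), unclass(space))
    full[names(state_cost)] <- state_cost
    state_cost <- full
  }
  if (upfront_cost < 0 || any(state_cost < 0)) {
    stop("costs must be nonnegative", call. = FALSE)
  }
  structure(list(name = name, matrix = matrix, upfront_cost = upfront_cost,
                 state_cost = state_cost, cost_sd = cost_sd,
                 n_patients = n_patients),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("Strategy '%s': upfront cost %.2f EUR%s\n", x$name,
              x$upfront_cost,
              if (!is.na(x$n_patients)) sprintf(" (n = %d)", x$n_patients) else ""))
  invisible(x)
}

#' Run a cohort trace
#'
#' Propagates a cohort occupancy vector through the transition matrix:
#' \code{occupancy[t + 1] = occupancy[t] \%*\% matrix}. Cycle 0 is the initial
#' distribution (base case: the full cohort in the stable state).
#'
#' @param matrix A \code{\link{transition_matrix}} (or row-stochastic matrix).
#' @param initial Initial occupancy vector summing to 1; default all mass in
#'   the first state.
#' @param n_cycles Number of cycles to run.
#' @return A \code{markov_trace}: an \code{(n_cycles + 1) x n_states} matrix,
#'   row \code{t + 1} holding the occupancy after cycle \code{t}.
#' @examples
#' m <- transition_matrix(rbind(
#'   stable     = c(0.744, 0.038, 0.115, 0.103),
#'   recurrence = c(1, 0, 0, 0),
#'   metastasis = c(1, 0, 0, 0),
#'   death      = c(0, 0, 0, 1)))
#' run_trace(m, n_cycles = 5)
#' @export
run_trace <- function(matrix, initial = NULL, n_cycles = 20) {
  m <- unclass(matrix)
  if (!is_stochastic(m)) stop("matrix is not row-stochastic", call. = FALSE)
  ns <- nrow(m)
  if (is.null(initial)) initial <- c(1, rep(0, ns - 1L))
  if (length(initial) != ns || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial occupancy must be nonnegative and sum to 1", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  occ <- matrix(0, n_cycles + 1L, ns,
                dimnames = list(0:n_cycles, colnames(m)))
  occ[1L, ] <- initial
  for (t in seq_len(n_cycles)) {
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% m
  }
  structure(occ, class = c("markov_trace", "matrix", "array"))
}

#' @export
print.markov_trace <- function(x, digits = 4, ...) {
  cat(sprintf("Cohort trace: %d cycles, %d states\n", nrow(x) - 1L, ncol(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Number of cycles until the cohort is (almost) fully absorbed
#'
#' Returns the smallest N <= cap at which the death-state occupancy reaches
#' \code{1 - epsilon}; if the cohort never absorbs within \code{cap} cycles
#' (e.g. a matrix with no path into death), returns \code{cap} with a warning.
#'
#' @inheritParams run_trace
#' @param epsilon Residual living mass tolerated (default 0.001).
#' @param cap Hard cap on the cycle count (default 100).
#' @param death Label of the absorbing death state.
#' @return Integer cycle count.
#' @export
lifetime_cycles <- function(matrix, initial = NULL, epsilon = 0.001, cap = 100,
                            death = "death") {
  m <- unclass(matrix)
  if (!is_stochastic(m)) stop("matrix is not row-stochastic", call. = FALSE)
  ns <- nrow(m)
  if (is.null(initial)) initial <- c(1, rep(0, ns - 1L))
  di <- match(death, colnames(m))
  if (is.na(di)) stop("no state labelled '", death, "'", call. = FALSE)
  occ <- initial
  if (occ[di] >= 1 - epsilon) return(0L)
  for (t in seq_len(cap)) {
    occ <- drop(occ %*% m)
    if (occ[di] >= 1 - epsilon) return(t)
  }
  warning(sprintf(
    "cohort not %.4g%% absorbed within %d cycles; returning the cap",
    100 * (1 - epsilon), cap), call. = FALSE)
  as.integer(cap)
}

# Trapezoidal half-cycle weights over cycles 0..N: 0.5 at both ends, 1 inside.
# With half_cycle = FALSE every cycle gets weight 1 except cycle N, excluded
# (plain forward sum over N cycles).
cycle_weights <- function(n_cycles, half_cycle = TRUE) {
  if (half_cycle) {
    w <- rep(1, n_cycles + 1L)
    w[1L] <- 0.5
    w[n_cycles + 1L] <- 0.5
  } else {
    w <- c(rep(1, n_cycles), 0)
  }
  w
}

#' Discounted QALY total of a cohort trace
#'
#' Accumulates \code{sum_t w_t * (u . occupancy[t]) * (1 + r)^(-t)} over
#' cycles 0..N, where \code{u} is the (deduction-adjusted) utility vector, r
#' the QALY discount rate and \code{w_t} trapezoidal half-cycle weights (0.5
#' at cycles 0 and N, 1 elsewhere). With \code{half_cycle = FALSE} the sum
#' runs over cycles 0..N-1 with unit weights.
#'
#' @param trace A \code{\link{run_trace}} result.
#' @param utilities A \code{\link{utility_set}} sharing the trace's states.
#' @param discount A \code{\link{discount_spec}}.
#' @param half_cycle Apply the half-cycle correction (default TRUE).
#' @return Total discounted QALYs (scalar).
#' @export
total_qalys <- function(trace, utilities = utility_set(),
                        discount = discount_spec(), half_cycle = TRUE) {
  states <- colnames(trace)
  if (!setequal(states, names(utilities$utilities))) {
    stop("trace and utility set use different state spaces", call. = FALSE)
  }
  n <- nrow(trace) - 1L
  w <- cycle_weights(n, half_cycle)
  r <- discount$qaly
  total <- 0
  for (t in 0:n) {
    if (w[t + 1L] == 0) next
    u <- effective_utilities(utilities, t)[states]
    total <- total + w[t + 1L] * sum(u * trace[t + 1L, ]) * (1 + r)^(-t)
  }
  total
}

#' Discounted cost total of a strategy over a trace
#'
#' The upfront cost enters at cycle 0 undiscounted; per-state annual costs (if
#' any) accumulate like QALYs, with half-cycle weights and cost discounting.
#' In the base case all state costs are zero, so the total equals the upfront
#' cost at every horizon.
#'
#' @param strategy A \code{\link{strategy}}.
#' @param trace A \code{\link{run_trace}} result for that strategy's matrix.
#' @param discount A \code{\link{discount_spec}}.
#' @param half_cycle Apply the half-cycle correction to state-cost streams.
#' @return Total discounted cost (EUR, scalar).
#' @export
total_cost <- function(strategy, trace, discount = discount_spec(),
                       half_cycle = TRUE) {
  sc <- strategy$state_cost[colnames(trace)]
  total <- strategy$upfront_cost
  if (any(sc > 0)) {
    n <- nrow(trace) - 1L
    w <- cycle_weights(n, half_cycle)
    r <- discount$cost
    stream <- drop(trace %*% sc) * (1 + r)^(-(0:n))
    total <- total + sum(w * stream)
  }
  total
}
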