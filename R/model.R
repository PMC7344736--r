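#' Fit a Markov cohort cost-effectiveness model
#'
#' Runs the discrete-time cohort model for each strategy and accumulates
#' discounted, half-cycle-corrected QALYs and costs. The first strategy is
#' the reference (comparator) for incremental analysis. Under a
#' \code{"lifetime"} horizon each strategy runs until its own cohort is
#' (almost) fully absorbed, capped as per the \code{\link{horizon_spec}}.
#'
#' @param strategies A list of \code{\link{strategy}} objects; the first is
#'   the reference arm.
#' @param utilities A \code{\link{utility_set}}.
#' @param discount A \code{\link{discount_spec}}.
#' @param horizon A \code{\link{horizon_spec}}.
#' @param initial Initial occupancy vector (default: whole cohort stable).
#' @param half_cycle Apply trapezoidal half-cycle correction (default TRUE).
#' @return An object of class \code{cea_model} with components
#'   \code{results} (data frame: strategy, cost, qalys, cycles),
#'   \code{traces} (named list of \code{markov_trace}s), and the inputs.
#' @seealso \code{\link{summary.cea_model}} for incremental/frontier analysis,
#'   \code{\link{simulate.cea_model}} for probabilistic sensitivity analysis,
#'   \code{\link{tornado}}, \code{\link{horizon_sweep}}.
#' @examples
#' inp <- trastuzumab_inputs()
#' mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
#' mod
#' @export
cea_model <- function(strategies, utilities = utility_set(),
                      discount = discount_spec(), horizon = horizon_spec(),
                      initial = NULL, half_cycle = TRUE) {
  if (!length(strategies) || !all(vapply(strategies, inherits, TRUE, "strategy"))) {
    stop("strategies must be a list of strategy objects", call. = FALSE)
  }
  nm <- vapply(strategies, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate strategy names", call. = FALSE)
  names(strategies) <- nm
  traces <- vector("list", length(strategies))
  names(traces) <- nm
  res <- data.frame(strategy = nm, cost = NA_real_, qalys = NA_real_,
                    cycles = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(strategies)) {
    s <- strategies[[i]]
    n <- if (horizon$mode == "fixed") horizon$n_cycles else
      lifetime_cycles(s$matrix, initial, horizon$epsilon, horizon$cap)
    tr <- run_trace(s$matrix, initial, n)
    traces[[i]] <- tr
    res$cycles[i] <- n
    res$qalys[i] <- total_qalys(tr, utilities, discount, half_cycle)
    res$cost[i] <- total_cost(s, tr, discount, half_cycle)
  }
  rownames(res) <- NULL
  structure(list(results = res, traces = traces, strategies = strategies,
                 utilities = utilities, discount = discount, horizon = horizon,
                 initial = initial, half_cycle = half_cycle),
            class = "cea_model")
}

# ce_result views of a model's rows
model_ce_results <- function(object) {
  lapply(seq_len(nrow(object$results)), function(i)
    ce_result(object$results$strategy[i], object$results$cost[i],
              object$results$qalys[i]))
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("Markov cohort cost-effectiveness model (%s horizon%s)\n",
              x$horizon$mode,
              if (x$horizon$mode == "fixed")
                sprintf(", %d cycles", x$horizon$n_cycles) else ""))
  df <- x$results
  df$cost <- round(df$cost, 2)
  df$qalys <- round(df$qalys, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Summarise a cost-effectiveness model
#'
#' Adds pairwise incremental analysis against the reference (first) strategy
#' and the multi-strategy efficiency frontier to the per-strategy totals.
#'
#' @param object A \code{\link{cea_model}}.
#' @param ... Unused.
#' @return An object of class \code{summary.cea_model}: list with
#'   \code{results}, \code{pairwise} (data frame of ICER entries vs the
#'   reference) and \code{frontier} (see \code{\link{incremental_frontier}}).
#' @export
summary.cea_model <- function(object, ...) {
  ce <- model_ce_results(object)
  pw <- NULL
  if (length(ce) > 1L) {
    entries <- lapply(ce[-1L], icer, reference = ce[[1L]])
    pw <- data.frame(
      intervention = vapply(entries, `[[`, "", "intervention"),
      comparator = vapply(entries, `[[`, "", "comparator"),
      delta_cost = vapply(entries, `[[`, 0, "delta_cost"),
      delta_qalys = vapply(entries, `[[`, 0, "delta_qalys"),
      icer = vapply(entries, `[[`, 0, "icer"),
      flag = vapply(entries, `[[`, "", "flag"),
      stringsAsFactors = FALSE)
  }
  fr <- if (length(ce) > 1L) incremental_frontier(ce) else NULL
  structure(list(results = object$results, pairwise = pw, frontier = fr,
                 horizon = object$horizon),
            class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  cat("Per-strategy discounted totals:\n")
  df <- x$results
  df$cost <- round(df$cost, 2); df$qalys <- round(df$qalys, 4)
  print(df, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nIncremental vs reference:\n")
    pw <- x$pairwise
    pw$delta_cost <- round(pw$delta_cost, 2)
    pw$delta_qalys <- round(pw$delta_qalys, 4)
    pw$icer <- round(pw$icer, 2)
    print(pw, row.names = FALSE)
  }
  if (!is.null(x$frontier)) {
    cat("\nEfficiency frontier:\n")
    fr <- x$frontier
    fr$cost <- round(fr$cost, 2); fr$qalys <- round(fr$qalys, 4)
    fr$icer <- round(fr$icer, 2)
    print(fr, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cea_model <- function(object, ...) {
  u <- object$utilities$utilities
  names(u) <- paste0("utility.", names(u))
  cst <- vapply(object$strategies, `[[`, 0, "upfront_cost")
  names(cst) <- paste0("cost.", names(cst))
  c(u, cst,
    discount.cost = object$discount$cost,
    discount.qaly = object$discount$qaly)
}

#' Re-evaluate a model at a different horizon
#'
#' @param object A \code{\link{cea_model}}.
#' @param horizon A \code{\link{horizon_spec}}, or an integer taken as a
#'   fixed cycle count, or the string \code{"lifetime"}.
#' @param ... Unused.
#' @return A new \code{cea_model}.
#' @export
predict.cea_model <- function(object, horizon = object$horizon, ...) {
  if (is.numeric(horizon)) horizon <- horizon_spec("fixed", horizon)
  if (is.character(horizon)) horizon <- horizon_spec("lifetime")
  cea_model(object$strategies, object$utilities, object$discount, horizon,
            object$initial, object$half_cycle)
}

#' Cost-effectiveness plane of a fitted model
#'
#' Plots each strategy's (QALYs, cost) point; frontier strategies are joined.
#'
#' @param x A \code{\link{cea_model}}.
#' @param ... Passed to \code{plot.default}.
#' @return Invisibly, the frontier data frame.
#' @export
plot.cea_model <- function(x, ...) {
  df <- x$results
  plot(df$qalys, df$cost, xlab = "QALYs", ylab = "Cost (EUR)",
       pch = 19, ...)
  graphics::text(df$qalys, df$cost, labels = df$strategy, pos = 3, cex = 0.8)
  fr <- NULL
  if (nrow(df) > 1L) {
    fr <- incremental_frontier(model_ce_results(x))
    on_fr <- fr[fr$status == "frontier", ]
    graphics::lines(on_fr$qalys, on_fr$cost, lty = 2)
  }
  invisible(fr)
}
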