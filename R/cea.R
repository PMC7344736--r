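#' Cost-effectiveness result of one strategy
#'
#' A plain container for a strategy's discounted totals.
#'
#' @param name Strategy name.
#' @param cost Total discounted cost (EUR), nonnegative.
#' @param qalys Total discounted QALYs.
#' @return An object of class \code{ce_result}.
#' @export
ce_result <- function(name, cost, qalys) {
  if (cost < 0) stop("total cost must be >= 0", call. = FALSE)
  structure(list(name = name, cost = cost, qalys = qalys), class = "ce_result")
}

#' Incremental cost-effectiveness ratio of two strategies
#'
#' Computes delta cost and delta QALYs of \code{alternative} minus
#' \code{reference} and classifies the comparison: \code{dominant} (cheaper
#' and no less effective, or no costlier and more effective),
#' \code{dominated} (the mirror image), \code{equivalent} (identical cost and
#' effect), otherwise \code{ratio} with ICER = delta cost / delta QALYs.
#' Boundary cases with zero QALY gain at a cost difference are classified as
#' dominance, never as infinite ratios. When both deltas are negative (the
#' alternative is cheaper \emph{and} less effective, the south-west quadrant)
#' a positive ratio is returned; it is then the cost saved per QALY forgone.
#'
#' @param reference,alternative \code{\link{ce_result}} objects (or lists with
#'   \code{name}, \code{cost}, \code{qalys}).
#' @return An object of class \code{icer_entry}: a list with
#'   \code{comparator}, \code{intervention}, \code{delta_cost},
#'   \code{delta_qalys}, \code{icer} (NA unless \code{flag == "ratio"}) and
#'   \code{flag}.
#' @examples
#' icer(ce_result("control", 3978.18, 1.42),
#'      ce_result("anthracyclines + trastuzumab", 41308.19, 3.46))
#' @export
icer <- function(reference, alternative) {
  dc <- alternative$cost - reference$cost
  de <- alternative$qalys - reference$qalys
  if (dc == 0 && de == 0) {
    flag <- "equivalent"; ratio <- NA_real_
  } else if ((dc <= 0 && de > 0) || (dc < 0 && de >= 0)) {
    flag <- "dominant"; ratio <- NA_real_
  } else if ((dc > 0 && de <= 0) || (dc >= 0 && de < 0)) {
    flag <- "dominated"; ratio <- NA_real_
  } else {
    flag <- "ratio"; ratio <- dc / de
  }
  structure(list(comparator = reference$name, intervention = alternative$name,
                 delta_cost = dc, delta_qalys = de, icer = ratio, flag = flag),
            class = "icer_entry")
}

#' @export
print.icer_entry <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost %.2f, dQALYs %.4f -> %s\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qalys,
              if (x$flag == "ratio") sprintf("ICER %.2f EUR/QALY", x$icer)
              else x$flag))
  invisible(x)
}

#' Net monetary benefit
#'
#' \code{lambda * qalys - cost} at willingness-to-pay threshold \code{lambda}
#' (EUR/QALY). For two strategies with positive QALY gain and positive extra
#' cost, the alternative has the higher NMB exactly when \code{lambda}
#' exceeds their pairwise ICER.
#'
#' @param result A \code{\link{ce_result}}.
#' @param lambda Nonnegative willingness-to-pay threshold (EUR/QALY).
#' @return Net monetary benefit (EUR).
#' @export
nmb <- function(result, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  lambda * result$qalys - result$cost
}

#' Incremental analysis over several strategies: the efficiency frontier
#'
#' Sorts strategies by cost (ties broken by higher QALYs), drops strictly
#' dominated strategies (costlier, no more effective), then iteratively drops
#' extended-dominated strategies -- those whose incremental ICER exceeds that
#' of the next frontier strategy -- until the sequential ICERs are
#' nondecreasing (strictly increasing unless strategies are collinear in the
#' cost-QALY plane, in which case the middle strategy is retained). Strategies
#' identical in cost and QALYs to a retained one are flagged
#' \code{equivalent}.
#'
#' @param results List of \code{\link{ce_result}} objects (>= 2, unique
#'   names).
#' @return A data frame with one row per strategy: \code{strategy},
#'   \code{cost}, \code{qalys}, \code{status} (\code{"frontier"},
#'   \code{"dominated"}, \code{"extended_dominated"}, \code{"equivalent"}),
#'   \code{comparator} and \code{icer} (sequential ICER along the frontier;
#'   NA for the cheapest strategy and for non-frontier rows).
#' @examples
#' res <- list(ce_result("control", 3978.18, 1.42),
#'             ce_result("anthra+tras", 41308.19, 3.46),
#'             ce_result("no-anthra+tras", 43664.83, 3.14),
#'             ce_result("anthra+tax+tras", 47304.25, 3.21))
#' incremental_frontier(res)
#' @export
incremental_frontier <- function(results) {
  if (length(results) < 2L) stop("need at least two strategies", call. = FALSE)
  nm <- vapply(results, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate strategy names", call. = FALSE)
  df <- data.frame(strategy = nm,
                   cost = vapply(results, `[[`, 0, "cost"),
                   qalys = vapply(results, `[[`, 0, "qalys"),
                   stringsAsFactors = FALSE)
  ord <- order(df$cost, -df$qalys)
  df <- df[ord, ]
  df$status <- "frontier"

  # exact duplicates of an earlier (retained) strategy
  for (i in seq_len(nrow(df))[-1L]) {
    j <- which(df$cost[seq_len(i - 1L)] == df$cost[i] &
                 df$qalys[seq_len(i - 1L)] == df$qalys[i] &
                 df$status[seq_len(i - 1L)] != "equivalent")
    if (length(j)) df$status[i] <- "equivalent"
  }
  # strict dominance: some cheaper-or-equal strategy has >= QALYs (and is not
  # identical); after cost-sorting it suffices to compare with the running max
  best_q <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$status[i] == "equivalent") next
    if (df$qalys[i] <= best_q) df$status[i] <- "dominated"
    else best_q <- df$qalys[i]
  }
  # extended dominance: drop frontier members whose incremental ICER exceeds
  # the next member's, repeat until sequential ICERs are nondecreasing
  repeat {
    idx <- which(df$status == "frontier")
    if (length(idx) < 3L) break
    ic <- diff(df$cost[idx]) / diff(df$qalys[idx])
    bad <- which(ic[-length(ic)] > ic[-1L] + 1e-12)
    if (!length(bad)) break
    df$status[idx[bad[1L] + 1L]] <- "extended_dominated"
  }
  idx <- which(df$status == "frontier")
  df$comparator <- NA_character_
  df$icer <- NA_real_
  if (length(idx) > 1L) {
    for (k in seq_along(idx)[-1L]) {
      i <- idx[k]; j <- idx[k - 1L]
      df$comparator[i] <- df$strategy[j]
      df$icer[i] <- (df$cost[i] - df$cost[j]) / (df$qalys[i] - df$qalys[j])
    }
  }
  rownames(df) <- NULL
  df
}
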