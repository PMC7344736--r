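#' One-way deterministic sensitivity analysis (tornado)
#'
#' Perturbs each addressable model parameter to \code{value * (1 - delta)}
#' and \code{value * (1 + delta)} (base case \code{delta = 0.1}), rebuilds the
#' model, and recomputes the pairwise ICER of \code{intervention} vs
#' \code{reference}. Transition-probability perturbations renormalise the row
#' afterwards; a perturbed probability outside [0, 1] is clamped with a
#' warning. The output is sorted by ICER range, widest bar first.
#'
#' Parameter paths: \code{"cost.<strategy>"} (upfront cost),
#' \code{"utility.<state>"}, \code{"discount.cost"}, \code{"discount.qaly"},
#' \code{"tp.<strategy>.<from>.<to>"}. By default every strategy cost, every
#' living-state utility and both discount rates are varied.
#'
#' @param model A \code{\link{cea_model}}.
#' @param parameters Character vector of parameter paths; NULL for the
#'   default set.
#' @param delta Relative perturbation in (0, 1); \code{delta = 0} returns the
#'   base ICER for every parameter.
#' @param reference,intervention Strategy names or indices (defaults: first
#'   and second strategy).
#' @return A data frame (class \code{cea_tornado}) with columns
#'   \code{parameter}, \code{base}, \code{low}, \code{high}, \code{range},
#'   sorted by decreasing \code{range}.
#' @examples
#' inp <- trastuzumab_inputs()
#' mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
#' head(tornado(mod))
#' @export
tornado <- function(model, parameters = NULL, delta = 0.1,
                    reference = 1L, intervention = 2L) {
  if (delta < 0 || delta >= 1) stop("delta must lie in [0, 1)", call. = FALSE)
  nm <- model$results$strategy
  ref <- if (is.numeric(reference)) nm[reference] else reference
  alt <- if (is.numeric(intervention)) nm[intervention] else intervention
  if (is.null(parameters)) {
    living <- setdiff(names(model$utilities$utilities), "death")
    parameters <- c(paste0("cost.", nm), paste0("utility.", living),
                    "discount.cost", "discount.qaly")
  }
  base <- pairwise_icer_value(model, ref, alt)
  out <- data.frame(parameter = parameters, base = base,
                    low = NA_real_, high = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(parameters)) {
    out$low[i] <- pairwise_icer_value(
      perturb_model(model, parameters[i], 1 - delta), ref, alt)
    out$high[i] <- pairwise_icer_value(
      perturb_model(model, parameters[i], 1 + delta), ref, alt)
  }
  out$range <- abs(out$high - out$low)
  out <- out[order(-out$range), ]
  rownames(out) <- NULL
  class(out) <- c("cea_tornado", "data.frame")
  out
}

pairwise_icer_value <- function(model, ref, alt) {
  res <- model$results
  e <- icer(ce_result(ref, res$cost[res$strategy == ref],
                      res$qalys[res$strategy == ref]),
            ce_result(alt, res$cost[res$strategy == alt],
                      res$qalys[res$strategy == alt]))
  if (e$flag == "ratio") e$icer else NA_real_
}

# Rebuild a model with one parameter scaled by `factor`.
perturb_model <- function(model, path, factor) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  strategies <- model$strategies
  utilities <- model$utilities
  discount <- model$discount
  kind <- parts[1L]
  if (kind == "cost") {
    s <- paste(parts[-1L], collapse = ".")
    if (!s %in% names(strategies)) stop("unknown strategy: ", s, call. = FALSE)
    strategies[[s]]$upfront_cost <- strategies[[s]]$upfront_cost * factor
  } else if (kind == "utility") {
    st <- parts[2L]
    if (!st %in% names(utilities$utilities)) {
      stop("unknown state: ", st, call. = FALSE)
    }
    utilities$utilities[st] <- utilities$utilities[st] * factor
  } else if (kind == "discount") {
    if (!parts[2L] %in% c("cost", "qaly")) {
      stop("unknown discount component: ", parts[2L], call. = FALSE)
    }
    discount[[parts[2L]]] <- discount[[parts[2L]]] * factor
  } else if (kind == "tp") {
    n <- length(parts)
    from <- parts[n - 1L]; to <- parts[n]
    s <- paste(parts[2:(n - 2L)], collapse = ".")
    if (!s %in% names(strategies)) stop("unknown strategy: ", s, call. = FALSE)
    m <- unclass(strategies[[s]]$matrix)
    if (!from %in% rownames(m) || !to %in% colnames(m)) {
      stop("unknown transition: ", from, " -> ", to, call. = FALSE)
    }
    v <- m[from, to] * factor
    if (v < 0 || v > 1) {
      warning(sprintf("perturbed P(%s -> %s) = %.4f clamped to [0, 1]",
                      from, to, v), call. = FALSE)
      v <- min(max(v, 0), 1)
    }
    m[from, to] <- v
    m[from, ] <- m[from, ] / sum(m[from, ])
    strategies[[s]]$matrix <- new_transition_matrix(
      m, source = attr(strategies[[s]]$matrix, "source"),
      space = attr(strategies[[s]]$matrix, "space"),
      arm = attr(strategies[[s]]$matrix, "arm"))
  } else {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  cea_model(strategies, utilities, discount, model$horizon, model$initial,
            model$half_cycle)
}

#' @export
print.cea_tornado <- function(x, ...) {
  cat("One-way sensitivity analysis (tornado order)\n")
  df <- as.data.frame(x)
  df[-1L] <- lapply(df[-1L], round, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws utilities from beta distributions (method of moments from mean and
#' standard error) and per-strategy upfront costs from gamma distributions
#' (shape = mean^2/sd^2, scale = sd^2/mean), then re-evaluates the cohort
#' model per iteration. Transition probabilities stay fixed. A zero SD makes
#' a distribution degenerate at its mean, so with all SDs zero every
#' iteration equals the base case.
#'
#' Utility standard errors default to \code{utility_se_fraction} times the
#' mean, shrunk where needed so the beta parameterisation stays feasible; an
#' explicitly supplied infeasible SE (\code{se^2 >= mean(1-mean)}) is an
#' error naming the state.
#'
#' @param object A \code{\link{cea_model}}. Strategies need a finite
#'   \code{cost_sd} to have their cost sampled; others keep it fixed.
#' @param nsim Number of Monte Carlo iterations (base case 1000).
#' @param seed Integer seed; recorded in the result.
#' @param utility_se Optional named vector of utility standard errors per
#'   living state; overrides the default fraction.
#' @param utility_se_fraction Default SE as a fraction of each utility mean.
#' @param ... Unused.
#' @return An object of class \code{cea_psa}: list with \code{draws} (data
#'   frame: iteration, strategy, cost, qalys), \code{seed}, \code{nsim} and
#'   the strategy names.
#' @examples
#' inp <- trastuzumab_inputs()
#' mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
#' psa <- simulate(mod, nsim = 50, seed = 1)
#' head(psa$draws)
#' @export
simulate.cea_model <- function(object, nsim = 1000, seed = NULL,
                               utility_se = NULL, utility_se_fraction = 0.10,
                               ...) {
  if (nsim < 1) stop("nsim must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u_mean <- object$utilities$utilities
  living <- setdiff(names(u_mean), "death")
  se <- stats::setNames(rep(NA_real_, length(living)), living)
  for (s in living) {
    m <- u_mean[[s]]
    if (!is.null(utility_se) && s %in% names(utility_se)) {
      se[s] <- utility_se[[s]]
      if (se[s] > 0 && (m <= 0 || m >= 1 || se[s]^2 >= m * (1 - m))) {
        stop(sprintf("beta parameterisation infeasible for utility '%s'", s),
             call. = FALSE)
      }
    } else {
      se[s] <- utility_se_fraction * m
      if (m > 0 && m < 1) se[s] <- min(se[s], 0.9 * sqrt(m * (1 - m)))
    }
  }
  strategies <- object$strategies
  nm <- names(strategies)
  nS <- length(nm)
  cost <- matrix(NA_real_, nsim, nS, dimnames = list(NULL, nm))
  qalys <- matrix(NA_real_, nsim, nS, dimnames = list(NULL, nm))
  for (i in seq_len(nsim)) {
    u <- u_mean
    for (s in living) u[s] <- rbeta_moments(1L, u_mean[[s]], se[s])
    u_set <- object$utilities
    u_set$utilities <- u
    for (k in seq_len(nS)) {
      st <- strategies[[k]]
      c_k <- st$upfront_cost
      if (!is.na(st$cost_sd) && st$cost_sd > 0 && c_k > 0) {
        c_k <- stats::rgamma(1L, shape = c_k^2 / st$cost_sd^2,
                             scale = st$cost_sd^2 / c_k)
      }
      cost[i, k] <- c_k + (total_cost(st, object$traces[[k]], object$discount,
                                      object$half_cycle) - st$upfront_cost)
      qalys[i, k] <- total_qalys(object$traces[[k]], u_set, object$discount,
                                 object$half_cycle)
    }
  }
  draws <- data.frame(iteration = rep(seq_len(nsim), times = nS),
                      strategy = rep(nm, each = nsim),
                      cost = as.vector(cost), qalys = as.vector(qalys),
                      stringsAsFactors = FALSE)
  structure(list(draws = draws, seed = seed, nsim = nsim, strategies = nm),
            class = "cea_psa")
}

# Beta draw parameterised by mean and standard error (method of moments);
# se = 0 degenerates to the mean.
rbeta_moments <- function(n, mean, se) {
  if (se == 0) return(rep(mean, n))
  if (mean <= 0 || mean >= 1 || se^2 >= mean * (1 - mean)) {
    stop("beta parameterisation infeasible (mean ", mean, ", se ", se, ")",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, %d strategies%s\n",
              x$nsim, length(x$strategies),
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  agg <- stats::aggregate(cbind(cost, qalys) ~ strategy, data = x$draws, mean)
  agg$cost <- round(agg$cost, 2); agg$qalys <- round(agg$qalys, 4)
  cat("Mean over iterations:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, counts the fraction of Monte Carlo
#' iterations in which each strategy has the maximal net monetary benefit;
#' exact ties split their iteration's weight equally. Fractions sum to 1 over
#' strategies at every threshold.
#'
#' @param psa A \code{\link{simulate.cea_model}} result.
#' @param thresholds Willingness-to-pay thresholds (EUR/QALY); base case
#'   20,000 / 40,000 / 60,000.
#' @return A data frame (class \code{cea_ceac}) with columns
#'   \code{threshold}, \code{strategy}, \code{fraction}.
#' @export
ceac <- function(psa, thresholds = c(20000, 40000, 60000)) {
  stopifnot(inherits(psa, "cea_psa"))
  nm <- psa$strategies
  cost <- matrix(psa$draws$cost, ncol = length(nm), dimnames = list(NULL, nm))
  qalys <- matrix(psa$draws$qalys, ncol = length(nm), dimnames = list(NULL, nm))
  out <- expand.grid(strategy = nm, threshold = thresholds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("threshold", "strategy")]
  out$fraction <- NA_real_
  for (lam in thresholds) {
    nb <- lam * qalys - cost
    top <- apply(nb, 1L, max)
    win <- nb >= top - 1e-9          # ties share the iteration equally
    share <- win / rowSums(win)
    out$fraction[out$threshold == lam] <- colMeans(share)[nm]
  }
  rownames(out) <- NULL
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' Plot acceptability curves
#'
#' @param x A \code{\link{ceac}} result (or a \code{cea_psa}, in which case
#'   curves are computed over a threshold grid first).
#' @param ... Passed to \code{matplot}.
#' @return Invisibly, the plotted data frame.
#' @export
plot.cea_ceac <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), idvar = "threshold",
                         timevar = "strategy", direction = "wide")
  m <- as.matrix(wide[-1L])
  graphics::matplot(wide$threshold, m, type = "b", pch = 19,
                    xlab = "Willingness to pay (EUR/QALY)",
                    ylab = "P(cost-effective)", ylim = c(0, 1), ...)
  graphics::legend("right", legend = sub("^fraction\\.", "", colnames(m)),
                   col = seq_len(ncol(m)), lty = seq_len(ncol(m)), cex = 0.8)
  invisible(x)
}

#' ICER as a function of the time horizon
#'
#' Re-evaluates the model at each horizon and reports the pairwise ICER of
#' every non-reference strategy against the reference. With upfront-only
#' costs the ICER is nonincreasing in the horizon, since extra cycles add
#' QALYs but no cost.
#'
#' @param model A \code{\link{cea_model}}.
#' @param horizons Vector of cycle counts; the string \code{"lifetime"} is
#'   also accepted.
#' @param reference Reference strategy name or index (default: first).
#' @return A data frame with columns \code{horizon}, \code{intervention},
#'   \code{icer}, \code{flag}.
#' @export
horizon_sweep <- function(model, horizons = c(5, 10, 15, 20), reference = 1L) {
  if (!length(horizons)) stop("horizons must be nonempty", call. = FALSE)
  nm <- model$results$strategy
  ref <- if (is.numeric(reference)) nm[reference] else reference
  alts <- setdiff(nm, ref)
  out <- NULL
  for (h in horizons) {
    mh <- predict(model, horizon = if (h == "lifetime") "lifetime"
                  else as.numeric(h))
    res <- mh$results
    for (a in alts) {
      e <- icer(ce_result(ref, res$cost[res$strategy == ref],
                          res$qalys[res$strategy == ref]),
                ce_result(a, res$cost[res$strategy == a],
                          res$qalys[res$strategy == a]))
      out <- rbind(out, data.frame(horizon = as.character(h), intervention = a,
                                   icer = e$icer, flag = e$flag,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
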