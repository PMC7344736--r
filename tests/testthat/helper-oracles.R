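# Independent oracles and generators used across the suite.

four_states <- c("stable", "recurrence", "metastasis", "death")

# Random row-stochastic matrix on the four-state space with absorbing death.
random_chain <- function(min_death = 0) {
  m <- matrix(0, 4, 4, dimnames = list(four_states, four_states))
  for (i in 1:3) {
    p <- stats::rgamma(4, 1)
    p <- p / sum(p)
    if (min_death > 0) {
      p <- p * (1 - min_death)
      p[4] <- p[4] + min_death
    }
    m[i, ] <- p
  }
  m[4, 4] <- 1
  m
}

# Occupancy after n cycles via explicit matrix powers (independent of the
# engine's step-by-step recursion).
power_trace_oracle <- function(m, initial, n) {
  p <- diag(nrow(m))
  out <- matrix(NA_real_, n + 1, nrow(m), dimnames = list(0:n, colnames(m)))
  for (t in 0:n) {
    out[t + 1, ] <- initial %*% p
    p <- p %*% m
  }
  out
}

# Closed-form discounted trapezoidal annuity: a cohort fixed in one state
# with utility u over cycles 0..n at rate r.
annuity_oracle <- function(u, r, n) {
  v <- (1 + r)^(-(0:n))
  w <- c(0.5, rep(1, n - 1), 0.5)
  u * sum(w * v)
}

# Step-until-absorbed oracle for lifetime cycle counts.
absorb_oracle <- function(m, initial, epsilon, cap) {
  occ <- initial
  if (occ[4] >= 1 - epsilon) return(0L)
  for (t in seq_len(cap)) {
    occ <- drop(occ %*% m)
    if (occ[4] >= 1 - epsilon) return(t)
  }
  cap
}

# Exhaustive frontier oracle on a (strategy, cost, qalys) data frame:
# a strategy is off the frontier if some other strategy weakly dominates it,
# or some convex combination of two others is strictly cheaper at equal
# effect. Returns the retained strategy names.
frontier_oracle <- function(df, tol = 1e-9) {
  n <- nrow(df)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qalys[j] >= df$qalys[i] &&
          (df$cost[j] < df$cost[i] || df$qalys[j] > df$qalys[i])) {
        keep[i] <- FALSE
      }
    }
    if (!keep[i]) next
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i %in% c(j, k) || j == k) next
        dq <- df$qalys[k] - df$qalys[j]
        if (abs(dq) < tol) next
        t <- (df$qalys[i] - df$qalys[j]) / dq
        if (t < -tol || t > 1 + tol) next
        combo_cost <- (1 - t) * df$cost[j] + t * df$cost[k]
        if (combo_cost < df$cost[i] - tol) keep[i] <- FALSE
      }
    }
  }
  df$strategy[keep]
}

# Two-strategy model on simple literal matrices, for sensitivity tests.
toy_model <- function(horizon = horizon_spec("fixed", 10)) {
  m1 <- transition_matrix(rbind(stable = c(0.8, 0.05, 0.05, 0.1),
                                recurrence = c(0.5, 0.3, 0.1, 0.1),
                                metastasis = c(0.2, 0.1, 0.4, 0.3),
                                death = c(0, 0, 0, 1)))
  m2 <- transition_matrix(rbind(stable = c(0.9, 0.03, 0.03, 0.04),
                                recurrence = c(0.6, 0.2, 0.1, 0.1),
                                metastasis = c(0.3, 0.1, 0.4, 0.2),
                                death = c(0, 0, 0, 1)))
  cea_model(list(strategy("standard", m1, 4000, cost_sd = 800),
                 strategy("intervention", m2, 40000, cost_sd = 6000)),
            horizon = horizon)
}
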