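control_printed <- function() {
  transition_matrix(rbind(stable = c(0.744, 0.038, 0.115, 0.103),
                          recurrence = c(1, 0, 0, 0),
                          metastasis = c(1, 0, 0, 0),
                          death = c(0, 0, 0, 1)))
}

test_that("one cycle from all-stable reproduces the stable row; identity is constant", {
  m <- control_printed()
  tr <- run_trace(m, n_cycles = 1)
  expect_equal(unname(tr[2, ]), c(0.744, 0.038, 0.115, 0.103))

  ident <- transition_matrix(diag(4), space = state_space())
  tr2 <- run_trace(ident, initial = c(0.3, 0.3, 0.2, 0.2), n_cycles = 10)
  for (t in 1:11) expect_equal(unname(tr2[t, ]), c(0.3, 0.3, 0.2, 0.2))
})

test_that("multi-cycle traces agree with the matrix-power oracle", {
  m <- control_printed()
  tr <- run_trace(m, n_cycles = 2)
  # stable share after 2 cycles: direct hand computation
  expect_equal(tr[3, "stable"], 0.744^2 + 0.038 + 0.115, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:10) {
    mm <- random_chain()
    init <- c(1, 0, 0, 0)
    tr <- run_trace(transition_matrix(mm), init, n_cycles = 15)
    expect_equal(unclass(tr), power_trace_oracle(mm, init, 15),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("traces conserve mass and death occupancy is monotone", {
  set.seed(11)
  for (rep in 1:200) {
    m <- random_chain()
    tr <- run_trace(transition_matrix(m), n_cycles = 25)
    expect_true(max(abs(rowSums(tr) - 1)) <= 1e-9)
    expect_true(all(diff(tr[, "death"]) >= -1e-12))
    expect_true(all(tr >= -1e-12))
  }
  # strict increase while living mass remains and stable feeds death
  m <- control_printed()
  tr <- run_trace(m, n_cycles = 30)
  expect_true(all(diff(tr[, "death"]) > 0))
})

test_that("invalid traces are refused", {
  expect_error(run_trace(matrix(c(0.5, 0.4, 0.5, 0.7), 2, 2)), "stochastic")
  m <- control_printed()
  expect_error(run_trace(m, initial = c(0.5, 0.5, 0.5, -0.5)), "sum to 1")
})

test_that("lifetime cycle counts match the step-until-absorbed oracle", {
  sudden <- transition_matrix(rbind(stable = c(0, 0, 0, 1),
                                    recurrence = c(1, 0, 0, 0),
                                    metastasis = c(1, 0, 0, 0),
                                    death = c(0, 0, 0, 1)))
  expect_equal(lifetime_cycles(sudden), 1L)

  m <- control_printed()
  expect_equal(lifetime_cycles(m, epsilon = 0.001, cap = 100),
               absorb_oracle(unclass(m), c(1, 0, 0, 0), 0.001, 100))
  set.seed(3)
  for (rep in 1:10) {
    mm <- random_chain(min_death = 0.05)
    expect_equal(lifetime_cycles(transition_matrix(mm), epsilon = 0.01, cap = 200),
                 absorb_oracle(mm, c(1, 0, 0, 0), 0.01, 200))
  }

  ident <- transition_matrix(diag(4), space = state_space())
  expect_warning(n <- lifetime_cycles(ident, cap = 50), "cap")
  expect_equal(n, 50L)
})

test_that("QALY accumulation matches closed forms", {
  ident <- transition_matrix(diag(4), space = state_space())
  tr20 <- run_trace(ident, n_cycles = 20)

  # undiscounted unit utility: trapezoidal weights sum to the cycle count
  u1 <- utility_set(stable = 1, recurrence = 1, metastasis = 1)
  expect_equal(total_qalys(tr20, u1, discount_spec(0, 0)), 20, tolerance = 1e-12)

  # discounted annuity at the stable-state utility
  expect_equal(total_qalys(tr20, utility_set(), discount_spec(0.03, 0.03)),
               annuity_oracle(0.620, 0.03, 20), tolerance = 1e-12)

  # a fully dead cohort accrues nothing
  dead <- run_trace(ident, initial = c(0, 0, 0, 1), n_cycles = 5)
  expect_equal(total_qalys(dead), 0)

  # without half-cycle correction: plain forward sum over cycles 0..N-1
  expect_equal(total_qalys(tr20, u1, discount_spec(0, 0), half_cycle = FALSE),
               20)
  v <- total_qalys(tr20, utility_set(), discount_spec(0, 0.03),
                   half_cycle = FALSE)
  expect_equal(v, 0.620 * sum(1.03^-(0:19)), tolerance = 1e-12)
})

test_that("QALYs are monotone in discount rate and horizon", {
  m <- control_printed()
  tr <- run_trace(m, n_cycles = 20)
  rates <- c(0, 0.01, 0.03, 0.05, 0.1)
  q <- vapply(rates, function(r) total_qalys(tr, discount = discount_spec(r, r)),
              0)
  expect_true(all(diff(q) < 0))

  q_h <- vapply(c(5, 10, 20, 40), function(n)
    total_qalys(run_trace(m, n_cycles = n)), 0)
  expect_true(all(diff(q_h) > 0))
})

test_that("disutility deductions enter per the configured mode", {
  ident <- transition_matrix(diag(4), space = state_space())
  tr <- run_trace(ident, n_cycles = 10)
  base <- total_qalys(tr, utility_set(), discount_spec(0, 0))
  first <- total_qalys(tr, utility_set(deduction_mode = "first_cycle"),
                       discount_spec(0, 0))
  allc <- total_qalys(tr, utility_set(deduction_mode = "all_cycles"),
                      discount_spec(0, 0))
  # stable cohort: -0.215 weighted 0.5 at cycle 0 only, or at every cycle
  expect_equal(first, base - 0.5 * 0.215, tolerance = 1e-12)
  expect_equal(allc, base - 10 * 0.215, tolerance = 1e-12)

  expect_error(total_qalys(tr, utility_set(stable = 2)), "\\[-1, 1\\]")
})

test_that("cost totals reduce to the upfront cost and honour state-cost streams", {
  inp <- trastuzumab_inputs()
  m <- estimate_transition_matrix(inp$counts$control)
  s <- strategy("control", m, upfront_cost = 3978.18)
  for (n in c(1, 20, 60)) {
    tr <- run_trace(m, n_cycles = n)
    expect_equal(total_cost(s, tr), 3978.18)
  }
  s0 <- strategy("free", m, upfront_cost = 0)
  expect_equal(total_cost(s0, run_trace(m, n_cycles = 20)), 0)

  # immortal stable cohort, annual stable cost 100, r = 0, N = 2:
  # 0.5*100 + 1*100 + 0.5*100 = 200
  ident <- transition_matrix(diag(4), space = state_space())
  s2 <- strategy("stream", ident, upfront_cost = 0,
                 state_cost = c(stable = 100))
  expect_equal(total_cost(s2, run_trace(ident, n_cycles = 2),
                          discount_spec(0, 0)), 200)
  expect_error(strategy("neg", ident, upfront_cost = -5), "nonnegative")
})

test_that("mismatched state spaces are rejected in QALY accumulation", {
  tr <- run_trace(transition_matrix(diag(4), space = state_space()),
                  n_cycles = 2)
  colnames(tr) <- c("a", "b", "c", "d")
  expect_error(total_qalys(tr), "state spaces")
})
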