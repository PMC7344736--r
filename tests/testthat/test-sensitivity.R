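test_that("tornado at delta = 0 returns the base ICER for every parameter", {
  mod <- toy_model()
  tn <- tornado(mod, delta = 0)
  expect_true(all(tn$low == tn$base))
  expect_true(all(tn$high == tn$base))
  expect_true(all(tn$range == 0))
})

test_that("tornado bars follow closed-form cost scaling", {
  mod <- toy_model()
  res <- mod$results
  de <- diff(res$qalys)
  cc <- res$cost[1]; ct <- res$cost[2]
  tn <- tornado(mod, parameters = "cost.intervention", delta = 0.1)
  expect_equal(tn$low, (0.9 * ct - cc) / de, tolerance = 1e-9)
  expect_equal(tn$high, (1.1 * ct - cc) / de, tolerance = 1e-9)

  # a parameter that does not enter the pairwise comparison leaves it unchanged
  mod3 <- cea_model(c(mod$strategies,
                      list(strategy("bystander", mod$strategies[[1]]$matrix,
                                    9999))),
                    horizon = mod$horizon)
  tn3 <- tornado(mod3, parameters = "cost.bystander", delta = 0.1,
                 reference = "standard", intervention = "intervention")
  expect_equal(tn3$low, tn3$base)
  expect_equal(tn3$high, tn3$base)
})

test_that("transition-probability perturbations renormalise and clamp", {
  mod <- toy_model()
  tn <- tornado(mod, parameters = "tp.intervention.stable.death", delta = 0.1)
  expect_true(is.finite(tn$low) && is.finite(tn$high))
  expect_true(tn$low != tn$high)
  # rows stay stochastic after perturbation
  pm <- markovcea:::perturb_model(mod, "tp.intervention.stable.death", 1.1)
  expect_true(max(abs(rowSums(pm$strategies$intervention$matrix) - 1)) <= 1e-9)
  # a perturbation pushing a probability above 1 is clamped with a warning
  m1 <- transition_matrix(rbind(stable = c(0.98, 0, 0, 0.02),
                                recurrence = c(1, 0, 0, 0),
                                metastasis = c(1, 0, 0, 0),
                                death = c(0, 0, 0, 1)))
  modc <- cea_model(list(strategy("a", m1, 100), strategy("b", m1, 200)))
  expect_warning(markovcea:::perturb_model(modc, "tp.a.stable.stable", 1.1),
                 "clamped")
})

test_that("with the case-study inputs the widest bars are trastuzumab cost and stable utility", {
  inp <- trastuzumab_inputs()
  mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
  tn <- tornado(mod, delta = 0.1)
  expect_setequal(tn$parameter[1:2], c("cost.trastuzumab", "utility.stable"))
})

test_that("PSA is seed-reproducible and degenerates to the base case at zero SD", {
  mod <- toy_model()
  p1 <- simulate(mod, nsim = 10, seed = 123)
  p2 <- simulate(mod, nsim = 10, seed = 123)
  expect_identical(p1$draws, p2$draws)
  p3 <- simulate(mod, nsim = 10, seed = 124)
  expect_false(identical(p3$draws, p1$draws))

  # zero-variance distributions: every iteration equals the base case
  strategies <- lapply(mod$strategies, function(s) { s$cost_sd <- 0; s })
  mod0 <- cea_model(strategies, horizon = mod$horizon)
  p0 <- simulate(mod0, nsim = 5, seed = 1,
                 utility_se = c(stable = 0, recurrence = 0, metastasis = 0))
  base <- mod0$results
  for (s in base$strategy) {
    d <- p0$draws[p0$draws$strategy == s, ]
    expect_equal(d$cost, rep(base$cost[base$strategy == s], 5))
    expect_equal(d$qalys, rep(base$qalys[base$strategy == s], 5))
  }
})

test_that("gamma cost draws reproduce the configured moments", {
  inp <- trastuzumab_inputs()
  mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
  psa <- simulate(mod, nsim = 1000, seed = 42)
  d <- psa$draws[psa$draws$strategy == "trastuzumab", ]
  mu <- inp$costs[["trastuzumab"]]
  sd_ <- inp$cost_sd[["trastuzumab"]]
  expect_lt(abs(mean(d$cost) - mu), 3 * sd_ / sqrt(1000))
  expect_lt(abs(sd(d$cost) - sd_), 0.15 * sd_)
  expect_true(all(d$cost > 0))
})

test_that("infeasible beta parameterisations are rejected by name", {
  mod <- toy_model()
  expect_error(simulate(mod, nsim = 2, seed = 1,
                        utility_se = c(stable = 0.7)),
               "stable")
})

test_that("acceptability fractions sum to one, respect threshold zero and ties", {
  mod <- toy_model()
  psa <- simulate(mod, nsim = 200, seed = 7)
  cc <- ceac(psa, thresholds = c(0, 20000, 40000, 60000))
  sums <- tapply(cc$fraction, cc$threshold, sum)
  expect_equal(as.numeric(sums), rep(1, 4), tolerance = 1e-9)
  # at threshold zero NMB is -cost: the cheaper strategy wins every draw
  at0 <- cc[cc$threshold == 0, ]
  expect_equal(at0$fraction[at0$strategy == "standard"], 1)

  # hand-constructed draws with known winners, including an exact tie
  fake <- structure(list(
    draws = data.frame(
      iteration = rep(1:10, 2),
      strategy = rep(c("a", "b"), each = 10),
      cost = c(rep(100, 10), rep(200, 10)),
      qalys = c(rep(1, 10), c(rep(2, 6), rep(1.5, 3), 1.1))),
    strategies = c("a", "b"), nsim = 10, seed = NULL),
    class = "cea_psa")
  cc2 <- ceac(fake, thresholds = 100)
  # NMB_a = 0; NMB_b = 100*q_b - 200: q=2 -> 0 (tie, 6 draws), q=1.5 -> -50,
  # q=1.1 -> -90; so b wins 6 half-shares = 0.3
  expect_equal(cc2$fraction[cc2$strategy == "b"], 0.3)
  expect_equal(cc2$fraction[cc2$strategy == "a"], 0.7)
})

test_that("acceptance of a costlier, more effective strategy rises with the threshold", {
  mod <- toy_model()
  psa <- simulate(mod, nsim = 300, seed = 11)
  d <- psa$draws
  # make the intervention costlier and more effective in every draw
  sel <- d$strategy == "intervention"
  d$cost[sel] <- d$cost[!sel] + abs(d$cost[sel] - d$cost[!sel]) + 1
  d$qalys[sel] <- d$qalys[!sel] + abs(d$qalys[sel] - d$qalys[!sel]) + 0.01
  psa$draws <- d
  grid <- seq(0, 2e5, by = 1e4)
  cc <- ceac(psa, thresholds = grid)
  frac <- cc$fraction[cc$strategy == "intervention"]
  expect_true(all(diff(frac) >= -1e-12))
  expect_equal(frac[1], 0)
})

test_that("ICER declines as the horizon lengthens under upfront-only costs", {
  inp <- trastuzumab_inputs()
  mod <- cea_model(trastuzumab_strategies(inp, arms = "pooled"))
  sw <- horizon_sweep(mod, horizons = c(5, 10, 15, 20))
  expect_true(all(sw$flag == "ratio"))
  expect_true(all(diff(sw$icer) < 0))

  # a single-cycle horizon equals the pairwise ICER of one-cycle totals
  sw1 <- horizon_sweep(mod, horizons = 1)
  m1 <- predict(mod, horizon = 1)
  e <- icer(ce_result("control", m1$results$cost[1], m1$results$qalys[1]),
            ce_result("trastuzumab", m1$results$cost[2], m1$results$qalys[2]))
  expect_equal(sw1$icer, e$icer)

  # identical matrices: no QALY gain, flagged not a ratio
  m <- mod$strategies$control$matrix
  dup <- cea_model(list(strategy("x", m, 100), strategy("y", m, 200)))
  swd <- horizon_sweep(dup, horizons = c(5, 10))
  expect_true(all(swd$flag == "dominated"))
})
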