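test_that("row-normalised estimates reproduce the published probabilities", {
  inp <- trastuzumab_inputs()
  ctrl <- estimate_transition_matrix(inp$counts$control)
  expect_equal(ctrl["stable", "death"], 8 / 78)
  expect_equal(round(ctrl["stable", "death"], 3), 0.103)
  expect_equal(round(ctrl["stable", "metastasis"], 3), 0.115)
  expect_equal(round(ctrl["stable", "stable"], 3), 0.744)

  tras <- estimate_transition_matrix(inp$counts$trastuzumab)
  expect_equal(tras["stable", "stable"], 400 / 423)
  expect_equal(round(tras["stable", "stable"], 3), 0.946)
  expect_equal(round(tras["recurrence", "stable"], 3), 0.714)

  anth <- estimate_transition_matrix(inp$counts$anthracycline_trastuzumab)
  expect_equal(round(anth["stable", "stable"], 3), 0.925)

  # single-destination row estimates to probability one
  cnt <- transition_counts(rbind(stable = c(5, 0, 0, 0),
                                 recurrence = c(1, 0, 0, 0),
                                 metastasis = c(1, 0, 0, 0),
                                 death = c(0, 0, 0, 0)))
  expect_equal(unname(estimate_transition_matrix(cnt)["stable", ]),
               c(1, 0, 0, 0))
})

test_that("estimation matches the per-cell division oracle and is scale-invariant", {
  set.seed(42)
  for (rep in 1:25) {
    cnt <- matrix(0L, 4, 4, dimnames = list(four_states, four_states))
    cnt[1:3, ] <- matrix(rpois(12, 20) + 1L, 3, 4)
    m <- estimate_transition_matrix(transition_counts(cnt))
    for (i in 1:3) for (j in 1:4) {
      expect_equal(m[i, j], cnt[i, j] / sum(cnt[i, ]))
    }
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    # scaling one row by a positive integer leaves its estimate unchanged
    cnt2 <- cnt
    cnt2[2, ] <- cnt2[2, ] * 7L
    m2 <- estimate_transition_matrix(transition_counts(cnt2))
    expect_equal(m2[2, ], m[2, ])
  }
})

test_that("degenerate and invalid count tables are handled", {
  zero_rec <- rbind(stable = c(5, 1, 1, 1), recurrence = c(0, 0, 0, 0),
                    metastasis = c(2, 0, 0, 0), death = c(0, 0, 0, 0))
  expect_warning(m <- estimate_transition_matrix(transition_counts(zero_rec)),
                 "self-loop")
  expect_equal(unname(m["recurrence", ]), c(0, 1, 0, 0))
  expect_equal(unname(m["death", ]), c(0, 0, 0, 1))

  expect_error(transition_counts(rbind(stable = c(-1, 0, 0, 0),
                                       recurrence = c(1, 0, 0, 0),
                                       metastasis = c(1, 0, 0, 0),
                                       death = c(0, 0, 0, 0))),
               "nonnegative")
  expect_error(transition_counts(rbind(stable = c(1, 0, 0, 0),
                                       recurrence = c(1, 0, 0, 0),
                                       metastasis = c(1, 0, 0, 0),
                                       death = c(1, 0, 0, 0))),
               "absorbing")
  all_zero <- matrix(0L, 4, 4, dimnames = list(four_states, four_states))
  expect_error(estimate_transition_matrix(transition_counts(all_zero)),
               "no observed transitions")
})

test_that("literal matrices accept printed rows and renormalise rounding slack", {
  # printed control rows sum to 1.000 exactly: accepted unchanged
  ctrl <- transition_matrix(rbind(stable = c(0.744, 0.038, 0.115, 0.103),
                                  recurrence = c(1, 0, 0, 0),
                                  metastasis = c(1, 0, 0, 0),
                                  death = c(0, 0, 0, 1)))
  expect_equal(ctrl["stable", "death"], 0.103)

  # published pooled-arm metastasis row (0.571, 0, 0.357, 0.072) sums to 1.000
  pooled <- transition_matrix(rbind(stable = c(0.946, 0.014, 0.038, 0.002),
                                    recurrence = c(0.714, 0.143, 0.143, 0),
                                    metastasis = c(0.571, 0, 0.357, 0.072),
                                    death = c(0, 0, 0, 1)))
  expect_equal(unname(rowSums(pooled)), rep(1, 4), tolerance = 1e-9)

  # a 3-decimal row off by < 0.01 is renormalised, with a message
  expect_message(
    m <- transition_matrix(rbind(stable = c(0.744, 0.038, 0.115, 0.107),
                                 recurrence = c(1, 0, 0, 0),
                                 metastasis = c(1, 0, 0, 0),
                                 death = c(0, 0, 0, 1))),
    "renormalising")
  expect_equal(sum(m["stable", ]), 1, tolerance = 1e-12)

  # a row summing to 1.5 is rejected
  expect_error(transition_matrix(rbind(stable = c(0.5, 0.5, 0.5, 0),
                                       recurrence = c(1, 0, 0, 0),
                                       metastasis = c(1, 0, 0, 0),
                                       death = c(0, 0, 0, 1))),
               "deviates")
  expect_error(transition_matrix(rbind(stable = c(1.2, 0, 0, -0.2),
                                       recurrence = c(1, 0, 0, 0),
                                       metastasis = c(1, 0, 0, 0),
                                       death = c(0, 0, 0, 1))),
               "\\[0, 1\\]")
})

test_that("count files round-trip in long and wide layouts", {
  inp <- trastuzumab_inputs()
  cnt <- inp$counts$control
  long <- file.path(tempdir(), "control_long.csv")
  df <- expand.grid(to_state = four_states, from_state = four_states[1:3],
                    stringsAsFactors = FALSE)[, 2:1]
  df$count <- unclass(cnt)[cbind(df$from_state, df$to_state)]
  write.csv(df, long, row.names = FALSE, quote = FALSE)
  rt <- read_counts(long, format = "long", arm = "control")
  expect_equal(unclass(rt), unclass(cnt))
  expect_equal(sum(rt["stable", ]), 78L)

  wide <- file.path(tempdir(), "control_wide.csv")
  write_matrix(cnt, wide)
  rt2 <- read_counts(wide, format = "wide", arm = "control")
  expect_equal(unclass(rt2), unclass(cnt))
})

test_that("malformed count files are rejected", {
  p <- file.path(tempdir(), "bad_counts.csv")
  writeLines("from_state,to_state,count", p)   # header only
  expect_error(read_counts(p), "empty")

  writeLines(c("from_state,to_state,count", "stable,stable,3.5"), p)
  expect_error(read_counts(p), "integer")

  writeLines(c("from_state,to_state,count", "stable,limbo,3"), p)
  expect_error(read_counts(p), "unknown")

  writeLines(c("from_state,to_state,count",
               "stable,stable,3", "stable,stable,4"), p)
  expect_error(read_counts(p), "duplicate")

  expect_error(read_counts(file.path(tempdir(), "no_such_file.csv")),
               "not found")
})
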