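t1 <- 3.41
t2 <- 6.10

test_that("root values on degenerate batteries match hand enumeration", {
  # battery admits exactly one collection
  tk <- forage_task(battery_long = t1, battery_short = t1)
  expect_equal(optimal_forager(t1, t2, "rich", "long", tk)$root_value, 8)
  expect_equal(optimal_forager(t1, t2, "mixed", "long", tk)$root_value,
               0.5 * 8 + 0.5 * 5)
  # two collections in a rich environment: 8 + 7
  tk2 <- forage_task(battery_long = 2 * t1, battery_short = t1)
  fit <- optimal_forager(t1, t2, "rich", "long", tk2)
  expect_equal(fit$root_value, 15)
  expect_identical(fit$root_action$kind, "move")
})

test_that("terminal and near-terminal states follow the value convention", {
  fit <- optimal_forager(t1, t2, "rich", "long")
  k <- knowledge_state("rich", boxes = c(4, 0, 0, 0))
  # last box of the area, exactly T1 left: collect 4 and stop
  expect_equal(state_value(fit, k, t1, location = 1), 4)
  # below T1: terminal, coins-to-go 0
  expect_equal(state_value(fit, k, t1 - 0.01, location = 1), 0)
  expect_error(optimal_action(fit, k, t1 - 0.01, location = 1), "terminal")
})

test_that("entering an unknown area is valued by the reveal expectation", {
  fit <- optimal_forager(t1, t2, "mixed", "long")
  k <- knowledge_state("mixed", c("rich", "poor", "unknown", "unknown"),
                       c(1, 1, 0, 0))
  # exactly one move possible: expected first box of an unknown area
  av <- action_values(fit, k, time_remaining = t2, location = 1)
  unknowns <- av[av$target %in% 3:4, ]
  expect_equal(unknowns$value, rep(0.5 * 8 + 0.5 * 5, 2))
})

test_that("feasible actions honor time, emptiness and location rules", {
  tm <- subject_timing(t1, t2)
  k <- knowledge_state("rich", boxes = c(5, 0, 0, 0))
  # not enough time for anything
  expect_identical(nrow(feasible_actions(k, 1, t1 - 0.1, tm)), 0L)
  # current area exhausted: moves only
  acts <- feasible_actions(k, 1, 30, tm)
  expect_true(all(acts$kind == "move"))
  expect_false(1 %in% acts$target)
  expect_true(all(acts$cost == t2))
  # from central every area costs T1 by default
  acts0 <- feasible_actions(knowledge_state("rich"), "central", 30, tm)
  expect_identical(acts0$target, 1:4)
  expect_true(all(acts0$cost == t1))
})

test_that("solver agrees with brute-force enumeration on short horizons", {
  set.seed(7)
  for (i in 1:60) {
    a <- runif(1, 1.5, 4.5)
    b <- runif(1, a + 0.5, a + 3)
    env <- sample(c("rich", "mixed"), 1)
    battery <- runif(1, a, 4 * a)  # at most four actions deep
    tk <- forage_task(battery_long = battery, battery_short = battery / 2)
    fit <- optimal_forager(a, b, env, "long", tk)
    expect_equal(fit$root_value, oracle_root_value(a, b, battery, env),
                 tolerance = 1e-12)
  }
})

test_that("value is monotone in time and in environment richness", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 2.5, 4.5)
    b <- runif(1, a + 1, a + 4)
    vals <- sapply(seq(25, 50, by = 5), function(dur) {
      tk <- forage_task(battery_long = dur, battery_short = 25)
      c(rich = optimal_forager(a, b, "rich", "long", tk)$root_value,
        mixed = optimal_forager(a, b, "mixed", "long", tk)$root_value)
    })
    expect_true(all(diff(vals["rich", ]) >= -1e-9))
    expect_true(all(diff(vals["mixed", ]) >= -1e-9))
    expect_true(all(vals["rich", ] >= vals["mixed", ] - 1e-9))
  }
})

test_that("root value never exceeds the richest consistent layout", {
  fit <- optimal_forager(t1, t2, "mixed", "long")
  expect_lte(fit$root_value, 90)
  fitr <- optimal_forager(t1, t2, "rich", "long")
  expect_lte(fitr$root_value, 120)
})

test_that("ties are broken toward the lowest-indexed area", {
  # all four areas symmetric and unknown at the root
  fit <- optimal_forager(t1, t2, "mixed", "long")
  expect_identical(fit$root_action$target, 1L)
  av <- action_values(fit)
  expect_equal(diff(range(av$value)), 0)
})

test_that("rich-environment root value equals realized coins on the path", {
  # coins-to-go at the root coincides with the cumulative coins actually
  # collected along the deterministic optimal trajectory
  for (battery in c("long", "short")) {
    fit <- optimal_forager(t1, t2, "rich", battery)
    log <- run_trial(fit, environment_config(rep("rich", 4)), battery,
                     coef(fit))
    expect_equal(fit$root_value, sum(log$events$coins))
  }
})
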