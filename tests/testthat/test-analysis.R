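make_log <- function(events, config = c("rich", "poor", "poor", "rich"),
                     env = "mixed", battery = "long", subject = 1L,
                     trial = 1L) {
  structure(list(subject = subject, trial = trial, env = env,
                 battery = battery,
                 duration = battery_duration(forage_task(), battery),
                 config = config, timing = c(T1 = 3.41, T2 = 6.10),
                 events = events),
            class = "trial_log")
}

test_that("trial summaries compute the six dependent variables", {
  ev <- data.frame(t = c(3.41, 6.82, 10.23), action = "stay",
                   area = c(1L, 1L, 1L), box = 1:3, coins = c(8L, 7L, 6L))
  ev$action <- c("move", "stay", "stay")
  s <- summarize_trial(make_log(ev))
  expect_equal(s$total_coins, 21)
  expect_equal(s$boxes_collected, 3)
  expect_equal(s$avg_coins_per_box, 7)
  expect_equal(s$n_unique_areas, 1)
  expect_equal(s$boxes_first_area, 3)
  expect_equal(s$avg_box_collection_time, 3.41)
  expect_identical(s$first_area_richness, "rich")

  one <- data.frame(t = 3.41, action = "move", area = 1L, box = 1L,
                    coins = 8L)
  expect_true(is.na(summarize_trial(make_log(one))$avg_box_collection_time))
})

test_that("optimal rich-environment summaries are integer-valued", {
  fit <- optimal_forager(3.41, 6.10, "rich", "long")
  st <- rollout_statistics(fit, n = 5, seed = 31)
  for (v in c("total_coins", "boxes_first_area", "boxes_collected",
              "n_unique_areas")) {
    expect_equal(st[[v]], round(st[[v]]))
    expect_equal(sd(st[[v]]), 0)
  }
})

test_that("timing estimation recovers generating parameters exactly without noise", {
  sim <- simulate_cohort(cohort_design(n_subjects = 3, trials_per_block = 4),
                         beta = 0, jitter_sd = 0, seed = 41)
  est <- estimate_timing(sim$logs)
  expect_equal(est$T1_hat, sim$subjects$T1, tolerance = 1e-9)
  expect_equal(est$T2_hat, sim$subjects$T2, tolerance = 1e-9)
})

test_that("timing estimation is consistent under duration jitter", {
  jit <- 0.3
  sim <- simulate_cohort(cohort_design(n_subjects = 4, trials_per_block = 20),
                         beta = 0, jitter_sd = jit, seed = 42)
  est <- estimate_timing(sim$logs)
  expect_true(all(est$n_T1 + est$n_T2 >= 200))
  ok_t1 <- abs(est$T1_hat - sim$subjects$T1) <= 2 * jit / sqrt(est$n_T1)
  ok_t2 <- abs(est$T2_hat - sim$subjects$T2) <= 2 * jit / sqrt(est$n_T2)
  # 2-s.e. bands each cover with ~95% probability; allow one miss in eight
  expect_gte(sum(ok_t1) + sum(ok_t2), 7)
})

test_that("switch probabilities mark forced leaves and resolved cells", {
  fit <- optimal_forager(3.41, 6.10, "mixed", "long")
  logs <- c(simulate(fit, nsim = 40, seed = 51),
            simulate(optimal_forager(3.41, 6.10, "rich", "long"),
                     nsim = 2, seed = 52))
  tab <- switch_probability_table(logs)
  # an exhausted area (box 5) forces leaving
  expect_true(all(tab$p_leave[tab$box == 5] == 1))
  # rich environments carry no unresolved uncertainty
  expect_true(all(tab$uncertainty_resolved[tab$env == "rich"]))
})

test_that("the optimal agent leaves poor areas earlier than rich ones", {
  fit <- optimal_forager(3.41, 6.10, "mixed", "short")
  logs <- simulate(fit, nsim = 60, seed = 53)
  tab <- switch_probability_table(logs)
  rate <- function(rich) {
    sub <- tab[tab$area_richness == rich, ]
    sum(sub$n_leave) / sum(sub$n)
  }
  expect_gt(rate("poor"), rate("rich"))
})

test_that("agent-vs-optimal contrasts behave at the identity and under noise", {
  fit <- optimal_forager(3.41, 6.10, "mixed", "short")
  opt <- rollout_statistics(fit, n = 40, seed = 61)
  same <- compare_to_optimal(opt, opt, "total_coins")
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, 0)

  noisy <- rollout_statistics(fit, n = 40,
                              policy = noisy_policy(fit, beta = 8),
                              seed = 62)
  res <- compare_to_optimal(noisy, opt, "total_coins")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$direction, -1)

  expect_error(compare_to_optimal(opt[0, ], opt, "total_coins"),
               "empty cell")
})

test_that("learning trends detect built-in speed-up and flat baselines", {
  des <- cohort_design(n_subjects = 5, trials_per_block = 8)
  fast <- simulate_cohort(des, beta = 0, jitter_sd = 0,
                          timing_speedup = 0.97, seed = 71)
  tr <- learning_trend(summarize_trials(fast$logs), "boxes_collected")
  expect_gt(tr$slope, 0)
  expect_lt(tr$p_value, 0.05)

  # a stationary noise-free generator in a fixed (all-rich) environment is
  # exactly flat: every per-trial mean is identical
  des0 <- cohort_design(n_subjects = 4, trials_per_block = 8,
                        prop_mixed = 0)
  flat <- simulate_cohort(des0, beta = 0, jitter_sd = 0, seed = 72)
  tr0 <- learning_trend(summarize_trials(flat$logs), "boxes_collected")
  expect_equal(tr0$slope, 0)
  expect_equal(tr0$r_squared, 0)
})
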