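# Enumerate every legal partially-revealed mixed knowledge state with all
# boxes at 0 or 1 (box counts do not affect beliefs).
all_mixed_knowledge <- function() {
  opts <- c("rich", "poor", "unknown")
  grid <- expand.grid(a = opts, b = opts, c = opts, d = opts,
                      stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(grid))) {
    r <- unlist(grid[i, ], use.names = FALSE)
    if (sum(r == "rich") > 2 || sum(r == "poor") > 2) next
    out[[length(out) + 1L]] <-
      knowledge_state("mixed", r, as.integer(r != "unknown"))
  }
  out
}

test_that("reveal posterior matches the two-rich/two-poor urn", {
  k0 <- knowledge_state("mixed")
  expect_equal(prob_rich_if_entered(k0, 1), 0.5)

  k1 <- knowledge_state("mixed", c("rich", "poor", "unknown", "unknown"),
                        c(1, 1, 0, 0))
  expect_equal(prob_rich_if_entered(k1, 3), 0.5)

  k2 <- knowledge_state("mixed", c("rich", "unknown", "unknown", "unknown"),
                        c(1, 0, 0, 0))
  expect_equal(prob_rich_if_entered(k2, 2), 1 / 3)

  expect_error(prob_rich_if_entered(k2, 1), "already revealed")
  expect_error(prob_rich_if_entered(knowledge_state("rich"), 1),
               "rich environment")
})

test_that("reveal posterior equals the consistent-configuration marginal", {
  for (k in all_mixed_knowledge()) {
    k <- apply_closure(k)
    cc <- consistent_configs(k)
    for (a in which(k$richness == "unknown")) {
      marg <- sum(cc$prob[cc[[paste0("area", a)]] == "rich"])
      expect_equal(prob_rich_if_entered(k, a), marg)
    }
  }
})

test_that("closure applies exactly the forced inferences and is idempotent", {
  k <- apply_closure(knowledge_state(
    "mixed", c("rich", "rich", "unknown", "unknown"), c(1, 1, 0, 0)))
  expect_identical(k$richness, c("rich", "rich", "poor", "poor"))

  k2 <- knowledge_state("mixed", c("rich", "poor", "unknown", "unknown"),
                        c(1, 1, 0, 0))
  expect_identical(apply_closure(k2)$richness, k2$richness)

  k3 <- apply_closure(knowledge_state("rich"))
  expect_identical(k3$richness, rep("rich", 4))

  for (k in all_mixed_knowledge()) {
    once <- apply_closure(k)
    expect_identical(apply_closure(once), once)
    revealed <- k$richness != "unknown"
    expect_identical(once$richness[revealed], k$richness[revealed])
  }
})

test_that("uncertainty is resolved exactly when the layout is inferable", {
  expect_true(uncertainty_resolved(knowledge_state(
    "mixed", c("rich", "rich", "unknown", "unknown"), c(1, 1, 0, 0))))
  expect_false(uncertainty_resolved(knowledge_state(
    "mixed", c("rich", "poor", "unknown", "unknown"), c(1, 1, 0, 0))))
  expect_true(uncertainty_resolved(knowledge_state("rich")))
  expect_false(uncertainty_resolved(knowledge_state("mixed")))
})

test_that("consistent configurations enumerate the posterior support", {
  cc0 <- consistent_configs(knowledge_state("mixed"))
  expect_identical(nrow(cc0), 6L)
  expect_equal(sum(cc0$prob), 1)
  expect_true(all(cc0$prob == 1 / 6))

  cc1 <- consistent_configs(knowledge_state(
    "mixed", c("rich", "unknown", "unknown", "unknown"), c(1, 0, 0, 0)))
  expect_identical(nrow(cc1), 3L)
  expect_true(all(cc1$area1 == "rich"))

  ccr <- consistent_configs(knowledge_state("rich"))
  expect_identical(nrow(ccr), 1L)
  expect_equal(ccr$prob, 1)
})

test_that("sequential reveals reproduce the uniform layout distribution", {
  # Composing reveal probabilities along any order of area visits must give
  # each of the 6 layouts mass 1/6.
  layout_prob <- function(config, order) {
    k <- knowledge_state("mixed")
    p <- 1
    for (a in order) {
      if (k$richness[a] == "unknown") {
        pr <- prob_rich_if_entered(k, a)
        p <- p * (if (config[a] == "rich") pr else 1 - pr)
      }
      k$richness[a] <- config[a]
      k$boxes[a] <- 1L
      k <- apply_closure(k)
    }
    p
  }
  cc <- consistent_configs(knowledge_state("mixed"))
  orders <- list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))
  for (i in seq_len(nrow(cc))) {
    cfg <- unlist(cc[i, 1:4])
    for (ord in orders)
      expect_equal(layout_prob(cfg, ord), 1 / 6)
  }
})

test_that("compact tuple notation shows next-box values and unknowns", {
  k <- knowledge_state("mixed", c("rich", "poor", "unknown", "unknown"),
                       c(1, 1, 0, 0))
  expect_identical(format(k), "(7, 4, ?, ?)")
  k2 <- knowledge_state("rich", boxes = c(5, 0, 1, 0))
  expect_identical(format(k2), "(-, 8, 7, 8)")
})
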