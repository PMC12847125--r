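# Independent brute-force oracle for state values.
#
# Enumerates the full tree of action sequences without memoization, and
# handles hidden-layout uncertainty by filtering the literal C(4,2)
# configuration set: the probability that an unexplored area is rich is the
# fraction of consistent configurations in which it is rich.  No forced-
# inference (closure) logic and no closed-form posterior is used, so this
# shares no mechanics with the package's solver.

oracle_all_mixed_configs <- function() {
  pairs <- combn(4, 2)
  lapply(seq_len(ncol(pairs)), function(j) {
    r <- rep("poor", 4)
    r[pairs[, j]] <- "rich"
    r
  })
}

# revealed: character vector of length 4, "rich"/"poor"/NA (NA = never
# collected there).  Configs consistent with direct observations only.
oracle_consistent <- function(env, revealed) {
  if (env == "rich") return(list(rep("rich", 4)))
  Filter(function(cfg) all(is.na(revealed) | revealed == cfg),
         oracle_all_mixed_configs())
}

oracle_value <- function(time_remaining, revealed, boxes, loc, t1, t2, env,
                         rich_seq = 8:4, poor_seq = 5:1,
                         first_move_t1 = TRUE) {
  eps <- 1e-9
  nbox <- length(rich_seq)
  configs <- oracle_consistent(env, revealed)
  best <- 0
  consider <- function(a, cost) {
    if (boxes[a] >= nbox || time_remaining < cost - eps) return(NULL)
    sub <- Filter(function(cfg) cfg[a] == "rich", configs)
    p_rich <- length(sub) / length(configs)
    branch <- function(rch) {
      rev2 <- revealed; rev2[a] <- rch
      bx2 <- boxes; bx2[a] <- bx2[a] + 1
      coin <- if (rch == "rich") rich_seq[boxes[a] + 1] else poor_seq[boxes[a] + 1]
      coin + oracle_value(time_remaining - cost, rev2, bx2, a, t1, t2, env,
                          rich_seq, poor_seq, first_move_t1)
    }
    v <- 0
    if (p_rich > 0) v <- v + p_rich * branch("rich")
    if (p_rich < 1) v <- v + (1 - p_rich) * branch("poor")
    v
  }
  if (!identical(loc, "central")) {
    v <- consider(loc, t1)
    if (!is.null(v) && v > best) best <- v
  }
  move_cost <- if (identical(loc, "central")) {
    if (first_move_t1) t1 else t2
  } else t2
  for (a in 1:4) {
    if (!identical(loc, "central") && a == loc) next
    v <- consider(a, move_cost)
    if (!is.null(v) && v > best) best <- v
  }
  best
}

oracle_root_value <- function(t1, t2, battery, env, ...) {
  oracle_value(battery, rep(NA_character_, 4), rep(0L, 4), "central",
               t1, t2, env, ...)
}
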