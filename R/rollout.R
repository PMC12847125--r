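#' Simulate one trial of a policy through the task
#'
#' Starts at the root state (full battery, trial-start knowledge, central
#' zone), repeatedly queries the policy, applies time costs and coin
#' collection against the hidden configuration, updates knowledge (with
#' forced inferences), and stops when no action is feasible.  With
#' `jitter_sd > 0` each action's realized duration is drawn from a normal
#' around its nominal cost, truncated below at 0.5 s and above at the
#' remaining battery, emulating execution variability; the policy still
#' plans with the nominal costs.
#'
#' @param policy an [optimal_forager()], or a function taking a state (a
#'   list with `time_remaining`, `knowledge`, `location`) and returning an
#'   action list with `kind` (`"stay"`/`"move"`) and `target` (area index),
#'   e.g. from [noisy_policy()].
#' @param config the hidden [environment_config()] of the trial.
#' @param battery `"long"` or `"short"`.
#' @param timing a [subject_timing()].
#' @param task a [forage_task()].
#' @param first_move cost rule for the first entry from the central zone.
#' @param jitter_sd standard deviation (s) of per-action duration noise.
#' @param subject,trial identifiers stored in the log.
#' @return A `trial_log`: the trial's condition, hidden configuration and an
#'   ordered event table with columns `t` (seconds from trial start at
#'   collection), `action`, `area`, `box` (ordinal within the area) and
#'   `coins`.
#' @examples
#' fit <- optimal_forager(3.41, 6.10, env = "rich", battery = "short")
#' log <- run_trial(fit, environment_config(rep("rich", 4)),
#'                  battery = "short", timing = coef(fit))
#' log$events
#' @export
run_trial <- function(policy, config, battery = c("long", "short"),
                      timing = subject_timing(), task = forage_task(),
                      first_move = c("T1", "T2"), jitter_sd = 0,
                      subject = NA_integer_, trial = NA_integer_) {
  battery <- match.arg(battery)
  first_move <- match.arg(first_move)
  config <- environment_config(config)
  env <- env_label(config)
  duration <- battery_duration(task, battery)

  if (inherits(policy, "optimal_forager")) {
    object <- policy
    stopifnot(object$env == env, object$battery == battery)
    policy_fun <- function(state)
      optimal_action(object, state$knowledge, state$time_remaining,
                     state$location)
  } else {
    stopifnot(is.function(policy))
    policy_fun <- policy
  }

  k <- knowledge_state(env)
  loc <- "central"
  elapsed <- 0
  t <- numeric(0); act <- character(0); area <- integer(0)
  box <- integer(0); coins <- integer(0)

  repeat {
    remaining <- duration - elapsed
    feas <- feasible_actions(k, loc, remaining, timing, task, first_move)
    if (nrow(feas) == 0L) break
    a <- policy_fun(list(time_remaining = remaining, knowledge = k,
                         location = loc))
    row <- which(feas$kind == a$kind & feas$target == a$target)
    if (length(row) != 1L)
      stop(sprintf(
        "policy returned infeasible action (%s -> area %s) at t=%.3f, %s, loc %s",
        a$kind, a$target, remaining, format(k), loc), call. = FALSE)
    cost <- feas$cost[row]
    dur <- if (jitter_sd > 0) {
      rtruncnorm1(cost, jitter_sd, lo = 0.5, hi = max(remaining, 0.5 + 1e-6))
    } else cost
    elapsed <- elapsed + dur
    tgt <- feas$target[row]
    c_now <- next_box_coins(config[tgt], k$boxes[tgt], task)
    k$richness[tgt] <- config[tgt]
    k$boxes[tgt] <- k$boxes[tgt] + 1L
    k <- apply_closure(k)
    t <- c(t, elapsed); act <- c(act, a$kind); area <- c(area, tgt)
    box <- c(box, k$boxes[tgt]); coins <- c(coins, c_now)
    loc <- tgt
  }

  structure(
    list(subject = subject, trial = trial, env = env, battery = battery,
         duration = duration, config = as.character(config),
         timing = c(T1 = unname(timing[["T1"]]), T2 = unname(timing[["T2"]])),
         events = data.frame(t = t, action = act, area = area, box = box,
                             coins = coins)),
    class = "trial_log")
}

# One draw from a normal truncated to [lo, hi] by inverse-CDF sampling.
rtruncnorm1 <- function(mean, sd, lo = -Inf, hi = Inf) {
  u <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("Trial log: %s environment, %s battery (%g s)\n",
              x$env, x$battery, x$duration))
  cat("  hidden config:", paste(x$config, collapse = ", "), "\n")
  cat(sprintf("  %d collections, %d coins\n",
              nrow(x$events), sum(x$events$coins)))
  invisible(x)
}

#' Validate the internal consistency of a trial log
#'
#' Checks the log invariants: strictly increasing timestamps bounded by the
#' battery duration, per-area box ordinals increasing 1..5, and coins
#' matching the schedule of the area's true richness.
#'
#' @param log a `trial_log`.
#' @param task a [forage_task()].
#' @return Invisibly `TRUE`; errors with the violated invariant otherwise.
#' @export
validate_trial_log <- function(log, task = forage_task()) {
  stopifnot(inherits(log, "trial_log"))
  ev <- log$events
  if (nrow(ev) == 0L) return(invisible(TRUE))
  if (any(diff(ev$t) <= 0)) stop("timestamps not strictly increasing")
  if (max(ev$t) > log$duration + 1e-6)
    stop("events exceed the battery duration")
  for (a in unique(ev$area)) {
    ord <- ev$box[ev$area == a]
    if (!identical(ord, seq_along(ord)))
      stop(sprintf("box ordinals in area %d are not 1..%d", a, length(ord)))
    sched <- if (log$config[a] == "rich") task$rich_coins else task$poor_coins
    if (!identical(as.integer(ev$coins[ev$area == a]), sched[ord]))
      stop(sprintf("coins in area %d do not match the %s schedule",
                   a, log$config[a]))
  }
  invisible(TRUE)
}

#' Monte-Carlo rollout statistics of a policy
#'
#' Samples hidden configurations for the condition, simulates one trial per
#' draw, and returns the per-trial dependent variables.  For the optimal
#' policy in a rich environment every statistic is a point mass (there is no
#' stochasticity); in a mixed environment the only randomness under the
#' optimal policy is the sampled configuration, so Monte-Carlo means
#' converge to the exact expectation over the six layouts returned by
#' [exact_statistics()].
#'
#' @param object an [optimal_forager()], used both as the condition
#'   definition and (by default) as the policy.
#' @param n number of trajectories (the reference analysis uses 1e5;
#'   smaller values are adequate for testing).
#' @param policy optional policy function overriding the optimal one, e.g.
#'   [noisy_policy()].
#' @param jitter_sd per-action duration noise passed to [run_trial()].
#' @param seed optional integer seed.
#' @return A data frame of per-trial summaries (see [summarize_trials()]),
#'   one row per trajectory.
#' @export
rollout_statistics <- function(object, n = 1e5, policy = NULL,
                               jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(object, "optimal_forager"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  pol <- if (is.null(policy)) object else policy
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- sample_environment(object$env)
    logs[[i]] <- run_trial(pol, cfg, object$battery, object$timing,
                           object$task, object$first_move, jitter_sd,
                           trial = i)
  }
  summarize_trials(logs)
}

#' Exact expected statistics of the optimal policy
#'
#' For a mixed environment, runs the (deterministic given the layout)
#' optimal trajectory once per consistent configuration and weights the
#' per-trial statistics by the uniform layout probabilities; for a rich
#' environment there is a single layout.  Also reports conditional means
#' split by the true richness of the first-visited area.
#'
#' @param object an [optimal_forager()].
#' @return A list with `trials` (one summary row per layout, with `prob`),
#'   `means` (probability-weighted means of the numeric dependent
#'   variables) and `by_first_area` (conditional means given first-area
#'   richness).
#' @export
exact_statistics <- function(object) {
  stopifnot(inherits(object, "optimal_forager"))
  cc <- consistent_configs(knowledge_state(object$env))
  logs <- lapply(seq_len(nrow(cc)), function(i)
    run_trial(object, environment_config(unlist(cc[i, 1:4])),
              object$battery, object$timing, object$task,
              object$first_move, trial = i))
  trials <- summarize_trials(logs)
  trials$prob <- cc$prob
  vars <- c("total_coins", "boxes_first_area", "boxes_collected",
            "avg_coins_per_box", "n_unique_areas")
  wmean <- function(df) vapply(vars, function(v)
    sum(df[[v]] * df$prob) / sum(df$prob), numeric(1))
  by_first <- lapply(split(trials, trials$first_area_richness), wmean)
  list(trials = trials, means = wmean(trials),
       by_first_area = by_first)
}

#' Write and read trial logs as JSON-lines
#'
#' One trial per line, losslessly round-tripping the log structure.
#' [trial_events_table()] flattens a collection of logs into a single event
#' table (one row per collection) suitable for CSV export.
#'
#' @param logs a list of `trial_log` objects.
#' @param path file path.
#' @export
write_trial_logs <- function(logs, path) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  lines <- vapply(logs, function(log) {
    x <- unclass(log)
    x$timing <- as.list(x$timing)  # keep names in JSON
    as.character(jsonlite::toJSON(x, dataframe = "columns",
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trial_logs
#' @return `read_trial_logs()`: a list of `trial_log` objects.
#' @export
read_trial_logs <- function(path) {
  lapply(readLines(path), function(line) {
    x <- jsonlite::fromJSON(line)
    ev <- x$events
    log <- list(subject = as.integer(x$subject), trial = as.integer(x$trial),
                env = x$env, battery = x$battery,
                duration = as.numeric(x$duration),
                config = as.character(x$config),
                timing = c(T1 = as.numeric(x$timing[["T1"]]),
                           T2 = as.numeric(x$timing[["T2"]])),
                events = data.frame(t = as.numeric(ev$t),
                                    action = as.character(ev$action),
                                    area = as.integer(ev$area),
                                    box = as.integer(ev$box),
                                    coins = as.integer(ev$coins)))
    class(log) <- "trial_log"
    log
  })
}

#' @rdname write_trial_logs
#' @return `trial_events_table()`: a data frame with one row per collection
#'   event, carrying subject, trial and condition columns.
#' @export
trial_events_table <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  do.call(rbind, lapply(logs, function(log) {
    ev <- log$events
    if (nrow(ev) == 0L) return(NULL)
    data.frame(subject = log$subject, trial = log$trial, env = log$env,
               battery = log$battery, ev)
  }))
}
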