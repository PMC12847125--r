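#' Study design for a synthetic cohort
#'
#' The design mirrors the reference study: 34 subjects, two battery blocks
#' of 20 trials each (40 trials per subject), block order counterbalanced
#' across two equal groups (long-first vs short-first), and each trial
#' independently assigned a rich or mixed environment (fair coin by
#' default; the true per-block proportions are not part of the task
#' definition).
#'
#' @param n_subjects number of subjects.
#' @param trials_per_block trials in each battery block.
#' @param prop_mixed probability that a trial is a mixed environment.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 34, trials_per_block = 20,
                          prop_mixed = 0.5) {
  stopifnot(n_subjects >= 1, trials_per_block >= 1,
            prop_mixed >= 0, prop_mixed <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_block = as.integer(trials_per_block),
                 prop_mixed = prop_mixed),
            class = "cohort_design")
}

#' Draw a synthetic cohort: subjects, timing parameters and trial schedule
#'
#' Subject timing parameters are drawn from the population distribution of
#' the study (T1 ~ 3.41 +- 0.53 s, T2 ~ 6.10 +- 0.72 s, truncated so that
#' T2 > T1 > 0.5 s).  Group assignment (block order) is balanced; the trial
#' schedule fixes, per trial, the block, battery label, environment label
#' and the hidden configuration.
#'
#' @param design a [cohort_design()].
#' @param t1_mean,t1_sd,t2_mean,t2_sd population moments of the timing
#'   parameters, seconds.
#' @param seed optional integer seed.
#' @return A list with `subjects` (subject, group, T1, T2) and `schedule`
#'   (subject, trial, block, battery, env, area1..area4).
#' @export
sample_cohort <- function(design = cohort_design(),
                          t1_mean = 3.41, t1_sd = 0.53,
                          t2_mean = 6.10, t2_sd = 0.72, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  ns <- design$n_subjects
  groups <- rep(c("long_first", "short_first"), length.out = ns)
  T1 <- vapply(seq_len(ns), function(i)
    rtruncnorm1(t1_mean, t1_sd, lo = 0.5), numeric(1))
  T2 <- vapply(seq_len(ns), function(i)
    rtruncnorm1(t2_mean, t2_sd, lo = T1[i] + 1e-6), numeric(1))
  subjects <- data.frame(subject = seq_len(ns), group = groups,
                         T1 = T1, T2 = T2)

  tpb <- design$trials_per_block
  schedule <- do.call(rbind, lapply(seq_len(ns), function(s) {
    order_long_first <- groups[s] == "long_first"
    battery <- c(rep(if (order_long_first) "long" else "short", tpb),
                 rep(if (order_long_first) "short" else "long", tpb))
    env <- ifelse(runif(2 * tpb) < design$prop_mixed, "mixed", "rich")
    cfg <- t(vapply(env, function(e) as.character(sample_environment(e)),
                    character(4)))
    out <- data.frame(subject = s, trial = seq_len(2 * tpb),
                      block = rep(1:2, each = tpb), battery = battery,
                      env = env)
    out[paste0("area", 1:4)] <- cfg
    out
  }))
  rownames(schedule) <- NULL
  list(subjects = subjects, schedule = schedule)
}

#' Softmax decision noise on the optimal agent's action values
#'
#' Returns a policy that, in each state, selects among the feasible actions
#' with probabilities proportional to `exp(value / beta)`, where the values
#' are the solver's expected coins-to-go.  `beta = 0` reproduces the
#' optimal policy exactly (including its tie-break); large `beta`
#' approaches a uniform choice among feasible actions.  This is the
#' package's stand-in for the stochasticity of human decisions.
#'
#' @param object an [optimal_forager()] providing the action values.
#' @param beta softmax temperature, in coins; `beta >= 0`.
#' @return A policy function usable with [run_trial()].
#' @export
noisy_policy <- function(object, beta) {
  stopifnot(inherits(object, "optimal_forager"), beta >= 0)
  if (beta == 0) {
    return(function(state)
      optimal_action(object, state$knowledge, state$time_remaining,
                     state$location))
  }
  function(state) {
    av <- action_values(object, state$knowledge, state$time_remaining,
                        state$location)
    if (nrow(av) == 0L)
      stop("terminal state: no action is feasible", call. = FALSE)
    w <- exp((av$value - max(av$value)) / beta)
    i <- sample.int(nrow(av), 1L, prob = w)
    list(kind = av$kind[i], target = av$target[i], cost = av$cost[i])
  }
}

#' Generate a complete synthetic study dataset
#'
#' Simulates every trial of a cohort with human-like deviations from
#' optimality: per-subject timing parameters, softmax decision noise on the
#' optimal agent's action values, per-action duration jitter, and optional
#' learning modifiers (a per-trial multiplicative speed-up of the timing
#' parameters and a per-trial decay of the softmax temperature, both off by
#' default).  With `beta = 0` and `jitter_sd = 0` every trial is the
#' optimal trajectory for its hidden layout.
#'
#' @param design a [cohort_design()].
#' @param beta softmax temperature (coins); 1 by default, a moderate noise
#'   level that degrades but does not destroy performance.
#' @param jitter_sd per-action duration noise, seconds.
#' @param timing_speedup per-trial multiplicative factor applied to T1 and
#'   T2 (e.g. 0.99 makes agents faster as trials progress); 1 disables.
#' @param beta_decay per-trial multiplicative factor on `beta`; 1 disables.
#' @param seed optional integer seed.
#' @param task a [forage_task()].
#' @param cohort optionally, a pre-drawn cohort from [sample_cohort()]
#'   (its schedule is then used as-is).
#' @return A list with `logs` (one `trial_log` per subject x trial),
#'   `subjects` and `schedule`.
#' @export
simulate_cohort <- function(design = cohort_design(), beta = 1,
                            jitter_sd = 0.3, timing_speedup = 1,
                            beta_decay = 1, seed = NULL,
                            task = forage_task(), cohort = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cohort)) cohort <- sample_cohort(design)
  subjects <- cohort$subjects
  schedule <- cohort$schedule
  static <- timing_speedup == 1 && beta_decay == 1

  logs <- vector("list", nrow(schedule))
  idx <- 0L
  for (s in subjects$subject) {
    sub_sched <- schedule[schedule$subject == s, , drop = FALSE]
    foragers <- list()
    get_forager <- function(env, battery, t1, t2) {
      key <- paste(env, battery, signif(t1, 10), signif(t2, 10))
      if (is.null(foragers[[key]]))
        foragers[[key]] <<- optimal_forager(t1, t2, env, battery, task)
      foragers[[key]]
    }
    for (r in seq_len(nrow(sub_sched))) {
      row <- sub_sched[r, ]
      fac <- if (static) 1 else timing_speedup^(row$trial - 1)
      t1 <- max(0.5, subjects$T1[s] * fac)
      t2 <- max(t1 + 1e-6, subjects$T2[s] * fac)
      b <- if (static) beta else beta * beta_decay^(row$trial - 1)
      fg <- get_forager(row$env, row$battery, t1, t2)
      cfg <- environment_config(unlist(row[paste0("area", 1:4)]))
      idx <- idx + 1L
      logs[[idx]] <- run_trial(noisy_policy(fg, b), cfg, row$battery,
                               subject_timing(t1, t2), task,
                               jitter_sd = jitter_sd, subject = s,
                               trial = row$trial)
    }
    # Free the per-subject memo tables before moving on.
    for (fg in foragers) .solver_clear(fg$ptr)
  }
  list(logs = logs, subjects = subjects, schedule = schedule)
}
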