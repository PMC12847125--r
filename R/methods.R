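#' @export
print.optimal_forager <- function(x, ...) {
  cat("Optimal foraging agent (finite-horizon backward induction)\n")
  cat(sprintf("  condition: %s environment, %s battery (%g s)\n",
              x$env, x$battery, x$duration))
  cat(sprintf("  timing: T1 = %.3f s, T2 = %.3f s (first entry costs %s)\n",
              x$t1, x$t2, x$first_move))
  cat(sprintf("  expected total coins under optimal play: %.4f\n",
              x$root_value))
  if (is.null(x$root_action))
    cat("  the battery admits no action\n")
  else
    cat(sprintf("  first action: enter area %d\n", x$root_action$target))
  invisible(x)
}

#' @export
coef.optimal_forager <- function(object, ...) {
  subject_timing(object$t1, object$t2)
}

#' Expected trial statistics of the optimal agent
#'
#' Computes the exact expectation of the per-trial dependent variables over
#' the hidden layouts (see [exact_statistics()]), overall and split by the
#' richness of the first-visited area.
#'
#' @param object an [optimal_forager()].
#' @param ... unused.
#' @export
summary.optimal_forager <- function(object, ...) {
  st <- exact_statistics(object)
  structure(list(object = object, stats = st),
            class = "summary.optimal_forager")
}

#' @export
print.summary.optimal_forager <- function(x, ...) {
  print(x$object)
  cat("\nExpected per-trial statistics (exact over hidden layouts):\n")
  print(round(x$stats$means, 4))
  if (length(x$stats$by_first_area) > 1L) {
    cat("\nConditional on first-area richness:\n")
    print(round(do.call(rbind, x$stats$by_first_area), 4))
  }
  invisible(x)
}

#' Predict state values or actions from the solved tree
#'
#' @param object an [optimal_forager()].
#' @param knowledge a [knowledge_state()]; default trial start.
#' @param time_remaining seconds left; default full battery.
#' @param location `"central"` or area index.
#' @param type `"value"` (coins-to-go), `"action"` (the optimal action) or
#'   `"action_values"` (all feasible actions with values).
#' @param ... unused.
#' @export
predict.optimal_forager <- function(object, knowledge = NULL,
                                    time_remaining = NULL,
                                    location = "central",
                                    type = c("value", "action",
                                             "action_values"), ...) {
  type <- match.arg(type)
  switch(type,
         value = state_value(object, knowledge, time_remaining, location),
         action = optimal_action(object, knowledge, time_remaining,
                                 location),
         action_values = action_values(object, knowledge, time_remaining,
                                       location))
}

#' Simulate trials of the optimal agent
#'
#' Draws `nsim` hidden configurations for the agent's condition and rolls
#' out the optimal policy through each, returning the trial logs.
#'
#' @param object an [optimal_forager()].
#' @param nsim number of trials.
#' @param seed optional integer seed.
#' @param jitter_sd per-action duration noise (s); see [run_trial()].
#' @param ... unused.
#' @return A list of `trial_log` objects.
#' @export
simulate.optimal_forager <- function(object, nsim = 1, seed = NULL,
                                     jitter_sd = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    run_trial(object, sample_environment(object$env), object$battery,
              object$timing, object$task, object$first_move, jitter_sd,
              trial = i))
}

#' Plot the root value as a function of remaining time
#'
#' Shows the expected coins-to-go from the trial-start state over a grid of
#' battery durations up to the agent's own, a compact picture of how the
#' time budget constrains attainable reward.
#'
#' @param x an [optimal_forager()].
#' @param n_grid number of grid points.
#' @param ... passed to [plot()].
#' @export
plot.optimal_forager <- function(x, n_grid = 60, ...) {
  ts <- seq(0, x$duration, length.out = n_grid)
  vs <- vapply(ts, function(t) state_value(x, time_remaining = t),
               numeric(1))
  plot(ts, vs, type = "s", xlab = "time remaining (s)",
       ylab = "expected coins-to-go",
       main = sprintf("%s environment, %s battery", x$env, x$battery), ...)
  invisible(data.frame(time = ts, value = vs))
}
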