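#' Per-trial dependent variables
#'
#' Computes the six dependent variables of the behavioral analysis from one
#' trial log: total coins; boxes collected in the first area (the initial
#' contiguous run of collections in the first-visited area); boxes
#' collected; average coins per box; number of unique areas visited (each
#' area counted once regardless of revisits); and average box collection
#' time (mean interval between consecutive collections within the same
#' area, `NA` when no such interval exists).  The first-area richness is
#' the true richness of the first-visited area, known post hoc from the
#' hidden configuration.
#'
#' @param log a `trial_log`.
#' @return A one-row data frame.
#' @export
summarize_trial <- function(log) {
  stopifnot(inherits(log, "trial_log"))
  ev <- log$events
  if (nrow(ev) == 0L)
    stop("malformed log: a trial must contain at least one collection",
         call. = FALSE)
  if (any(diff(ev$t) <= 0))
    stop("malformed log: timestamps not strictly increasing", call. = FALSE)
  first_area <- ev$area[1L]
  streak <- which(ev$area != first_area)
  boxes_first <- if (length(streak) == 0L) nrow(ev) else streak[1L] - 1L
  same_area <- ev$area[-1L] == ev$area[-nrow(ev)]
  intervals <- diff(ev$t)[same_area]
  data.frame(
    subject = log$subject, trial = log$trial, env = log$env,
    battery = log$battery,
    first_area = first_area,
    first_area_richness = log$config[first_area],
    total_coins = sum(ev$coins),
    boxes_first_area = boxes_first,
    boxes_collected = nrow(ev),
    avg_coins_per_box = sum(ev$coins) / nrow(ev),
    n_unique_areas = length(unique(ev$area)),
    avg_box_collection_time =
      if (length(intervals)) mean(intervals) else NA_real_)
}

#' @rdname summarize_trial
#' @param logs a list of `trial_log` objects (or a single one).
#' @return `summarize_trials()`: a data frame with one row per trial.
#' @export
summarize_trials <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  out <- do.call(rbind, lapply(logs, summarize_trial))
  rownames(out) <- NULL
  out
}

#' Estimate timing parameters from trial logs
#'
#' Recovers each subject's collection time T1 and travel time T2 from the
#' inter-collection intervals, pooling all trials regardless of condition:
#' T1 is the mean interval between consecutive collections within the same
#' area, T2 the mean interval between consecutive collections in different
#' areas (leave + travel + first collection).  The first collection of a
#' trial has no preceding event and contributes to neither pool.
#'
#' @param logs a list of `trial_log` objects.
#' @return A data frame with one row per subject: `subject`, `T1_hat`,
#'   `T2_hat`, and the interval counts `n_T1`, `n_T2`.  Errors if any
#'   subject lacks intervals of either kind.
#' @export
estimate_timing <- function(logs) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  pools <- list()
  for (log in logs) {
    ev <- log$events
    if (nrow(ev) < 2L) next
    s <- as.character(log$subject)
    same <- ev$area[-1L] == ev$area[-nrow(ev)]
    d <- diff(ev$t)
    if (is.null(pools[[s]]))
      pools[[s]] <- list(t1 = numeric(0), t2 = numeric(0))
    pools[[s]]$t1 <- c(pools[[s]]$t1, d[same])
    pools[[s]]$t2 <- c(pools[[s]]$t2, d[!same])
  }
  if (length(pools) == 0L)
    stop("no inter-collection intervals in the logs", call. = FALSE)
  out <- do.call(rbind, lapply(names(pools), function(s) {
    p <- pools[[s]]
    if (length(p$t1) == 0L || length(p$t2) == 0L)
      stop(sprintf(
        "subject %s lacks %s intervals", s,
        if (length(p$t1) == 0L) "within-area" else "area-switch"),
        call. = FALSE)
    data.frame(subject = as.integer(s), T1_hat = mean(p$t1),
               T2_hat = mean(p$t2), n_T1 = length(p$t1),
               n_T2 = length(p$t2))
  }))
  out[order(out$subject), , drop = FALSE]
}

#' Area-switch probabilities after each box
#'
#' For every collection event, records whether the agent left the area
#' afterwards (the next collection happened in a different area).  The
#' final event of each trial is censored — the battery, not a decision,
#' ended the visit — and excluded.  Events are classified by environment
#' label, the (revealed) richness of the current area, whether the layout
#' was already inferable at that moment (uncertainty resolved, computed
#' from the knowledge state after the collection), and the box ordinal
#' within the area; the rich environment contributes only resolved rows,
#' giving the five feasible condition cells.
#'
#' @param logs a list of `trial_log` objects.
#' @return A data frame with columns `env`, `area_richness`,
#'   `uncertainty_resolved`, `box`, `n`, `n_leave`, `p_leave`, plus
#'   `subject` when `by_subject = TRUE`.
#' @param by_subject if `TRUE`, tabulate per subject (for subject-level
#'   contrasts).
#' @export
switch_probability_table <- function(logs, by_subject = FALSE) {
  if (inherits(logs, "trial_log")) logs <- list(logs)
  recs <- do.call(rbind, lapply(logs, switch_records))
  if (is.null(recs) || nrow(recs) == 0L)
    stop("no uncensored collection events in the logs", call. = FALSE)
  keys <- c(if (by_subject) "subject", "env", "area_richness",
            "uncertainty_resolved", "box")
  agg <- aggregate(recs$leave, recs[keys],
                   FUN = function(x) c(n = length(x), n_leave = sum(x)))
  out <- cbind(agg[keys], n = agg$x[, "n"], n_leave = agg$x[, "n_leave"])
  out$p_leave <- out$n_leave / out$n
  out[do.call(order, out[keys]), , drop = FALSE]
}

# Event-level leave/stay records for one trial, with the uncertainty flag
# reconstructed from the knowledge state after each collection.
switch_records <- function(log) {
  ev <- log$events
  n <- nrow(ev)
  if (n < 2L) return(NULL)  # single event is trial-final, hence censored
  k <- knowledge_state(log$env)
  resolved <- logical(n)
  for (i in seq_len(n)) {
    a <- ev$area[i]
    k$richness[a] <- log$config[a]
    k$boxes[a] <- k$boxes[a] + 1L
    k <- apply_closure(k)
    resolved[i] <- uncertainty_resolved(k)
  }
  i <- seq_len(n - 1L)
  data.frame(subject = log$subject, env = log$env,
             area_richness = log$config[ev$area[i]],
             uncertainty_resolved = resolved[i],
             box = ev$box[i],
             leave = ev$area[i + 1L] != ev$area[i])
}

#' Compare agent summaries against optimal-agent summaries
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of a dependent variable
#' between two sets of per-trial summaries, per condition cell.  The test
#' uses the exact distribution for small tie-free samples and the normal
#' approximation with tie correction otherwise (the [wilcox.test()]
#' defaults); identical samples give p = 1.
#'
#' @param agent,optimal data frames from [summarize_trials()].
#' @param variable name of the dependent variable column.
#' @param by grouping columns defining the condition cells.
#' @return A data frame with one row per cell: group labels, sample sizes,
#'   the U statistic, the two-sided p value, and the effect direction
#'   (sign of the agent-minus-optimal median difference).
#' @export
compare_to_optimal <- function(agent, optimal, variable,
                               by = c("env", "battery")) {
  stopifnot(variable %in% names(agent), variable %in% names(optimal),
            all(by %in% names(agent)), all(by %in% names(optimal)))
  cells <- unique(rbind(agent[by], optimal[by]))
  rownames(cells) <- NULL
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel_a <- rep(TRUE, nrow(agent)); sel_o <- rep(TRUE, nrow(optimal))
    for (b in by) {
      sel_a <- sel_a & agent[[b]] == cells[i, b]
      sel_o <- sel_o & optimal[[b]] == cells[i, b]
    }
    xa <- agent[[variable]][sel_a]; xo <- optimal[[variable]][sel_o]
    xa <- xa[!is.na(xa)]; xo <- xo[!is.na(xo)]
    if (length(xa) == 0L || length(xo) == 0L)
      stop("empty cell in agent-vs-optimal comparison: ",
           paste(unlist(cells[i, ]), collapse = "/"), call. = FALSE)
    wt <- suppressWarnings(wilcox.test(xa, xo, exact = NULL))
    cbind(cells[i, , drop = FALSE],
          data.frame(n_agent = length(xa), n_optimal = length(xo),
                     statistic = unname(wt$statistic),
                     p_value = wt$p.value,
                     direction = sign(median(xa) - median(xo))))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Linear trend of a dependent variable across trials
#'
#' Averages the variable over subjects at each trial index and fits an
#' ordinary least-squares line to the per-trial means, the learning-curve
#' summary of the analysis stage.
#'
#' @param summaries a data frame from [summarize_trials()].
#' @param variable name of the dependent variable column.
#' @return An object of class `forage_trend`: slope, `r_squared`, the
#'   slope's p value, the number of trial indices, and the underlying
#'   [lm()] fit.
#' @export
learning_trend <- function(summaries, variable) {
  stopifnot(variable %in% names(summaries))
  ok <- !is.na(summaries[[variable]])
  means <- aggregate(summaries[[variable]][ok],
                     list(trial = summaries$trial[ok]), mean)
  names(means)[2L] <- "mean"
  if (nrow(means) < 3L)
    stop("need at least 3 trial indices for a trend fit", call. = FALSE)
  if (sd(means$mean) == 0) {
    return(structure(list(slope = 0, r_squared = 0, p_value = NA_real_,
                          n_trials = nrow(means), fit = NULL,
                          variable = variable),
                     class = "forage_trend"))
  }
  fit <- lm(mean ~ trial, data = means)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2L]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 n_trials = nrow(means), fit = fit, variable = variable),
            class = "forage_trend")
}

#' @export
print.forage_trend <- function(x, ...) {
  cat(sprintf(
    "Trend of %s across %d trials: slope %.4f per trial, R^2 = %.3f, p = %.4g\n",
    x$variable, x$n_trials, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
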