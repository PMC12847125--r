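#' Optimal finite-horizon foraging agent
#'
#' Builds and solves the stochastic decision tree for one task condition
#' (environment label x battery length) and one subject's timing parameters.
#' States are (time remaining, knowledge state, location); actions either
#' stay and collect the next box in the current area (cost `t1` seconds) or
#' move to another area and collect its first reachable box (cost `t2`).
#' Entering an unknown area in a mixed environment branches stochastically
#' on the revealed richness, weighted by the exact posterior over the six
#' possible rich/poor layouts.  Values are expected coins-to-go (terminal
#' nodes are worth 0) and are computed by memoized backward induction; an
#' action is feasible only if its full time cost fits in the remaining time.
#'
#' The very first action, from the central zone, enters an area and collects
#' a box at cost `t1` by default (`first_move = "T1"`); set
#' `first_move = "T2"` to charge the travel cost instead, as a sensitivity
#' check.
#'
#' Ties between equally valued actions are broken deterministically: staying
#' is preferred over moving, and among moves the lowest area index wins.
#'
#' @param t1 collection time within the current area, seconds.
#' @param t2 travel time to another area plus first collection, seconds;
#'   must exceed `t1`.
#' @param env `"mixed"` (two rich + two poor areas, locations hidden) or
#'   `"rich"` (all four areas rich).
#' @param battery `"long"` (50 s by default) or `"short"` (25 s).
#' @param task a [forage_task()]; override to change schedules or durations.
#' @param first_move cost charged for entering the first area from the
#'   central zone, `"T1"` (default) or `"T2"`.
#' @return An object of class `optimal_forager` with components `root_value`
#'   (expected total coins under optimal play) and `root_action`, supporting
#'   [print()], [summary()], [predict()], [simulate()], [coef()] and
#'   [plot()] methods.
#' @examples
#' fit <- optimal_forager(3.41, 6.10, env = "mixed", battery = "long")
#' fit
#' summary(fit)
#' @export
optimal_forager <- function(t1 = 3.41, t2 = 6.10, env = c("mixed", "rich"),
                            battery = c("long", "short"),
                            task = forage_task(),
                            first_move = c("T1", "T2")) {
  env <- match.arg(env)
  battery <- match.arg(battery)
  first_move <- match.arg(first_move)
  timing <- subject_timing(t1, t2)
  duration <- battery_duration(task, battery)
  ptr <- .solver_create(t1, t2, duration, env == "mixed",
                        first_move == "T1", task$rich_coins, task$poor_coins)
  obj <- structure(
    list(t1 = t1, t2 = t2, env = env, battery = battery,
         duration = duration, task = task, first_move = first_move,
         timing = timing, ptr = ptr, call = match.call()),
    class = "optimal_forager")
  obj$root_value <- state_value(obj)
  av <- action_values(obj)
  obj$root_action <- if (nrow(av) == 0L) NULL else optimal_action(obj)
  obj
}

root_knowledge <- function(object) knowledge_state(object$env)

# Translate a (knowledge, location) pair into solver codes.
.solver_args <- function(object, knowledge, location) {
  stopifnot(inherits(knowledge, "knowledge_state"))
  if (knowledge$env != object$env)
    stop("knowledge state is for a different environment label",
         call. = FALSE)
  rz <- match(knowledge$richness, c("unknown", "rich", "poor")) - 1L
  loc <- if (identical(location, "central")) -1L
         else as.integer(location) - 1L
  if (loc < -1L || loc > 3L) stop("invalid location", call. = FALSE)
  list(rz = rz, bx = knowledge$boxes, loc = loc)
}

#' State values and action values under the optimal policy
#'
#' `state_value()` returns the expected coins-to-go of a state under optimal
#' play (0 at terminal states).  `action_values()` lists the feasible
#' actions with their time costs and expected coins-to-go (immediate coins
#' plus successor value, marginalized over reveal outcomes for unknown
#' targets).  `optimal_action()` returns the argmax action with the
#' deterministic tie-break, and errors at terminal states.
#'
#' @param object an [optimal_forager()].
#' @param knowledge a [knowledge_state()]; defaults to the trial-start state.
#' @param time_remaining seconds of battery left; defaults to the full
#'   battery.
#' @param location `"central"` or an area index 1..4.
#' @return `state_value()`: a number.  `action_values()`: a data frame with
#'   columns `kind` (`"stay"`/`"move"`), `target` (area index), `cost`,
#'   `value`.  `optimal_action()`: a list with `kind`, `target`, `cost`.
#' @export
state_value <- function(object, knowledge = NULL, time_remaining = NULL,
                        location = "central") {
  stopifnot(inherits(object, "optimal_forager"))
  if (is.null(knowledge)) knowledge <- root_knowledge(object)
  if (is.null(time_remaining)) time_remaining <- object$duration
  if (time_remaining > object$duration + 1e-9)
    stop("time_remaining exceeds the battery duration", call. = FALSE)
  a <- .solver_args(object, knowledge, location)
  .solver_value(object$ptr, time_remaining, a$rz, a$bx, a$loc)
}

#' @rdname state_value
#' @export
action_values <- function(object, knowledge = NULL, time_remaining = NULL,
                          location = "central") {
  stopifnot(inherits(object, "optimal_forager"))
  if (is.null(knowledge)) knowledge <- root_knowledge(object)
  if (is.null(time_remaining)) time_remaining <- object$duration
  a <- .solver_args(object, knowledge, location)
  res <- .solver_actions(object$ptr, time_remaining, a$rz, a$bx, a$loc)
  data.frame(kind = c("stay", "move")[res$kind + 1L],
             target = res$target + 1L,
             cost = res$cost,
             value = res$value)
}

#' @rdname state_value
#' @export
optimal_action <- function(object, knowledge = NULL, time_remaining = NULL,
                           location = "central") {
  av <- action_values(object, knowledge, time_remaining, location)
  if (nrow(av) == 0L)
    stop("terminal state: no action is feasible", call. = FALSE)
  # Rows are in canonical order (stay, then moves ascending); the first row
  # within tie tolerance of the maximum implements the tie-break.
  best <- which(av$value >= max(av$value) - 1e-9)[1L]
  list(kind = av$kind[best], target = av$target[best], cost = av$cost[best])
}

#' Feasible actions in a state
#'
#' Pure-R enumeration of the action set: staying is feasible if the current
#' area has boxes left and at least `t1` seconds remain; moving to area `a`
#' is feasible if `a` differs from the current location, has boxes left, and
#' at least `t2` seconds remain (the first entry from the central zone is
#' charged per `first_move`).  At a terminal state the data frame is empty.
#'
#' @param knowledge a [knowledge_state()].
#' @param location `"central"` or an area index 1..4.
#' @param time_remaining seconds of battery left.
#' @param timing a [subject_timing()].
#' @param task a [forage_task()].
#' @param first_move `"T1"` or `"T2"`, cost of the first entry from central.
#' @return A data frame with columns `kind`, `target`, `cost`, in canonical
#'   order (stay first, then moves by area index).
#' @export
feasible_actions <- function(knowledge, location, time_remaining, timing,
                             task = forage_task(),
                             first_move = c("T1", "T2")) {
  first_move <- match.arg(first_move)
  stopifnot(inherits(knowledge, "knowledge_state"))
  t1 <- unname(timing[["T1"]]); t2 <- unname(timing[["T2"]])
  eps <- 1e-9
  central <- identical(location, "central")
  kind <- character(0); target <- integer(0); cost <- numeric(0)
  if (!central) {
    loc <- as.integer(location)
    if (knowledge$boxes[loc] < task$boxes_per_area &&
        time_remaining >= t1 - eps) {
      kind <- "stay"; target <- loc; cost <- t1
    }
  }
  move_cost <- if (central) (if (first_move == "T1") t1 else t2) else t2
  for (a in 1:4) {
    if (!central && a == as.integer(location)) next
    if (knowledge$boxes[a] >= task$boxes_per_area) next
    if (time_remaining < move_cost - eps) next
    kind <- c(kind, "move"); target <- c(target, a)
    cost <- c(cost, move_cost)
  }
  data.frame(kind = kind, target = target, cost = cost)
}
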