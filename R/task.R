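#' Task configuration
#'
#' Fixed structure of the foraging task: four areas of five coin boxes each,
#' a linearly depleting coin schedule per area type, and two battery (time
#' budget) conditions.  Rich areas pay 8,7,6,5,4 coins in collection order;
#' poor areas pay 5,4,3,2,1.  The long battery lasts 50 s and the short one
#' 25 s.  All defaults can be overridden for sensitivity analyses; the area
#' count is fixed at four because the belief machinery is specific to the
#' two-rich/two-poor composition.
#'
#' @param battery_long,battery_short battery durations in seconds.
#' @param rich_coins,poor_coins integer coin schedules, one value per box in
#'   collection order, strictly decreasing.
#' @param boxes_per_area number of boxes in each area.
#' @return An object of class `forage_task`.
#' @examples
#' task <- forage_task()
#' total_coins_available(sample_environment("mixed"), task)
#' @export
forage_task <- function(battery_long = 50, battery_short = 25,
                        rich_coins = c(8L, 7L, 6L, 5L, 4L),
                        poor_coins = c(5L, 4L, 3L, 2L, 1L),
                        boxes_per_area = 5L) {
  boxes_per_area <- as.integer(boxes_per_area)
  rich_coins <- as.integer(rich_coins)
  poor_coins <- as.integer(poor_coins)
  stopifnot(battery_long > 0, battery_short > 0,
            battery_long >= battery_short,
            length(rich_coins) == boxes_per_area,
            length(poor_coins) == boxes_per_area,
            all(diff(rich_coins) < 0), all(diff(poor_coins) < 0),
            all(rich_coins > 0), all(poor_coins > 0))
  structure(
    list(n_areas = 4L, boxes_per_area = boxes_per_area,
         rich_coins = rich_coins, poor_coins = poor_coins,
         battery = c(long = battery_long, short = battery_short)),
    class = "forage_task")
}

#' @export
print.forage_task <- function(x, ...) {
  cat("Patch-foraging task\n")
  cat(sprintf("  %d areas x %d boxes\n", x$n_areas, x$boxes_per_area))
  cat("  rich schedule:", paste(x$rich_coins, collapse = ", "), "coins\n")
  cat("  poor schedule:", paste(x$poor_coins, collapse = ", "), "coins\n")
  cat(sprintf("  battery: long %g s, short %g s\n",
              x$battery[["long"]], x$battery[["short"]]))
  invisible(x)
}

#' @rdname forage_task
#' @param task a `forage_task`.
#' @param battery `"long"` or `"short"`.
#' @return `battery_duration()`: the duration in seconds.
#' @export
battery_duration <- function(task, battery = c("long", "short")) {
  battery <- match.arg(battery)
  unname(task$battery[[battery]])
}

#' Coins delivered by the next box of an area
#'
#' The first box of a rich area always delivers the top of the rich schedule
#' (8 coins by default) and the first box of a poor area the top of the poor
#' schedule (5 coins); subsequent boxes deplete linearly.  Once all boxes are
#' taken the area is empty and `NA` is returned.
#'
#' @param richness `"rich"` or `"poor"`.  An `"unknown"` area has no defined
#'   next coin value; callers must marginalize over the belief state instead,
#'   so `"unknown"` is an error here.
#' @param boxes_taken number of boxes already collected in the area, 0..5.
#' @param task a [forage_task()].
#' @return Integer coin count, or `NA_integer_` when the area is exhausted.
#' @examples
#' next_box_coins("rich", 0)  # 8
#' next_box_coins("poor", 4)  # 1
#' next_box_coins("rich", 5)  # NA: empty
#' @export
next_box_coins <- function(richness, boxes_taken, task = forage_task()) {
  if (!richness %in% c("rich", "poor"))
    stop("richness must be \"rich\" or \"poor\"; marginalize unknown areas ",
         "over the belief state instead", call. = FALSE)
  boxes_taken <- as.integer(boxes_taken)
  stopifnot(length(boxes_taken) == 1L, boxes_taken >= 0,
            boxes_taken <= task$boxes_per_area)
  if (boxes_taken == task$boxes_per_area) return(NA_integer_)
  sched <- if (richness == "rich") task$rich_coins else task$poor_coins
  sched[boxes_taken + 1L]
}

#' Environment configurations
#'
#' The hidden truth of one trial: the richness of each of the four areas.
#' A `"rich"` environment has all four areas rich; a `"mixed"` environment
#' has exactly two rich and two poor areas, placed uniformly at random among
#' the six possible arrangements.  Areas are indexed 1..4 in the fixed order
#' North, East, South, West.
#'
#' @param richness character vector of length 4 with entries `"rich"` /
#'   `"poor"`; must be all-rich or exactly two of each.
#' @return `environment_config()`: a validated character vector of class
#'   `environment_config`.
#' @export
environment_config <- function(richness) {
  richness <- as.character(richness)
  stopifnot(length(richness) == 4L, all(richness %in% c("rich", "poor")))
  nr <- sum(richness == "rich")
  if (!(nr == 4L || nr == 2L))
    stop("configuration must be all-rich or exactly 2 rich + 2 poor",
         call. = FALSE)
  structure(richness, class = "environment_config")
}

#' @rdname environment_config
#' @param config an environment configuration (or any rich/poor vector).
#' @return `env_label()`: `"rich"` or `"mixed"`.
#' @export
env_label <- function(config) {
  if (all(config == "rich")) "rich" else "mixed"
}

#' @rdname environment_config
#' @param label `"rich"` or `"mixed"`.
#' @details `sample_environment()` draws from R's global random number
#'   stream; seed with [set.seed()] for reproducibility.
#' @export
sample_environment <- function(label = c("mixed", "rich")) {
  label <- match.arg(label)
  if (label == "rich") return(environment_config(rep("rich", 4)))
  richness <- rep("poor", 4)
  richness[sample.int(4L, 2L)] <- "rich"
  environment_config(richness)
}

#' @rdname environment_config
#' @param task a [forage_task()].
#' @return `total_coins_available()`: the sum over areas of the full
#'   schedule of the area's type (120 for all-rich, 90 for mixed).
#' @export
total_coins_available <- function(config, task = forage_task()) {
  stopifnot(length(config) == 4L, all(config %in% c("rich", "poor")))
  sums <- c(rich = sum(task$rich_coins), poor = sum(task$poor_coins))
  sum(sums[as.character(config)])
}

#' Per-subject timing parameters
#'
#' `t1` is the time to collect the next box within the current area; `t2` the
#' time to leave the area, travel, and collect the first box in another area.
#' Travelling necessarily takes longer than staying, so `t2 > t1 > 0`.
#'
#' @param t1,t2 times in seconds.
#' @return A named numeric vector of class `subject_timing`.
#' @export
subject_timing <- function(t1 = 3.41, t2 = 6.10) {
  stopifnot(is.numeric(t1), is.numeric(t2), t1 > 0, t2 > t1)
  structure(c(T1 = t1, T2 = t2), class = "subject_timing")
}

#' Read and write the task configuration as YAML
#'
#' Serializes the task parameters (battery durations, coin schedules, area
#' and box counts) to a plain-text YAML file, so sensitivity analyses can be
#' driven from a config file.
#'
#' @param task a [forage_task()].
#' @param path file path.
#' @export
write_task_config <- function(task, path) {
  yaml::write_yaml(list(
    n_areas = task$n_areas,
    boxes_per_area = task$boxes_per_area,
    rich_coins = task$rich_coins,
    poor_coins = task$poor_coins,
    battery_long = unname(task$battery[["long"]]),
    battery_short = unname(task$battery[["short"]])), path)
  invisible(path)
}

#' @rdname write_task_config
#' @return `read_task_config()`: a `forage_task`.
#' @export
read_task_config <- function(path) {
  y <- yaml::read_yaml(path)
  forage_task(battery_long = y$battery_long, battery_short = y$battery_short,
              rich_coins = y$rich_coins, poor_coins = y$poor_coins,
              boxes_per_area = y$boxes_per_area)
}
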