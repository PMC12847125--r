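#' Knowledge state of a foraging agent
#'
#' What an agent can know mid-trial: for each area, either the revealed
#' richness (learned when the first box there was collected) together with
#' the number of boxes taken, or `"unknown"` with zero boxes taken.  The
#' environment label (rich vs mixed) is always known via the sensor consulted
#' at trial start.  In a rich environment nothing is ever unknown; in a mixed
#' environment at most two areas can be revealed rich and at most two poor,
#' and once two areas of the same type are revealed the remaining areas are
#' logically forced (see [apply_closure()]).
#'
#' @param env `"rich"` or `"mixed"`: the sensor reading.
#' @param richness character vector of length 4 over
#'   `c("rich", "poor", "unknown")`.  Defaults to all-rich in a rich
#'   environment and all-unknown in a mixed one (the trial-start state).
#' @param boxes integer vector of length 4, boxes already taken per area.
#' @return An object of class `knowledge_state`.
#' @examples
#' k <- knowledge_state("mixed",
#'                      richness = c("rich", "poor", "unknown", "unknown"),
#'                      boxes = c(1, 1, 0, 0))
#' format(k)  # "(7, 4, ?, ?)"
#' @export
knowledge_state <- function(env = c("mixed", "rich"), richness = NULL,
                            boxes = NULL) {
  env <- match.arg(env)
  if (is.null(richness))
    richness <- if (env == "rich") rep("rich", 4) else rep("unknown", 4)
  if (is.null(boxes)) boxes <- rep(0L, 4)
  boxes <- as.integer(boxes)
  stopifnot(length(richness) == 4L, length(boxes) == 4L,
            all(richness %in% c("rich", "poor", "unknown")),
            all(boxes >= 0L), all(boxes <= 5L))
  if (any(richness == "unknown" & boxes > 0L))
    stop("an unknown area cannot have boxes taken: richness is revealed ",
         "upon first collection", call. = FALSE)
  if (env == "rich" && any(richness == "poor"))
    stop("no poor areas exist in a rich environment", call. = FALSE)
  if (env == "mixed" &&
      (sum(richness == "rich") > 2L || sum(richness == "poor") > 2L))
    stop("a mixed environment has exactly two rich and two poor areas",
         call. = FALSE)
  structure(list(env = env, richness = richness, boxes = boxes),
            class = "knowledge_state")
}

#' @export
format.knowledge_state <- function(x, task = forage_task(), ...) {
  # Compact tuple of next-box coin values, "?" for unknown, "-" for empty.
  vals <- vapply(seq_len(4L), function(i) {
    if (x$richness[i] == "unknown") return("?")
    v <- next_box_coins(x$richness[i], x$boxes[i], task)
    if (is.na(v)) "-" else as.character(v)
  }, character(1))
  paste0("(", paste(vals, collapse = ", "), ")")
}

#' @export
print.knowledge_state <- function(x, ...) {
  cat(sprintf("Knowledge state [%s environment]: %s\n", x$env, format(x)))
  cat("  boxes taken:", paste(x$boxes, collapse = ", "), "\n")
  invisible(x)
}

#' Forced inferences on a knowledge state
#'
#' Applies all logically forced inferences: in a mixed environment, once two
#' areas are revealed rich the remaining unknown areas must be poor (and vice
#' versa); in a rich environment every area is rich from the start.  The
#' operation is idempotent and never alters an already revealed entry.
#'
#' @param k a [knowledge_state()].
#' @return The closed `knowledge_state`.
#' @export
apply_closure <- function(k) {
  stopifnot(inherits(k, "knowledge_state"))
  r <- k$richness
  if (k$env == "rich") {
    r[r == "unknown"] <- "rich"
  } else if (sum(r == "rich") >= 2L) {
    r[r == "unknown"] <- "poor"
  } else if (sum(r == "poor") >= 2L) {
    r[r == "unknown"] <- "rich"
  }
  k$richness <- r
  k
}

#' Is the rich/poor layout fully determined?
#'
#' `TRUE` once every area's richness is known or inferable: always in a rich
#' environment, and in a mixed environment exactly when two areas of the same
#' type have been revealed (directly or by inference).
#'
#' @param k a [knowledge_state()].
#' @return Logical scalar.
#' @export
uncertainty_resolved <- function(k) {
  k <- apply_closure(k)
  !any(k$richness == "unknown")
}

#' Environment configurations consistent with a knowledge state
#'
#' Enumerates every hidden configuration that could underlie the current
#' knowledge, with its posterior probability.  Because rich/poor placements
#' are uniform a priori, the posterior is uniform over the consistent set
#' (six configurations at the start of a mixed trial, fewer as areas are
#' revealed, exactly one in a rich environment).
#'
#' @param k a [knowledge_state()].
#' @return A data frame with columns `area1`..`area4` (richness) and `prob`;
#'   probabilities sum to 1.
#' @export
consistent_configs <- function(k) {
  stopifnot(inherits(k, "knowledge_state"))
  if (k$env == "rich") {
    out <- as.data.frame(as.list(setNames(rep("rich", 4),
                                          paste0("area", 1:4))))
    out$prob <- 1
    return(out)
  }
  pairs <- utils::combn(4L, 2L)
  cfgs <- apply(pairs, 2L, function(idx) {
    r <- rep("poor", 4)
    r[idx] <- "rich"
    r
  })
  keep <- apply(cfgs, 2L, function(cfg)
    all(k$richness == "unknown" | k$richness == cfg))
  cfgs <- cfgs[, keep, drop = FALSE]
  if (ncol(cfgs) == 0L)
    stop("knowledge state is inconsistent with a 2 rich + 2 poor layout",
         call. = FALSE)
  out <- as.data.frame(t(cfgs), stringsAsFactors = FALSE)
  names(out) <- paste0("area", 1:4)
  rownames(out) <- NULL
  out$prob <- 1 / nrow(out)
  out
}

#' Posterior probability that an unexplored area is rich
#'
#' When the agent enters an unknown area in a mixed environment, the first
#' collected box reveals the area's type.  The reveal probability follows the
#' urn of two rich and two poor areas:
#' `p(rich) = (2 - #revealed rich) / (4 - #revealed)`, where revealed counts
#' include inferred areas.  With one rich and one poor area known this is the
#' 50/50 branch of the decision tree; with nothing known it is also 1/2.
#'
#' @param k a [knowledge_state()] with `env = "mixed"`.
#' @param area area index 1..4; must be unknown in `k`.
#' @return The probability in `[0, 1]` that the area is revealed rich.
#' @export
prob_rich_if_entered <- function(k, area) {
  stopifnot(inherits(k, "knowledge_state"))
  if (k$env == "rich")
    stop("nothing is unknown in a rich environment", call. = FALSE)
  k <- apply_closure(k)
  area <- as.integer(area)
  stopifnot(length(area) == 1L, area >= 1L, area <= 4L)
  if (k$richness[area] != "unknown")
    stop(sprintf("area %d is already revealed %s", area, k$richness[area]),
         call. = FALSE)
  nr <- sum(k$richness == "rich")
  np <- sum(k$richness == "poor")
  (2 - nr) / (4 - nr - np)
}
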