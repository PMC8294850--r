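#' Construct a time-stamped node sequence
#'
#' The node sequence is the core reduced representation of a session: the
#' ordered list of maze nodes the animal's nose entered, with arrival times,
#' interleaved with cage residencies (rows with `location == "cage"` and
#' `node = NA`). A transition between two consecutive maze nodes is a "step".
#'
#' @param node Integer node ids (0-based); `NA` for cage rows.
#' @param time Numeric arrival times in seconds, nondecreasing.
#' @param location Character, `"maze"` or `"cage"`; default all `"maze"`.
#' @param maze Optional `maze_graph`; if supplied, consecutive maze nodes are
#'   checked for graph adjacency.
#' @return A `data.frame` of class `node_sequence` with columns
#'   `node`, `time`, `location`.
#' @export
node_sequence <- function(node, time, location = rep("maze", length(node)),
                          maze = NULL) {
  if (length(node) != length(time) || length(node) != length(location))
    stop("node, time, location must have equal length", call. = FALSE)
  if (length(time) > 1L && any(diff(time) < 0))
    stop("times must be nondecreasing", call. = FALSE)
  if (any(location == "maze" & is.na(node)))
    stop("maze rows must carry a node id", call. = FALSE)
  seq <- data.frame(node = as.integer(node), time = as.numeric(time),
                    location = as.character(location))
  class(seq) <- c("node_sequence", "data.frame")
  if (!is.null(maze)) .check_seq_adjacent(seq, maze)
  seq
}

.check_seq_adjacent <- function(seq, maze) {
  bouts <- segment_bouts(seq)
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start[b]:bouts$end[b]
    if (length(idx) < 2L) next
    a <- seq$node[idx[-length(idx)]]; z <- seq$node[idx[-1L]]
    ok <- .steps_adjacent(a, z)
    if (!all(ok))
      stop("non-adjacent maze step at row ", idx[which(!ok)[1L]], call. = FALSE)
  }
  invisible(TRUE)
}

.steps_adjacent <- function(a, b) {
  (a == (b - 1L) %/% 2L & b > 0L) | (b == (a - 1L) %/% 2L & a > 0L)
}

#' Write / read node sequences as delimited text
#'
#' Tab-separated with header `node_id`, `t_s`, `location`; cage rows have an
#' empty `node_id`.
#'
#' @param seq A `node_sequence`.
#' @param path File path.
#' @return `read_node_sequence` returns a `node_sequence`.
#' @export
write_node_sequence <- function(seq, path) {
  df <- data.frame(node_id = seq$node, t_s = seq$time, location = seq$location)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_node_sequence
#' @export
read_node_sequence <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "", stringsAsFactors = FALSE)
  node_sequence(df$node_id, df$t_s, df$location)
}

#' Reduce a continuous keypoint track to a node sequence
#'
#' Marks the times when the nose trajectory enters a new node cell (the grid
#' cells centred on T-junctions and end nodes). Re-entering the same node cell
#' without visiting another node cell in between is not a new node event. A
#' new cell is registered only once the nose has crossed the midline of that
#' cell (hysteresis against boundary jitter). Frames outside the maze bounding
#' box are classified as cage.
#'
#' @param track A data.frame with columns `time`, `x`, `y` (grid units in the
#'   maze frame, as produced by [render_track()]).
#' @param maze A `maze_graph`.
#' @param register_radius Chebyshev distance to a node-cell centre below which
#'   the cell counts as entered (default 0.25 = the cell midline).
#' @param smooth_frames Width (frames) of a centred moving-average filter
#'   applied to the coordinates before cell assignment, suppressing tracking
#'   jitter (default 5; 1 disables).
#' @param teleport Repair policy when consecutive node events are not
#'   graph-adjacent: `"split"` (default) breaks the sequence with an
#'   interposed cage marker and warns; `"interpolate"` inserts the unique
#'   tree path with interpolated times.
#' @return A `node_sequence`.
#' @export
to_node_sequence <- function(track, maze, register_radius = 0.25,
                             smooth_frames = 5L,
                             teleport = c("split", "interpolate")) {
  teleport <- match.arg(teleport)
  if (nrow(track) == 0L)
    return(node_sequence(integer(0), numeric(0), character(0)))
  if (smooth_frames > 1L && nrow(track) > smooth_frames) {
    f <- rep(1 / smooth_frames, smooth_frames)
    xs <- as.numeric(stats::filter(track$x, f, sides = 2))
    ys <- as.numeric(stats::filter(track$y, f, sides = 2))
    keep <- !is.na(xs)
    track <- data.frame(time = track$time[keep], x = xs[keep], y = ys[keep])
  }
  # node lookup by rounded grid coordinate
  key <- paste(maze$coords[, 1], maze$coords[, 2])
  cx <- round(track$x); cy <- round(track$y)
  hit <- match(paste(cx, cy), key)            # candidate node id + 1 or NA
  near <- !is.na(hit) &
    pmax(abs(track$x - cx), abs(track$y - cy)) <= register_radius
  half <- max(abs(maze$coords)) + 0.5
  in_maze <- abs(track$x) <= half + 0.5 & abs(track$y) <= half + 0.5

  node <- integer(0); time <- numeric(0); loc <- character(0)
  cur <- NA_integer_; cur_loc <- "cage"
  for (i in seq_len(nrow(track))) {
    if (!in_maze[i]) {
      if (cur_loc != "cage") {
        node <- c(node, NA_integer_); time <- c(time, track$time[i])
        loc <- c(loc, "cage"); cur_loc <- "cage"; cur <- NA_integer_
      }
      next
    }
    if (near[i]) {
      id <- maze$node_ids[hit[i]]
      if (is.na(cur) || id != cur) {
        node <- c(node, id); time <- c(time, track$time[i])
        loc <- c(loc, "maze"); cur <- id; cur_loc <- "maze"
      }
    }
  }
  .repair_teleports(node, time, loc, maze, teleport)
}

.repair_teleports <- function(node, time, loc, maze, policy) {
  n <- length(node)
  if (n < 2L) return(node_sequence(node, time, loc))
  out_n <- integer(0); out_t <- numeric(0); out_l <- character(0)
  push <- function(nn, tt, ll) {
    out_n <<- c(out_n, nn); out_t <<- c(out_t, tt); out_l <<- c(out_l, ll)
  }
  push(node[1L], time[1L], loc[1L])
  for (i in 2L:n) {
    if (loc[i] == "maze" && loc[i - 1L] == "maze" &&
        !.steps_adjacent(node[i - 1L], node[i])) {
      if (policy == "interpolate") {
        p <- .tree_path(node[i - 1L], node[i])
        mid <- p[-c(1L, length(p))]
        if (length(mid)) {
          tt <- seq(time[i - 1L], time[i],
                    length.out = length(p))[-c(1L, length(p))]
          push(mid, tt, rep("maze", length(mid)))
        }
      } else {
        warning("non-adjacent node events at t=", signif(time[i], 6),
                "; sequence split", call. = FALSE)
        push(NA_integer_, time[i], "cage")
      }
    }
    push(node[i], time[i], loc[i])
  }
  node_sequence(out_n, out_t, out_l)
}

# unique path between nodes a and b (inclusive), via heap ancestry
.tree_path <- function(a, b) {
  up_a <- a; x <- a
  while (x != 0L) { x <- (x - 1L) %/% 2L; up_a <- c(up_a, x) }
  up_b <- b; x <- b
  while (x != 0L) { x <- (x - 1L) %/% 2L; up_b <- c(up_b, x) }
  lca <- up_a[min(which(up_a %in% up_b))]
  ib <- which(up_b == lca)
  c(up_a[seq_len(which(up_a == lca))],
    if (ib > 1L) rev(up_b[seq_len(ib - 1L)]))
}

#' Segment a node sequence into bouts
#'
#' A bout is one foray into the maze, from entrance to exit: a maximal
#' contiguous run of maze-labelled rows.
#'
#' @param seq A `node_sequence`.
#' @return A data.frame with one row per bout: `bout`, `start`, `end` (row
#'   indices into `seq`), `entry_time`, `exit_time`, `n_steps`.
#' @export
segment_bouts <- function(seq) {
  is_maze <- seq$location == "maze"
  if (!any(is_maze))
    return(data.frame(bout = integer(0), start = integer(0), end = integer(0),
                      entry_time = numeric(0), exit_time = numeric(0),
                      n_steps = integer(0)))
  r <- rle(is_maze)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  # exit time = start of following cage residency if recorded, else last event
  exit_t <- vapply(seq_along(ends), function(k) {
    j <- ends[k] + 1L
    if (j <= nrow(seq)) seq$time[j] else seq$time[ends[k]]
  }, numeric(1))
  data.frame(bout = seq_along(starts), start = starts, end = ends,
             entry_time = seq$time[starts], exit_time = exit_t,
             n_steps = pmax(ends - starts, 0L))
}

#' Cage and maze residency durations
#'
#' Durations of the contiguous residencies in each location, with the final
#' (right-censored) residency flagged.
#'
#' @param seq A `node_sequence`.
#' @param where `"maze"` or `"cage"`.
#' @param end_time Observation end (default: last event time).
#' @return A data.frame `duration`, `censored` usable by
#'   [cumulative_hazard()].
#' @export
residency_durations <- function(seq, where = c("maze", "cage"),
                                end_time = NULL) {
  where <- match.arg(where)
  if (is.null(end_time)) end_time <- max(seq$time)
  r <- rle(seq$location == "maze")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- if (where == "maze") r$values else !r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts))
    return(data.frame(duration = numeric(0), censored = logical(0)))
  t0 <- seq$time[starts]
  t1 <- vapply(ends, function(e) {
    if (e + 1L <= nrow(seq)) seq$time[e + 1L] else end_time
  }, numeric(1))
  cens <- ends == nrow(seq)
  data.frame(duration = pmax(t1 - t0, 0), censored = cens)
}

#' Map absolute times to cumulative time-in-maze
#'
#' Event times for changepoint analysis are measured in time spent in the
#' maze, with cage residencies excised.
#'
#' @param seq A `node_sequence`.
#' @param t Absolute times (seconds).
#' @return Numeric vector of in-maze times; the total in-maze duration is
#'   attached as attribute `"total"`.
#' @export
in_maze_time <- function(seq, t) {
  bouts <- segment_bouts(seq)
  if (!nrow(bouts)) return(structure(rep(0, length(t)), total = 0))
  t0 <- bouts$entry_time; t1 <- bouts$exit_time
  cum0 <- cumsum(c(0, head(t1 - t0, -1)))
  out <- vapply(t, function(tt) {
    k <- findInterval(tt, t0)
    if (k == 0L) return(0)
    cum0[k] + min(max(tt - t0[k], 0), t1[k] - t0[k])
  }, numeric(1))
  structure(out, total = sum(t1 - t0))
}

#' Reversal flags of a node run
#'
#' Position i of a node vector is a reversal pivot when the node after i
#' equals the node before i (the animal backtracked its last step).
#'
#' @param nodes Integer node vector.
#' @return Logical vector, same length.
#' @export
reversal_pivots <- function(nodes) {
  n <- length(nodes)
  piv <- rep(FALSE, n)
  if (n >= 3L) piv[2:(n - 1L)] <- nodes[1:(n - 2L)] == nodes[3:n]
  piv
}

#' Find long direct paths ending at a target node
#'
#' A direct path is a node run without reversals. For every arrival at
#' `target`, the maximal reversal-free run ending there is extracted; it
#' qualifies if its junction count (number of T-junctions among the nodes
#' before the target) is strictly greater than `min_junctions`. The perfect
#' six-step entrance run passes through 6 junctions and is excluded by the
#' default `min_junctions = 6`.
#'
#' @param seq A `node_sequence`.
#' @param maze A `maze_graph`.
#' @param target Node id.
#' @param min_junctions Strict lower bound on the junction count (default 6).
#' @return A data.frame with one row per qualifying path: `start`, `end` (row
#'   indices), `start_node`, `n_junctions`, `start_time`, `end_time`.
#' @export
find_direct_paths <- function(seq, maze, target, min_junctions = 6L) {
  bouts <- segment_bouts(seq)
  out <- list()
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start[b]:bouts$end[b]
    nodes <- seq$node[idx]
    piv <- which(reversal_pivots(nodes))
    for (k in which(nodes == target)) {
      if (k == 1L) next
      lastpiv <- piv[piv < k]
      j <- if (length(lastpiv)) max(lastpiv) else 1L
      path <- nodes[j:k]
      nj <- sum(maze$node_kind[path[-length(path)] + 1L] == "junction")
      if (nj > min_junctions) {
        out[[length(out) + 1L]] <- data.frame(
          start = idx[j], end = idx[k], start_node = nodes[j],
          n_junctions = nj, start_time = seq$time[idx[j]],
          end_time = seq$time[idx[k]])
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      start_node = integer(0), n_junctions = integer(0),
                      start_time = numeric(0), end_time = numeric(0)))
  do.call(rbind, out)
}

#' Event train of long direct paths, on the in-maze clock
#'
#' Collects completion times of long direct paths to one or more target nodes
#' (e.g. the water port, or its three symmetry controls) as an event train for
#' changepoint analysis. When several targets are pooled the per-target rate
#' is the returned count divided by the number of targets.
#'
#' @inheritParams find_direct_paths
#' @param targets Integer vector of target node ids.
#' @return An [event_train()] on `[0, total in-maze time]`, with attribute
#'   `"n_targets"`.
#' @export
long_path_train <- function(seq, maze, targets, min_junctions = 6L) {
  tt <- numeric(0)
  for (tg in targets) {
    dp <- find_direct_paths(seq, maze, tg, min_junctions)
    tt <- c(tt, dp$end_time)
  }
  mt <- in_maze_time(seq, sort(tt))
  structure(event_train(as.numeric(mt), attr(mt, "total")),
            n_targets = length(targets))
}

#' Turning errors of a path from its length
#'
#' In a tree every wrong step must be backtracked, so a path of even excess
#' length over the direct path contains (length - direct length)/2 errors.
#'
#' @param path_length Path length in steps.
#' @param direct_length Direct-path length in steps.
#' @return Integer error count.
#' @export
count_errors <- function(path_length, direct_length) {
  if (any(path_length < direct_length))
    stop("path_length must be >= direct_length", call. = FALSE)
  d <- path_length - direct_length
  if (any(d %% 2 != 0))
    stop("odd path-length excess: mis-segmented path", call. = FALSE)
  as.integer(d / 2)
}

#' Home run of a bout
#'
#' The maximal reversal-free terminal segment of a bout ending at the central
#' junction (node 0): the direct path that takes the animal to the exit.
#'
#' @param seq A `node_sequence`.
#' @param bout One row of [segment_bouts()] output (or its index).
#' @param maze Optional `maze_graph` for reporting the start level.
#' @return List with `nodes`, `start_node`, `start_level` (if `maze` given),
#'   `length` (steps), `start_time`, `end_time`.
#' @export
home_run <- function(seq, bout, maze = NULL) {
  if (is.numeric(bout) && length(bout) == 1L) bout <- segment_bouts(seq)[bout, ]
  idx <- bout$start:bout$end
  nodes <- seq$node[idx]
  k <- length(nodes)
  if (nodes[k] != 0L)
    stop("bout does not end at the central junction", call. = FALSE)
  piv <- which(reversal_pivots(nodes))
  j <- if (length(piv)) max(piv) else 1L
  run <- nodes[j:k]
  list(nodes = run, start_node = run[1L],
       start_level = if (!is.null(maze)) maze$level[run[1L] + 1L] else NA,
       length = length(run) - 1L,
       start_time = seq$time[idx[j]], end_time = seq$time[idx[k]])
}

#' Overlap between an outbound and a home path
#'
#' Number of distinct nodes present in both paths. The minimum is 1 because
#' both pass through the central junction.
#'
#' @param outbound,home Integer node vectors.
#' @return Integer count of shared distinct nodes.
#' @export
path_overlap <- function(outbound, home) {
  length(intersect(unique(outbound), unique(home)))
}

#' Visit times at a node under the two-step rule
#'
#' A new visit to the target only counts once the animal has moved at least
#' two steps away since the previous qualifying visit, which avoids counting
#' rapid flickers between adjacent nodes.
#'
#' @param seq A `node_sequence`.
#' @param maze A `maze_graph`.
#' @param node Target node id.
#' @param min_departure Required tree distance before re-qualifying
#'   (default 2).
#' @return Numeric vector of qualifying visit times.
#' @export
visit_times <- function(seq, maze, node, min_departure = 2L) {
  times <- numeric(0)
  armed <- TRUE
  for (i in seq_len(nrow(seq))) {
    if (seq$location[i] != "maze") { armed <- TRUE; next }
    v <- seq$node[i]
    if (v == node) {
      if (armed) { times <- c(times, seq$time[i]); armed <- FALSE }
    } else if (!armed && tree_distance(maze, v, node) >= min_departure) {
      armed <- TRUE
    }
  }
  times
}
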