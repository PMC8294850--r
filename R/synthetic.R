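#' Recipe for a synthetic labyrinth session
#'
#' Describes the data-generating process for a full night of cage/maze
#' behaviour with known ground truth: cage residencies with a hazard that
#' starts high and relaxes (the animal is most likely to re-enter the maze
#' right after returning to the cage), maze bouts with a constant exit
#' hazard, within-bout behaviour alternating drink / explore / leave
#' activities, reward delivery with a port timeout, and scheduled abrupt
#' policy switches.
#'
#' @param duration Session length in seconds (default 25200 = 7 h).
#' @param maze_config A [maze_config()].
#' @param epochs List of epoch configs, each a list with `start` (s),
#'   `policy` (a [bias_set()] for a biased walk or `"unbiased"`),
#'   `p_drink_start` (probability a bout opens with a water run),
#'   `p_drink_step` (per-step hazard of switching from explore to a water
#'   run). Later epochs model abrupt policy switches ("insight").
#' @param rewarded Logical; unrewarded sessions have no drink activities.
#' @param p_explore_after_drink Probability of exploring after a drink
#'   (default 0.9, the rest leave).
#' @param reward_timeout Port re-arming timeout (default 90 s).
#' @param drink_dwell Time spent at the port per drink (default 5 s).
#' @param step_dt Seconds per node-to-node step (default 0.7, giving the
#'   observed scale of ~16,000 steps per 7-h session at ~50% maze residency).
#' @param cage_rate_late Asymptotic cage-to-maze hazard (default 1/160 /s).
#' @param cage_decline Initial-to-late hazard ratio (default 4: the entry
#'   rate declines fourfold over the first minute in the cage).
#' @param cage_tau Hazard relaxation time constant (default 20 s).
#' @param exit_rate Constant maze-to-cage hazard (default 1/120 /s).
#' @return Object of class `session_recipe`.
#' @export
session_recipe <- function(duration = 25200,
                           maze_config = labmaze::maze_config(),
                           epochs = list(list(start = 0,
                                              policy = bias_set(0.85, 0.55, 0.90, 0.60),
                                              p_drink_start = 0.5,
                                              p_drink_step = 0.002)),
                           rewarded = TRUE,
                           p_explore_after_drink = 0.9,
                           reward_timeout = 90,
                           drink_dwell = 5,
                           step_dt = 0.7,
                           cage_rate_late = 1 / 160,
                           cage_decline = 4,
                           cage_tau = 20,
                           exit_rate = 1 / 120) {
  starts <- vapply(epochs, function(e) e$start, numeric(1))
  if (any(starts < 0) || any(starts > duration) || is.unsorted(starts))
    stop("epoch start times must be sorted within the session", call. = FALSE)
  structure(as.list(environment()), class = "session_recipe")
}

# cage residency duration by inversion of the cumulative hazard
# r(t) = r_inf + r_inf*(decline-1)*exp(-t/tau)
.draw_cage_duration <- function(recipe) {
  r_inf <- recipe$cage_rate_late
  A <- r_inf * (recipe$cage_decline - 1)
  tau <- recipe$cage_tau
  E <- stats::rexp(1)
  Lam <- function(t) r_inf * t + A * tau * (1 - exp(-t / tau))
  upper <- 10 / r_inf
  while (Lam(upper) < E) upper <- upper * 2
  stats::uniroot(function(t) Lam(t) - E, c(0, upper))$root
}

.epoch_at <- function(recipe, t) {
  starts <- vapply(recipe$epochs, function(e) e$start, numeric(1))
  recipe$epochs[[max(which(starts <= t))]]
}

#' Generate a synthetic session with ground truth
#'
#' Runs the recipe's generative model and returns the node sequence (with
#' cage residencies), reward event times, and a ground-truth log: mode
#' segments as generated, epoch switch times and the policy of each epoch.
#' With the seed fixed the session is reproducible bit for bit.
#'
#' @param recipe A [session_recipe()].
#' @param seed Optional integer seed.
#' @return Object of class `synthetic_session`: list with `seq`
#'   (`node_sequence`), `maze`, `rewards` (times), `truth` (list:
#'   `segments` data.frame `bout`, `mode`, `start_time`, `end_time`;
#'   `switch_times`; `epochs`), `recipe`, `seed`.
#' @export
generate_session <- function(recipe, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maze <- build_maze(recipe$maze_config)
  L <- recipe$maze_config$n_junction_levels
  water <- recipe$maze_config$water_port_leaf
  dt <- recipe$step_dt

  node <- integer(0); time <- numeric(0); loc <- character(0)
  gt <- list(); rewards <- numeric(0)
  last_reward <- -Inf
  t <- 0; bout_i <- 0L

  add_rows <- function(nn, tt, ll) {
    node <<- c(node, nn); time <<- c(time, tt); loc <<- c(loc, ll)
  }
  add_gt <- function(mode, t0, t1) {
    gt[[length(gt) + 1L]] <<- data.frame(bout = bout_i, mode = mode,
                                         start_time = t0, end_time = t1)
  }

  # session starts in the cage
  add_rows(NA_integer_, 0, "cage")
  t <- .draw_cage_duration(recipe)

  while (t < recipe$duration) {
    bout_i <- bout_i + 1L
    D <- stats::rexp(1, recipe$exit_rate)       # constant exit hazard
    bout_end <- t + D
    cur <- 0L
    add_rows(0L, t, "maze")
    ep <- .epoch_at(recipe, t)
    activity <- if (recipe$rewarded && stats::runif(1) < ep$p_drink_start)
      "drink" else "explore"

    repeat {
      ep <- .epoch_at(recipe, t)
      if (activity == "drink") {
        t0 <- t
        if (cur != water) {
          p <- .tree_path(cur, water)
          steps <- p[-1L]
          add_rows(steps, t + dt * seq_along(steps), rep("maze", length(steps)))
          t <- t + dt * length(steps)
          cur <- water
        }
        if (t - last_reward >= recipe$reward_timeout) {
          rewards <- c(rewards, t); last_reward <- t
        }
        t <- t + recipe$drink_dwell
        add_gt("drink", t0, t)
        # the post-drink choice is a pure Bernoulli draw; the exit hazard
        # acts on explore time only (animals rarely abort an approach run)
        activity <- if (stats::runif(1) > recipe$p_explore_after_drink)
          "leave" else "explore"
      } else if (activity == "explore") {
        t0 <- t
        pds <- if (recipe$rewarded) ep$p_drink_step else 0
        m <- if (pds > 0) stats::rgeom(1, pds) + 1L else Inf
        steps_left <- max(ceiling((bout_end - t) / dt), 0L)
        n_sim <- min(m, steps_left)
        if (n_sim >= 1L) {
          pol <- ep$policy
          v <- if (identical(pol, "unbiased")) {
            walk_sim_cpp(n_sim, L, cur, 0, 0, 0, 0, TRUE)
          } else {
            walk_sim_cpp(n_sim, L, cur, pol$PSF, pol$PSA, pol$PBF, pol$PBS,
                         FALSE)
          }
          steps <- v[-1L]
          add_rows(steps, t + dt * seq_along(steps), rep("maze", length(steps)))
          t <- t + dt * length(steps)
          cur <- steps[length(steps)]
          add_gt("explore", t0, t)
        }
        activity <- if (t >= bout_end || steps_left < 1L) "leave"
                    else "drink"
      } else {                                  # leave
        t0 <- t
        if (cur != 0L) {
          p <- .tree_path(cur, 0L)
          steps <- p[-1L]
          add_rows(steps, t + dt * seq_along(steps), rep("maze", length(steps)))
          t <- t + dt * length(steps)
          cur <- 0L
        }
        t <- t + dt                             # crossing into the tunnel
        add_gt("leave", t0, t)
        break
      }
    }
    add_rows(NA_integer_, t, "cage")
    t <- t + .draw_cage_duration(recipe)
  }

  seq <- node_sequence(node, time, loc, maze = maze)
  truth <- list(
    segments = if (length(gt)) do.call(rbind, gt) else NULL,
    switch_times = vapply(recipe$epochs, function(e) e$start, numeric(1)),
    epochs = recipe$epochs)
  structure(list(seq = seq, maze = maze, rewards = rewards, truth = truth,
                 recipe = recipe, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  b <- segment_bouts(x$seq)
  cat(sprintf("synthetic_session: %.1f h, %d bouts, %d node events, %d rewards\n",
              max(x$seq$time) / 3600, nrow(b), sum(x$seq$location == "maze"),
              length(x$rewards)))
  invisible(x)
}

#' Render a node sequence as a continuous nose track
#'
#' Produces a keypoint track through the corridor cell centres: frames at
#' the given rate interpolate linearly between consecutive node-cell
#' centres, with optional gaussian positional jitter. Cage residencies are
#' rendered at a fixed cage anchor outside the maze. At the default jitter
#' the track round-trips through [to_node_sequence()] to exactly the
#' original maze node sequence.
#'
#' @param session A `synthetic_session`, `sim_session` or `node_sequence`.
#' @param maze A `maze_graph` (taken from the session when available).
#' @param frame_rate Frames per second (default 30).
#' @param jitter SD of gaussian positional noise in cell widths (default 0).
#' @param seed Optional seed for the jitter.
#' @return A data.frame of class `keypoint_track` with columns `time`, `x`,
#'   `y`, and attribute `frame_rate`.
#' @export
render_track <- function(session, maze = NULL, frame_rate = 30,
                         jitter = 0, seed = NULL) {
  if (inherits(session, "synthetic_session")) {
    if (is.null(maze)) maze <- session$maze
    seq <- session$seq
  } else if (inherits(session, "sim_session")) {
    seq <- session$seq
  } else seq <- session
  if (is.null(maze)) stop("maze required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  half <- max(abs(maze$coords)) + 0.5
  cage_pt <- c(0, -(half + 3.5))
  n <- nrow(seq)
  pos <- matrix(NA_real_, n, 2)
  mz <- seq$location == "maze"
  pos[mz, ] <- maze$coords[seq$node[mz] + 1L, , drop = FALSE]
  pos[!mz, 1L] <- cage_pt[1L]; pos[!mz, 2L] <- cage_pt[2L]

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- seq$time[i]
    t1 <- if (i < n) seq$time[i + 1L] else seq$time[i] + 1
    if (t1 <= t0) next
    tt <- seq(t0, t1 - 1e-9, by = 1 / frame_rate)
    if (!length(tt)) next
    if (i < n) {
      # dwell at the current position, then transit over the final stretch
      transit <- min(0.5 * (t1 - t0), 1.5)
      u <- pmax(0, (tt - (t1 - transit)) / transit)
      xx <- pos[i, 1L] + u * (pos[i + 1L, 1L] - pos[i, 1L])
      yy <- pos[i, 2L] + u * (pos[i + 1L, 2L] - pos[i, 2L])
    } else {
      xx <- rep(pos[i, 1L], length(tt)); yy <- rep(pos[i, 2L], length(tt))
    }
    frames[[i]] <- data.frame(time = tt, x = xx, y = yy)
  }
  tr <- do.call(rbind, frames[!vapply(frames, is.null, logical(1))])
  if (jitter > 0) {
    tr$x <- tr$x + stats::rnorm(nrow(tr), 0, jitter)
    tr$y <- tr$y + stats::rnorm(nrow(tr), 0, jitter)
  }
  class(tr) <- c("keypoint_track", "data.frame")
  attr(tr, "frame_rate") <- frame_rate
  tr
}

#' Write / read keypoint tracks as delimited text
#'
#' Tab-separated with header `time_s`, `x`, `y`, one row per frame.
#'
#' @param track A `keypoint_track`.
#' @param path File path.
#' @return `read_track` returns a `keypoint_track`.
#' @export
write_track <- function(track, path) {
  utils::write.table(data.frame(time_s = track$time, x = track$x, y = track$y),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  tr <- data.frame(time = df$time_s, x = df$x, y = df$y)
  class(tr) <- c("keypoint_track", "data.frame")
  tr
}
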