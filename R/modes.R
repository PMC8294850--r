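#' Segment maze time into drink / leave / explore modes
#'
#' Three behavioural modes partition the time in the maze: `drink` is the
#' maximal reversal-free run terminating at the water port plus the dwell at
#' the port until the first step away; `leave` is the terminal home run of
#' the bout (direct path to the exit); `explore` is everything else. For
#' unrewarded sessions (no water leaf) only leave/explore are assigned.
#'
#' @param seq A `node_sequence`.
#' @param maze A `maze_graph`.
#' @param water_leaf End node with the water port; `NULL` for unrewarded
#'   sessions. Defaults to the maze config value.
#' @param rewarded Logical; set `FALSE` to force the unrewarded definition.
#' @return A data.frame of class `mode_segments` with columns `bout`, `mode`,
#'   `start_time`, `end_time`; segments tile each bout. The per-row mode of
#'   the underlying sequence is attached as attribute `"row_mode"`.
#' @export
segment_modes <- function(seq, maze, water_leaf = maze$config$water_port_leaf,
                          rewarded = !is.null(water_leaf)) {
  if (rewarded && is.null(water_leaf))
    stop("water_leaf must be set for rewarded analysis", call. = FALSE)
  bouts <- segment_bouts(seq)
  row_mode <- rep(NA_character_, nrow(seq))
  segs <- list()
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start[b]:bouts$end[b]
    nodes <- seq$node[idx]
    k <- length(nodes)
    mode <- rep("explore", k)
    piv <- which(reversal_pivots(nodes))
    if (nodes[k] == 0L) {                        # terminal home run
      jL <- if (length(piv)) max(piv) else 1L
      mode[jL:k] <- "leave"
    }
    if (rewarded) {
      for (w in which(nodes == water_leaf)) {
        lastpiv <- piv[piv < w]
        j <- if (length(lastpiv)) max(lastpiv) else 1L
        mode[j:w] <- "drink"
      }
    }
    row_mode[idx] <- mode
    # interval i runs from arrival at node i to arrival at node i+1 (or exit)
    t0 <- seq$time[idx]
    t1 <- c(seq$time[idx][-1L], bouts$exit_time[b])
    r <- rle(mode)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    segs[[b]] <- data.frame(bout = b, mode = r$values,
                            start_time = t0[s], end_time = t1[e])
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(bout = integer(0), mode = character(0),
               start_time = numeric(0), end_time = numeric(0))
  class(out) <- c("mode_segments", "data.frame")
  attr(out, "row_mode") <- row_mode
  out
}

#' Contiguous explore-mode clips of a node sequence
#'
#' Row-index ranges of maximal contiguous explore-labelled runs, the unit on
#' which discovery curves and decision models operate (windows and histories
#' never span clip boundaries).
#'
#' @inheritParams segment_modes
#' @param segments Optional precomputed [segment_modes()] result.
#' @return List of integer row-index vectors.
#' @export
explore_clips <- function(seq, maze, water_leaf = maze$config$water_port_leaf,
                          rewarded = !is.null(water_leaf), segments = NULL) {
  if (is.null(segments))
    segments <- segment_modes(seq, maze, water_leaf, rewarded)
  rm <- attr(segments, "row_mode")
  is_ex <- !is.na(rm) & rm == "explore"
  if (!any(is_ex)) return(list())
  r <- rle(is_ex)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  Map(function(s, e) s:e, starts[r$values], ends[r$values])
}

#' Ethogram: mode occupancies and transition probabilities
#'
#' Time fraction spent in each mode and the first-order transition matrix
#' between modes. Transitions out of `leave` are read from the first mode of
#' the next bout (what the animal does when it re-enters the maze).
#'
#' @param segments A [segment_modes()] result.
#' @return List with `occupancy` (named fractions), `transitions` (row-
#'   stochastic matrix) and `counts` (raw transition counts).
#' @export
ethogram <- function(segments) {
  if (!nrow(segments)) stop("no segments", call. = FALSE)
  modes <- c("drink", "explore", "leave")
  dur <- segments$end_time - segments$start_time
  occ <- vapply(modes, function(m) sum(dur[segments$mode == m]), numeric(1))
  occ <- occ / sum(occ)
  counts <- matrix(0, 3, 3, dimnames = list(modes, modes))
  sq <- segments$mode
  bt <- segments$bout
  for (i in seq_len(length(sq) - 1L)) {
    a <- sq[i]; b <- sq[i + 1L]
    # consecutive within a bout, or leave -> start of next bout
    if (bt[i + 1L] == bt[i] || a == "leave")
      counts[a, b] <- counts[a, b] + 1
  }
  rs <- rowSums(counts)
  trans <- counts / ifelse(rs > 0, rs, 1)
  # a mode never left keeps all its mass on itself
  for (m in modes) if (rs[m] == 0 && occ[m] > 0) trans[m, m] <- 1
  list(occupancy = occ, transitions = trans, counts = counts)
}

#' Mode occupancy as a function of absolute time
#'
#' Fraction of in-maze time spent in each mode per time bin.
#'
#' @param segments A [segment_modes()] result.
#' @param bin_width Bin width in seconds.
#' @return A data.frame `t_mid`, `drink`, `explore`, `leave`, `in_maze_s`;
#'   fractions per bin sum to 1 where `in_maze_s > 0`.
#' @export
mode_timecourse <- function(segments, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (!nrow(segments))
    return(data.frame(t_mid = numeric(0), drink = numeric(0),
                      explore = numeric(0), leave = numeric(0),
                      in_maze_s = numeric(0)))
  t0 <- min(segments$start_time); t1 <- max(segments$end_time)
  breaks <- seq(t0, t1 + bin_width, by = bin_width)
  nb <- length(breaks) - 1L
  acc <- matrix(0, nb, 3, dimnames = list(NULL, c("drink", "explore", "leave")))
  for (i in seq_len(nrow(segments))) {
    lo <- segments$start_time[i]; hi <- segments$end_time[i]
    m <- segments$mode[i]
    for (bidx in seq_len(nb)) {
      ov <- min(hi, breaks[bidx + 1L]) - max(lo, breaks[bidx])
      if (ov > 0) acc[bidx, m] <- acc[bidx, m] + ov
    }
  }
  tot <- rowSums(acc)
  frac <- acc / ifelse(tot > 0, tot, 1)
  data.frame(t_mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
             drink = frac[, "drink"], explore = frac[, "explore"],
             leave = frac[, "leave"], in_maze_s = tot)
}

#' Export mode segments and ethograms
#'
#' Mode segments are written as tab-separated text (`bout`, `mode`, `t0`,
#' `t1`); the ethogram as JSON (occupancies, transition matrix, counts).
#'
#' @param segments A [segment_modes()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mode_segments <- function(segments, path) {
  df <- data.frame(bout = segments$bout, mode = segments$mode,
                   t0 = segments$start_time, t1 = segments$end_time)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mode_segments
#' @param eth An [ethogram()] result.
#' @export
ethogram_to_json <- function(eth, path = NULL) {
  js <- jsonlite::toJSON(list(occupancy = as.list(eth$occupancy),
                              transitions = eth$transitions,
                              counts = eth$counts),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
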