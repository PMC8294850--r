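#' End-node visit sequences of the explore mode
#'
#' Extracts, clip by clip, the ordered end nodes visited during explore mode
#' (or over the whole maze time when `mode_filter = FALSE`).
#'
#' @param seq A `node_sequence`.
#' @param maze A `maze_graph`.
#' @param mode_filter Restrict to explore-mode clips (default TRUE).
#' @param water_leaf,rewarded Passed to [segment_modes()].
#' @param visit_rule `"two_step"` (default) or `"first_entry"`; see
#'   [leaf_visit_sequence()].
#' @return List of integer vectors of end-node ids, one per clip.
#' @export
endnode_visits <- function(seq, maze, mode_filter = TRUE,
                           water_leaf = maze$config$water_port_leaf,
                           rewarded = !is.null(water_leaf),
                           visit_rule = c("two_step", "first_entry")) {
  visit_rule <- match.arg(visit_rule)
  clips <- if (mode_filter) {
    explore_clips(seq, maze, water_leaf, rewarded)
  } else {
    b <- segment_bouts(seq)
    Map(function(s, e) s:e, b$start, b$end)
  }
  out <- lapply(clips, function(idx)
    leaf_visit_sequence(seq$node[idx], maze, visit_rule))
  out[vapply(out, length, integer(1)) > 0L]
}

#' End-node visit sequence of a node run
#'
#' Extracts the ordered end nodes along a contiguous node path. Under the
#' `"two_step"` rule (the default), an arrival at an end node does not count
#' as a new visit when it is an immediate re-entry by reversal at the parent
#' junction: the animal must move at least two steps away from the end node
#' before another visit qualifies, which avoids counting rapid flickers
#' between two adjacent nodes. `"first_entry"` counts every arrival.
#'
#' @param nodes Integer vector of consecutive node ids (one contiguous run).
#' @param maze A `maze_graph`.
#' @param rule `"two_step"` or `"first_entry"`.
#' @return Integer vector of end-node ids.
#' @export
leaf_visit_sequence <- function(nodes, maze,
                                rule = c("two_step", "first_entry")) {
  rule <- match.arg(rule)
  is_leaf <- maze$node_kind[nodes + 1L] == "end_node"
  if (rule == "two_step" && length(nodes) >= 3L) {
    n <- length(nodes)
    flicker <- c(FALSE, FALSE, nodes[3:n] == nodes[1:(n - 2L)])
    is_leaf <- is_leaf & !flicker
  }
  nodes[is_leaf]
}

# distance of each visit to the previous occurrence of the same end node
# (position index if none); computed once per clip
.first_gaps <- function(e) {
  idx <- seq_along(e)
  prev <- stats::ave(idx, e, FUN = function(ix) c(0L, ix[-length(ix)]))
  idx - prev                     # gap = idx when no earlier occurrence
}

# mean distinct count over all windows of size n, pooled over clips, via
# the first-occurrence-gap identity (exact, O(N) per n)
.window_distinct <- function(gaps, n) {
  tot <- 0; nw <- 0
  for (gap in gaps) {
    N <- length(gap)
    if (N < n) next
    idx <- seq_len(N)
    lo <- pmax(idx - n + 1L, idx - gap + 1L)
    lo[lo < 1L] <- 1L
    hi <- pmin(idx, N - n + 1L)
    tot <- tot + sum(pmax(0L, hi - lo + 1L))
    nw <- nw + (N - n + 1L)
  }
  c(sum = tot, windows = nw)
}

#' Discovery curve: distinct end nodes per visit window
#'
#' Slides a window of n end-node visits across the explore-mode visit
#' sequence and averages the number of distinct end nodes per window, pooling
#' all windows of all clips with equal weight. Windows never span clip
#' boundaries.
#'
#' @param x A `node_sequence`, a list of end-node visit vectors, or a single
#'   integer vector of end-node visits.
#' @param maze A `maze_graph` (required when `x` is a `node_sequence`).
#' @param ns Window sizes; default `1:min(longest clip, 512)`.
#' @param ... Passed to [endnode_visits()] when `x` is a `node_sequence`.
#' @return A data.frame of class `discovery_curve` with columns `n`, `d`
#'   (mean distinct count) and `windows` (number of windows contributing),
#'   plus attribute `n_leaves`.
#' @export
discovery_curve <- function(x, maze = NULL, ns = NULL, ...) {
  clips <- if (inherits(x, "node_sequence")) {
    if (is.null(maze)) stop("maze required for a node_sequence", call. = FALSE)
    endnode_visits(x, maze, ...)
  } else if (is.list(x)) x else list(as.integer(x))
  clips <- clips[vapply(clips, length, integer(1)) > 0L]
  n_leaves <- if (!is.null(maze)) sum(maze$node_kind == "end_node") else 64L
  if (!length(clips)) {
    out <- data.frame(n = integer(0), d = numeric(0), windows = integer(0))
    class(out) <- c("discovery_curve", "data.frame")
    attr(out, "n_leaves") <- n_leaves
    return(out)
  }
  maxlen <- max(vapply(clips, length, integer(1)))
  if (is.null(ns)) ns <- seq_len(min(maxlen, 512L))
  gaps <- lapply(clips, .first_gaps)
  res <- vapply(ns, function(n) .window_distinct(gaps, n), numeric(2))
  out <- data.frame(n = ns, d = res["sum", ] / pmax(res["windows", ], 1),
                    windows = res["windows", ])
  out$d[res["windows", ] == 0] <- NA_real_
  class(out) <- c("discovery_curve", "data.frame")
  attr(out, "n_leaves") <- n_leaves
  out
}

#' Exploration efficiency from the half-coverage crossing
#'
#' E = 32/N32, where N32 is the mean number of end-node visits needed to
#' encounter half (32) of the end nodes, obtained by linear interpolation of
#' the discovery curve at its crossing of 32.
#'
#' @param curve A [discovery_curve()].
#' @param target Half-coverage target (default: half the end nodes).
#' @return List of class `efficiency` with `E`, `N32`, `target`, `reached`.
#'   If the curve never reaches the target, `E` and `N32` are `NA` and
#'   `reached` is `FALSE`.
#' @export
n32_efficiency <- function(curve, target = NULL) {
  n_leaves <- attr(curve, "n_leaves"); if (is.null(n_leaves)) n_leaves <- 64L
  if (is.null(target)) target <- n_leaves / 2
  ok <- !is.na(curve$d)
  n <- curve$n[ok]; d <- curve$d[ok]
  hit <- which(d >= target)
  if (!length(hit)) {
    out <- list(E = NA_real_, N32 = NA_real_, target = target,
                reached = FALSE)
    class(out) <- "efficiency"
    return(out)
  }
  k <- hit[1L]
  N32 <- if (k == 1L || d[k] == target) {
    n[k]
  } else {
    n[k - 1L] + (target - d[k - 1L]) / (d[k] - d[k - 1L]) * (n[k] - n[k - 1L])
  }
  out <- list(E = target / N32, N32 = N32, target = target, reached = TRUE)
  class(out) <- "efficiency"
  out
}

#' @export
print.efficiency <- function(x, ...) {
  if (x$reached)
    cat(sprintf("exploration efficiency E = %.3f (N%g = %.1f visits)\n",
                x$E, x$target, x$N32))
  else
    cat(sprintf("efficiency undefined: curve never reaches %g distinct end nodes\n",
                x$target))
  invisible(x)
}

#' Parametric fit of the discovery curve
#'
#' Least-squares fit of d(n) = 64 (1 - (1+b) / (1 + z + b z^3)), z = n/a.
#' The parameter a is (approximately) the number of visits needed to survey
#' half the end nodes, and b captures a late acceleration in discovering the
#' last few end nodes; the quoted efficiency is E = 32/a.
#'
#' @param curve A [discovery_curve()].
#' @param start Optional named start values `a`, `b`.
#' @return List of class `efficiency_fit` with `a`, `b`, `E`, `rss`,
#'   `converged` and the underlying `nls` fit. On non-convergence, returns
#'   `converged = FALSE` with diagnostics instead of failing.
#' @export
fit_discovery <- function(curve, start = NULL) {
  n_leaves <- attr(curve, "n_leaves"); if (is.null(n_leaves)) n_leaves <- 64L
  ok <- !is.na(curve$d)
  df <- data.frame(n = curve$n[ok], d = curve$d[ok])
  if (nrow(df) < 4L) stop("curve too short to fit", call. = FALSE)
  if (is.null(start)) {
    eff <- n32_efficiency(curve)
    a0 <- if (eff$reached) eff$N32 else max(df$n)
    start <- list(a = a0, b = 0.1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      d ~ n_leaves * (1 - (1 + b) / (1 + n / a + b * (n / a)^3)),
      data = df, start = start,
      lower = c(a = 1e-6, b = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(a = NA_real_, b = NA_real_, E = NA_real_, rss = NA_real_,
                converged = FALSE, message = conditionMessage(fit), fit = NULL)
  } else {
    cf <- stats::coef(fit)
    out <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                E = (n_leaves / 2) / unname(cf["a"]),
                rss = sum(stats::resid(fit)^2),
                converged = TRUE, message = NULL, fit = fit)
  }
  class(out) <- "efficiency_fit"
  out
}

#' Split-half exploration efficiency
#'
#' Splits the session at the midpoint of cumulative in-maze time and computes
#' the efficiency separately in each half; their ratio measures the decline
#' of exploration over the session.
#'
#' @param seq A `node_sequence`.
#' @param maze A `maze_graph`.
#' @param ns Window sizes passed to [discovery_curve()].
#' @param ... Passed to [endnode_visits()].
#' @return List with `E1`, `E2`, `ratio` (`E2/E1`) and the per-half
#'   [n32_efficiency()] results; halves with insufficient coverage yield `NA`
#'   with `reached = FALSE` in the corresponding element.
#' @export
split_half_efficiency <- function(seq, maze, ns = NULL, ...) {
  bouts <- segment_bouts(seq)
  if (!nrow(bouts)) stop("no maze time in sequence", call. = FALSE)
  tot <- sum(bouts$exit_time - bouts$entry_time)
  # absolute time at which cumulative in-maze time reaches tot/2
  acc <- 0; t_split <- bouts$exit_time[nrow(bouts)]
  for (b in seq_len(nrow(bouts))) {
    d <- bouts$exit_time[b] - bouts$entry_time[b]
    if (acc + d >= tot / 2) { t_split <- bouts$entry_time[b] + (tot / 2 - acc); break }
    acc <- acc + d
  }
  halves <- list(seq[seq$time <= t_split, ], seq[seq$time > t_split, ])
  effs <- lapply(halves, function(h) {
    class(h) <- c("node_sequence", "data.frame")
    if (!any(h$location == "maze")) {
      return(structure(list(E = NA_real_, N32 = NA_real_, target = NA_real_,
                            reached = FALSE), class = "efficiency"))
    }
    n32_efficiency(discovery_curve(h, maze, ns = ns, ...))
  })
  list(E1 = effs[[1L]]$E, E2 = effs[[2L]]$E,
       ratio = effs[[2L]]$E / effs[[1L]]$E,
       first = effs[[1L]], second = effs[[2L]])
}

#' End-node occupancy distribution
#'
#' Fraction of end-node visits falling on each of the 64 leaves (first
#' entries; an immediate re-entry without visiting another node is already
#' collapsed in the node sequence).
#'
#' @param seq A `node_sequence` (or list of end-node visit vectors).
#' @param maze A `maze_graph`.
#' @param mode_filter Restrict to explore mode (default FALSE: all visits).
#' @param ... Passed to [endnode_visits()].
#' @return Named numeric vector of visit fractions over all leaves.
#' @export
endnode_occupancy <- function(seq, maze, mode_filter = FALSE, ...) {
  visits <- if (inherits(seq, "node_sequence")) {
    unlist(endnode_visits(seq, maze, mode_filter = mode_filter, ...))
  } else unlist(seq)
  leaves <- maze_leaves(maze)
  cnt <- table(factor(visits, levels = leaves))
  if (sum(cnt) == 0) stop("no end-node visits", call. = FALSE)
  prop <- as.numeric(cnt) / sum(cnt)
  stats::setNames(prop, leaves)
}

#' Outer/inner end-node preference ratio
#'
#' Mean visit fraction over the outer ring (excluding the water port and its
#' sibling neighbour) divided by the mean over the inner ring.
#'
#' @param occupancy Named fractions from [endnode_occupancy()].
#' @param maze A `maze_graph`.
#' @return Numeric ratio.
#' @export
outer_inner_ratio <- function(occupancy, maze) {
  rings <- classify_rings(maze)
  wl <- maze$config$water_port_leaf
  sib <- if (wl %% 2L == 1L) wl + 1L else wl - 1L
  outer <- as.integer(names(rings)[rings == "outer"])
  outer <- setdiff(outer, c(wl, sib))
  inner <- as.integer(names(rings)[rings == "inner"])
  mo <- mean(occupancy[as.character(outer)])
  mi <- mean(occupancy[as.character(inner)])
  if (mi == 0) stop("no visits to inner end nodes", call. = FALSE)
  mo / mi
}

#' Variance in end-node preference explained by a model
#'
#' R-squared between an observed and a predicted visit distribution:
#' 1 - SS_res / SS_tot.
#'
#' @param observed,predicted Numeric vectors of matching length.
#' @return Fraction of variance explained.
#' @export
variance_explained <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch", call. = FALSE)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else NA_real_)
  1 - ss_res / ss_tot
}
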