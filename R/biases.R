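#' Encode maze steps as turning actions
#'
#' Every link between nodes is a left or a right branch relative to its
#' parent T-junction, so each step is one of four actions:
#' 0 "in left", 1 "in right" (descending a left/right branch),
#' 2 "out left", 3 "out right" (ascending one).
#'
#' @param nodes Integer vector of consecutive, graph-adjacent node ids (one
#'   contiguous maze run), or a `node_sequence` (steps are then taken within
#'   bouts only).
#' @param maze A `maze_graph`.
#' @return For a vector input, an integer action vector of length
#'   `length(nodes) - 1`; for a `node_sequence`, a data.frame `from`, `to`,
#'   `action`, `time` over all within-bout steps.
#' @export
encode_actions <- function(nodes, maze) {
  if (inherits(nodes, "node_sequence")) {
    seq <- nodes
    bouts <- segment_bouts(seq)
    out <- list()
    for (b in seq_len(nrow(bouts))) {
      idx <- bouts$start[b]:bouts$end[b]
      if (length(idx) < 2L) next
      v <- seq$node[idx]
      out[[length(out) + 1L]] <- data.frame(
        from = v[-length(v)], to = v[-1L],
        action = .step_actions(v),
        time = seq$time[idx][-1L])
    }
    return(if (length(out)) do.call(rbind, out) else
      data.frame(from = integer(0), to = integer(0), action = integer(0),
                 time = numeric(0)))
  }
  .step_actions(as.integer(nodes))
}

.step_actions <- function(v) {
  a <- v[-length(v)]; b <- v[-1L]
  down <- (b - 1L) %/% 2L == a & b > 0L
  up <- (a - 1L) %/% 2L == b & a > 0L
  if (!all(down | up)) stop("non-adjacent step", call. = FALSE)
  # geometric branch label of the traversed link
  g <- ifelse(down, .edge_gsign(a, b), .edge_gsign(b, a))
  ifelse(down, ifelse(g < 0L, 0L, 1L),
               ifelse(g < 0L, 2L, 3L))
}

#' Estimate the four turning biases at T-junctions
#'
#' Tallies consecutive action pairs (a0, a1) at junction passages, pooled
#' over junctions, and forms the conditional probabilities p(a1|a0). The four
#' biases are then: PSF, the probability of moving forward (vs reversing)
#' when arriving from the stem; PSA, the probability of an alternating turn
#' given forward from the stem; PBF, forward (vs reversing) when arriving
#' along the bar; and PBS, branching into the stem given forward along the
#' bar. An unbiased three-way walk gives (2/3, 1/2, 2/3, 1/2).
#'
#' Only explore-mode passages enter the tallies by default, and pairs never
#' span clip or bout boundaries. The central junction is excluded by default:
#' for maze-confined trajectories it has no stem corridor, so its passages
#' are not comparable to the other junctions (set `include_root = TRUE` for
#' data in which the entrance step supplies the stem arrival).
#'
#' @param seq A `node_sequence`, or a list of contiguous node-run vectors.
#' @param maze A `maze_graph`.
#' @param explore_only Restrict to explore mode (default TRUE; requires a
#'   `node_sequence`).
#' @param include_root Include central-junction passages (default FALSE).
#' @param ... Passed to [segment_modes()] (e.g. `water_leaf`, `rewarded`).
#' @return Object of class `bias_set`: list with `PSF`, `PSA`, `PBF`, `PBS`,
#'   the 4x4 `conditional` table p(a1|a0), raw `counts`, and `n_pairs`.
#'   A bias whose denominator is empty is `NA`.
#' @export
estimate_biases <- function(seq, maze, explore_only = TRUE,
                            include_root = FALSE, ...) {
  runs <- if (inherits(seq, "node_sequence")) {
    if (explore_only) {
      lapply(explore_clips(seq, maze, ...), function(idx) seq$node[idx])
    } else {
      b <- segment_bouts(seq)
      Map(function(s, e) seq$node[s:e], b$start, b$end)
    }
  } else if (is.list(seq)) seq else list(as.integer(seq))

  counts <- matrix(0, 4, 4, dimnames = list(a0 = 0:3, a1 = 0:3))
  for (v in runs) {
    if (length(v) < 3L) next
    acts <- .step_actions(v)
    mid <- 2:(length(v) - 1L)             # nodes with both an in- and out-step
    keep <- maze$node_kind[v[mid] + 1L] == "junction"
    if (!include_root) keep <- keep & v[mid] != 0L
    a0 <- acts[mid - 1L][keep]; a1 <- acts[mid][keep]
    if (length(a0))
      counts <- counts + table(factor(a0, 0:3), factor(a1, 0:3))
  }
  counts <- matrix(as.numeric(counts), 4L, 4L,
                   dimnames = list(a0 = 0:3, a1 = 0:3))
  rs <- rowSums(counts)
  cond <- counts / ifelse(rs > 0, rs, 1)
  cond[rs == 0, ] <- NA_real_
  p <- function(a1, a0) cond[a0 + 1L, a1 + 1L]

  stem_fwd <- p(0, 0) + p(0, 1) + p(1, 0) + p(1, 1)
  PSF <- stem_fwd / (stem_fwd + p(2, 0) + p(3, 1))
  PSA <- (p(0, 1) + p(1, 0)) / stem_fwd
  bar_fwd <- p(0, 3) + p(1, 2) + p(2, 2) + p(2, 3) + p(3, 2) + p(3, 3)
  PBF <- bar_fwd / (bar_fwd + p(0, 2) + p(1, 3))
  PBS <- (p(2, 2) + p(2, 3) + p(3, 2) + p(3, 3)) / bar_fwd

  out <- list(PSF = unname(PSF), PSA = unname(PSA),
              PBF = unname(PBF), PBS = unname(PBS),
              conditional = cond, counts = counts, n_pairs = sum(counts))
  class(out) <- "bias_set"
  out
}

#' @export
print.bias_set <- function(x, ...) {
  cat(sprintf("turning biases (from %.0f junction passages):\n", x$n_pairs))
  cat(sprintf("  PSF = %.3f  PSA = %.3f  PBF = %.3f  PBS = %.3f\n",
              x$PSF, x$PSA, x$PBF, x$PBS))
  invisible(x)
}

#' Construct a bias set for the agent simulators
#'
#' @param PSF,PSA,PBF,PBS Probabilities in `[0, 1]`.
#' @return Object of class `bias_set`.
#' @export
bias_set <- function(PSF, PSA, PBF, PBS) {
  p <- c(PSF = PSF, PSA = PSA, PBF = PBF, PBS = PBS)
  if (any(p < 0 | p > 1)) stop("biases must be in [0, 1]", call. = FALSE)
  structure(list(PSF = PSF, PSA = PSA, PBF = PBF, PBS = PBS,
                 conditional = NULL, counts = NULL, n_pairs = 0L),
            class = "bias_set")
}

#' Turning biases of an unbiased three-way random walk
#' @return A [bias_set()] at (2/3, 1/2, 2/3, 1/2).
#' @export
unbiased_bias_set <- function() bias_set(2/3, 1/2, 2/3, 1/2)

#' Serialize a bias report to JSON
#' @param biases A `bias_set`.
#' @param path Optional output path.
#' @return JSON string (invisibly if written).
#' @export
biases_to_json <- function(biases, path = NULL) {
  obj <- list(PSF = biases$PSF, PSA = biases$PSA, PBF = biases$PBF,
              PBS = biases$PBS,
              conditional = biases$conditional, counts = biases$counts,
              n_pairs = biases$n_pairs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
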