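#' Define an exploration agent policy
#'
#' @param kind One of `"unbiased"` (uniform over available neighbours),
#'   `"four_bias"` (turning-bias random walk), `"markov"` (samples from a
#'   fitted [fit_markov()] model) or `"optimal"` (systematic depth-first
#'   traversal visiting every end node exactly once per sweep).
#' @param biases A [bias_set()] (required for `"four_bias"`).
#' @param model A `markov_model` (required for `"markov"`).
#' @return Object of class `agent_policy`.
#' @export
agent_policy <- function(kind = c("unbiased", "four_bias", "markov", "optimal"),
                         biases = NULL, model = NULL) {
  kind <- match.arg(kind)
  if (kind == "four_bias" && !inherits(biases, "bias_set"))
    stop("four_bias policy needs a bias_set", call. = FALSE)
  if (kind == "markov" && !inherits(model, "markov_model"))
    stop("markov policy needs a fitted markov_model", call. = FALSE)
  structure(list(kind = kind, biases = biases, model = model),
            class = "agent_policy")
}

# depth-first Euler tour of the tree from node i (each edge walked twice)
.euler_tour <- function(maze, i = 0L) {
  L <- maze$config$n_junction_levels
  if (.level_of(i) == L) return(i)
  c(i, .euler_tour(maze, 2L * i + 1L), i, .euler_tour(maze, 2L * i + 2L), i)
}

#' Simulate an exploration agent on the maze
#'
#' Agents are confined to the maze. The four-bias walker reverses from the
#' stem with probability 1-PSF, alternates turns with probability PSA,
#' reverses along the bar with probability 1-PBF and branches into the stem
#' with probability PBS; end nodes force reversal; at the central junction
#' (which has no stem corridor for a confined walker) the stem-branch mass is
#' renormalised onto the two remaining moves. With the seed fixed the
#' simulation is reproducible bit for bit.
#'
#' @param policy An [agent_policy()].
#' @param maze A `maze_graph`.
#' @param n_steps Number of node-to-node steps (>= 1). For the optimal agent
#'   the default is one full sweep.
#' @param start Start node id (default: central junction).
#' @param step_dt Seconds per step used to time-stamp the sequence
#'   (default 1.5, the scale of a mouse's node-to-node transition).
#' @param seed Optional integer seed.
#' @return Object of class `sim_session`: list with `seq` (a
#'   `node_sequence`), `policy`, `seed`, `n_steps`.
#' @export
simulate_agent <- function(policy, maze, n_steps = NULL, start = 0L,
                           step_dt = 1.5, seed = NULL) {
  if (!inherits(policy, "agent_policy")) stop("need an agent_policy")
  if (!is.null(seed)) set.seed(seed)
  L <- maze$config$n_junction_levels
  start <- .check_ids(maze, start)
  if (policy$kind == "optimal") {
    tour <- .euler_tour(maze)
    if (is.null(n_steps)) n_steps <- length(tour) - 1L
    nodes <- tour
    while (length(nodes) < n_steps + 1L) nodes <- c(nodes, tour[-1L])
    nodes <- nodes[1:(n_steps + 1L)]
  } else if (policy$kind %in% c("unbiased", "four_bias")) {
    if (is.null(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
    b <- if (policy$kind == "four_bias") policy$biases else
      list(PSF = 2/3, PSA = 1/2, PBF = 2/3, PBS = 1/2)
    nodes <- walk_sim_cpp(as.integer(n_steps), L, start,
                          b$PSF, b$PSA, b$PBF, b$PBS,
                          policy$kind == "unbiased")
  } else {                                   # markov
    if (is.null(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
    nodes <- .simulate_markov_agent(policy$model, maze, n_steps, start)
  }
  seq <- node_sequence(nodes, seq_along(nodes) * step_dt - step_dt)
  structure(list(seq = seq, policy = policy, seed = seed,
                 n_steps = as.integer(n_steps)),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("sim_session: %s agent, %d steps\n",
              x$policy$kind, x$n_steps))
  invisible(x)
}

#' End-node visits needed to cover the maze
#'
#' Number of end-node visits until every end node has been encountered at
#' least once (the optimal explorer needs exactly 64 in the 6-level maze).
#'
#' @param session A `sim_session` or `node_sequence`.
#' @param maze A `maze_graph`.
#' @return Integer visit count, or `NA` if coverage is never reached.
#' @export
coverage_visits <- function(session, maze) {
  seq <- if (inherits(session, "sim_session")) session$seq else session
  v <- seq$node[seq$location == "maze"]
  v <- v[maze$node_kind[v + 1L] == "end_node"]
  leaves <- maze_leaves(maze)
  seen <- !duplicated(v)
  k <- cumsum(seen)
  full <- which(k == length(leaves))
  if (!length(full)) return(NA_integer_)
  full[1L]
}

#' Exploration efficiency of a policy over replicate simulations
#'
#' Runs replicate simulations, computes the discovery curve of each and the
#' efficiency E = 32/N32, and reports their distribution.
#'
#' @param policy An [agent_policy()].
#' @param maze A `maze_graph`.
#' @param n_steps Steps per replicate (default 1e5; ignored for the optimal
#'   agent, which uses exactly one full sweep).
#' @param replicates Number of replicates (default 10).
#' @param seed Optional seed for the whole set.
#' @param ns Window sizes for the discovery curves (default 1:300, ample to
#'   bracket the half-coverage crossing of all policies).
#' @return List with `E` (per replicate), `mean`, `sd`, `N32` (per
#'   replicate).
#' @export
efficiency_of_policy <- function(policy, maze, n_steps = 1e5,
                                 replicates = 10L, seed = NULL,
                                 ns = 1:300) {
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  E <- N <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s <- simulate_agent(policy, maze,
                        n_steps = if (policy$kind == "optimal") NULL else n_steps)
    v <- leaf_visit_sequence(s$seq$node, maze)
    eff <- n32_efficiency(discovery_curve(v, maze, ns = ns))
    E[r] <- eff$E; N[r] <- eff$N32
  }
  list(E = E, mean = mean(E), sd = stats::sd(E), N32 = N)
}
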