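# shared fixtures, built in code
maze6 <- build_maze()
water6 <- maze6$config$water_port_leaf

# the four-bias parameter set used throughout the recovery tests
bias_ref <- bias_set(0.85, 0.55, 0.90, 0.60)
# stronger alternation, used where the centrifugal preference must show
bias_alt <- bias_set(0.85, 0.75, 0.90, 0.60)

walk <- function(policy, n_steps, seed = NULL, maze = maze6) {
  simulate_agent(policy, maze, n_steps = n_steps, seed = seed)
}

# independent breadth-first distances over the adjacency list (oracle for
# tree_distance, which uses heap arithmetic instead)
bfs_distances <- function(maze, from) {
  d <- rep(NA_integer_, maze$n_nodes)
  d[from + 1L] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (nb in maze$adjacency[[v + 1L]]) {
      if (is.na(d[nb + 1L])) { d[nb + 1L] <- d[v + 1L] + 1L; nxt <- c(nxt, nb) }
    }
    frontier <- nxt
  }
  d
}

# tiny hand-built node sequence: times 1 s apart, all in the maze
nseq <- function(nodes, dt = 1) {
  node_sequence(nodes, seq_along(nodes) * dt - dt)
}
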