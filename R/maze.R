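#' Maze configuration
#'
#' Describes a binary-tree labyrinth: a full binary tree of T-junctions with an
#' end node (leaf) at the tip of every terminal corridor. The physical maze is
#' laid out as an H-tree on a regular grid, with corridor lengths halving every
#' other level.
#'
#' @param n_junction_levels Number of T-junction levels (default 6, giving 63
#'   junctions and 64 end nodes).
#' @param water_port_leaf Node id (0-based) of the end node holding the water
#'   port. Default `NULL` picks the documented canonical choice: the outer-ring
#'   leaf adjacent to the all-right corner leaf (id 125 for 6 levels).
#' @param cell_pitch Physical grid spacing in inches (default 1.5).
#' @param embedding Geometric layout scheme; only `"htree"` is implemented.
#' @return An object of class `maze_config`.
#' @export
maze_config <- function(n_junction_levels = 6L, water_port_leaf = NULL,
                        cell_pitch = 1.5, embedding = "htree") {
  n_junction_levels <- as.integer(n_junction_levels)
  if (is.na(n_junction_levels) || n_junction_levels < 1L)
    stop("n_junction_levels must be an integer >= 1", call. = FALSE)
  embedding <- match.arg(embedding, "htree")
  if (is.null(water_port_leaf)) {
    # sibling of the all-right corner leaf: turns R,...,R,L
    water_port_leaf <- .turns_to_id(c(rep("R", n_junction_levels - 1L), "L"))
  }
  water_port_leaf <- as.integer(water_port_leaf)
  n_nodes <- 2L^(n_junction_levels + 1L) - 1L
  first_leaf <- 2L^n_junction_levels - 1L
  if (water_port_leaf < first_leaf || water_port_leaf >= n_nodes)
    stop("water_port_leaf must be a leaf node id (",
         first_leaf, "..", n_nodes - 1L, ")", call. = FALSE)
  structure(list(n_junction_levels = n_junction_levels,
                 water_port_leaf = water_port_leaf,
                 cell_pitch = cell_pitch,
                 embedding = embedding),
            class = "maze_config")
}

# heap arithmetic on 0-based node ids
.parent_id <- function(i) ifelse(i == 0L, NA_integer_, (i - 1L) %/% 2L)
.children_ids <- function(i) c(2L * i + 1L, 2L * i + 2L)
.level_of <- function(i) floor(log2(i + 1))

# heap-path helpers (left = odd child); used only for canonical ids
.turns_to_id <- function(turns) {
  i <- 0L
  for (tn in turns) i <- if (tn == "L") 2L * i + 1L else 2L * i + 2L
  i
}

# Geometric left/right label of the edge junction j -> child c, as seen by
# an animal arriving at j from its stem. In the H-tree the corridor axes
# alternate with depth, so the label combines the heap parities of j and c
# with an alternating handedness factor; the entrance corridor fixes the
# convention at the root. -1 = left branch, +1 = right branch.
.edge_gsign <- function(j, c) {
  sc <- ifelse(c %% 2L == 1L, -1L, 1L)
  sj <- ifelse(j == 0L, 1L, ifelse(j %% 2L == 1L, -1L, 1L))
  lev <- as.integer(.level_of(j))
  sg <- ifelse(lev %% 2L == 0L, -1L, 1L)
  sc * sj * sg
}

# geometric turn sequence (root -> leaf) of a node id, and its inverse
.id_to_gturns <- function(i) {
  path <- i
  while (i > 0L) { i <- (i - 1L) %/% 2L; path <- c(i, path) }
  g <- .edge_gsign(path[-length(path)], path[-1L])
  ifelse(g < 0L, "L", "R")
}

.gturns_to_id <- function(turns) {
  i <- 0L
  for (tn in turns) {
    g <- if (tn == "L") -1L else 1L
    left <- 2L * i + 1L
    i <- if (.edge_gsign(i, left) == g) left else left + 1L
  }
  i
}

#' Build the labyrinth graph
#'
#' Constructs the binary-tree maze with heap node numbering (root = 0 is the
#' central junction; children of junction i are 2i+1 and 2i+2; end nodes are
#' the last 2^L ids) and a deterministic H-tree embedding on the cell grid.
#' The entrance corridor is not a node: paths "from the entrance" start at the
#' central junction.
#'
#' @param config A [maze_config()] object (default: the 6-level maze).
#' @return An object of class `maze_graph` with components `config`,
#'   `n_nodes`, `node_ids` (0-based), `level`, `node_kind`
#'   (`"junction"`/`"end_node"`), `lr_type` (`"L"`, `"R"` or `"root"`),
#'   `adjacency` (list of neighbour id vectors), `coords` (n x 2 grid
#'   coordinates centred on the root) and `entry_node` (0).
#' @export
build_maze <- function(config = maze_config()) {
  if (!inherits(config, "maze_config")) stop("config must be a maze_config")
  L <- config$n_junction_levels
  n_nodes <- 2L^(L + 1L) - 1L
  ids <- 0L:(n_nodes - 1L)
  level <- as.integer(.level_of(ids))
  kind <- ifelse(level == L, "end_node", "junction")
  # left/right type of a node = geometric label of the branch that reaches
  # it from its parent junction
  lr <- ifelse(ids == 0L, "root",
               ifelse(.edge_gsign(.parent_id(ids), ids) < 0L, "L", "R"))

  adjacency <- vector("list", n_nodes)
  for (i in ids) {
    nb <- integer(0)
    if (i > 0L) nb <- .parent_id(i)
    if (level[i + 1L] < L) nb <- c(nb, .children_ids(i))
    adjacency[[i + 1L]] <- nb
  }

  # H-tree embedding: child k of a level-k junction is displaced from its
  # parent along alternating axes (x,y,x,y,...) by halving magnitudes.
  coords <- matrix(0, nrow = n_nodes, ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  for (i in ids[-1L]) {
    k <- level[i + 1L] - 1L               # branching level producing node i
    m <- 2^floor((L - 1L - k) / 2)
    sgn <- if (i %% 2L == 1L) -1 else 1   # left child to negative side
    d <- if (k %% 2L == 0L) c(m, 0) else c(0, m)
    coords[i + 1L, ] <- coords[.parent_id(i) + 1L, ] + sgn * d
  }

  structure(list(config = config, n_nodes = n_nodes, node_ids = ids,
                 level = level, node_kind = kind, lr_type = lr,
                 adjacency = adjacency, coords = coords, entry_node = 0L),
            class = "maze_graph")
}

#' @export
print.maze_graph <- function(x, ...) {
  cat(sprintf("maze_graph: %d-level binary tree, %d nodes (%d junctions, %d end nodes)\n",
              x$config$n_junction_levels, x$n_nodes,
              sum(x$node_kind == "junction"), sum(x$node_kind == "end_node")))
  cat(sprintf("  water port at end node %d\n", x$config$water_port_leaf))
  invisible(x)
}

.check_ids <- function(maze, i) {
  if (any(is.na(i)) || any(i < 0L) || any(i >= maze$n_nodes))
    stop("unknown node id", call. = FALSE)
  as.integer(i)
}

#' End nodes of a maze
#' @param maze A `maze_graph`.
#' @return Integer vector of leaf node ids.
#' @export
maze_leaves <- function(maze) maze$node_ids[maze$node_kind == "end_node"]

#' Is a node an end node?
#' @param maze A `maze_graph`.
#' @param i Node id(s).
#' @return Logical vector.
#' @export
is_end_node <- function(maze, i) {
  i <- .check_ids(maze, i)
  maze$node_kind[i + 1L] == "end_node"
}

#' Tree distance between two nodes
#'
#' Number of edges on the unique path between nodes `a` and `b`, computed as
#' level(a) + level(b) - 2 level(lca).
#'
#' @param maze A `maze_graph`.
#' @param a,b Node ids (vectors recycle).
#' @return Integer step counts.
#' @export
tree_distance <- function(maze, a, b) {
  a <- .check_ids(maze, a); b <- .check_ids(maze, b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (j in seq_len(n)) {
    x <- a[j]; y <- b[j]; d <- 0L
    while (x != y) {
      if (x > y) { x <- .parent_id(x) } else { y <- .parent_id(y) }
      d <- d + 1L
    }
    out[j] <- d
  }
  out
}

#' Turn sequence addressing an end node
#'
#' Each leaf is addressed by the ordered geometric left/right turns taken
#' from the central junction (as experienced by an animal walking in from
#' the stem of each T-junction); the empty sequence addresses the root.
#' Under this addressing, flipping the first turn while keeping the rest
#' lands on the end node diametrically across the maze (the 180-degree
#' rotation image), and flipping every turn reflects the maze about its
#' entrance axis.
#'
#' @param maze A `maze_graph`.
#' @param leaf An end-node id.
#' @return Character vector over `"L"`, `"R"`.
#' @export
leaf_turns <- function(maze, leaf) {
  leaf <- .check_ids(maze, leaf)
  if (!is_end_node(maze, leaf)) stop("node is not an end node", call. = FALSE)
  .id_to_gturns(leaf)
}

#' End node addressed by a turn sequence
#' @param maze A `maze_graph`.
#' @param turns Character vector over `"L"`, `"R"` of length
#'   `n_junction_levels`.
#' @return End-node id.
#' @export
turns_to_leaf <- function(maze, turns) {
  if (length(turns) != maze$config$n_junction_levels ||
      !all(turns %in% c("L", "R")))
    stop("turns must be L/R of length n_junction_levels", call. = FALSE)
  .gturns_to_id(turns)
}

#' Rotation image of an end node
#'
#' The end node reached by flipping the FIRST turn of the leaf's turn sequence
#' and keeping all later turns: the 180-degree rotation image of the leaf in
#' the H-tree layout. An animal navigating by a remembered turn sequence that
#' errs only at the first T-junction ends up here.
#'
#' @param maze A `maze_graph`.
#' @param leaf An end-node id.
#' @return End-node id of the image.
#' @export
image_node <- function(maze, leaf) {
  turns <- leaf_turns(maze, leaf)
  turns[1L] <- if (turns[1L] == "L") "R" else "L"
  .gturns_to_id(turns)
}

#' Symmetry-related control nodes of an end node
#'
#' The three end nodes obtained from the target's turn sequence under the
#' maze's symmetry operations: flip the first turn (rotation image), flip all
#' turns (mirror), or both. Together with the identity these form a group of
#' order 4 acting on leaves without fixed points.
#'
#' @param maze A `maze_graph`.
#' @param target An end-node id.
#' @return Integer vector of three distinct end-node ids, excluding `target`.
#' @export
control_nodes <- function(maze, target) {
  turns <- leaf_turns(maze, target)
  flip <- function(x) ifelse(x == "L", "R", "L")
  first_flip <- turns; first_flip[1L] <- flip(first_flip[1L])
  mirror <- flip(turns)
  both <- mirror; both[1L] <- flip(both[1L])
  sort(vapply(list(first_flip, mirror, both), .gturns_to_id, integer(1)))
}

#' Classify end nodes into concentric rings of the embedding
#'
#' End nodes of the H-tree layout fall on a regular grid of positions; the
#' outer ring is the bounding perimeter of that grid (28 leaves in the 6-level
#' maze: 26 plus the water port and its neighbour), the inner ring is the
#' central block (16 leaves), and the rest are middle.
#'
#' @param maze A `maze_graph`.
#' @return Named character vector (names = leaf ids) over
#'   `"outer"`, `"middle"`, `"inner"`.
#' @export
classify_rings <- function(maze) {
  leaves <- maze_leaves(maze)
  xy <- maze$coords[leaves + 1L, , drop = FALSE]
  xs <- sort(unique(xy[, 1])); ys <- sort(unique(xy[, 2]))
  nx <- length(xs); ny <- length(ys)
  rx <- match(xy[, 1], xs); ry <- match(xy[, 2], ys)
  ring <- pmin(rx - 1L, nx - rx, ry - 1L, ny - ry)
  inner_min <- floor(nx / 4)
  cls <- ifelse(ring == 0L, "outer",
                ifelse(ring >= inner_min, "inner", "middle"))
  stats::setNames(cls, leaves)
}

#' Serialize a maze to JSON
#'
#' Writes config, adjacency, levels and coordinates with stable key order.
#'
#' @param maze A `maze_graph`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
maze_to_json <- function(maze, path = NULL) {
  obj <- list(
    config = maze$config[c("n_junction_levels", "water_port_leaf",
                           "cell_pitch", "embedding")],
    entry_node = maze$entry_node,
    level = maze$level,
    node_kind = maze$node_kind,
    adjacency = maze$adjacency,
    coords = apply(maze$coords, 1, function(r) as.numeric(r), simplify = FALSE)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Read a maze from its JSON serialization
#' @param path File path written by [maze_to_json()].
#' @return A `maze_graph`.
#' @export
maze_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- maze_config(obj$config$n_junction_levels,
                     obj$config$water_port_leaf,
                     obj$config$cell_pitch,
                     obj$config$embedding)
  build_maze(cfg)
}

#' Decision-complexity of a navigation task, in bits
#'
#' A path through k successive three-way T-junction decisions has complexity
#' k log2(3) bits: 9.5 bits for the six-junction entrance-to-port path and
#' about 100 bits for correct turns at all 63 junctions of the 6-level maze.
#'
#' @param n_decisions Number of three-way decisions.
#' @return Bits of complexity.
#' @export
path_complexity_bits <- function(n_decisions) n_decisions * log2(3)

#' Prior uncertainty of a single T-junction decision, in bits
#' @return log2(3), about 1.585 bits.
#' @export
junction_entropy_bits <- function() log2(3)
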