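test_that("the 6-level maze has the right shape", {
  expect_equal(maze6$n_nodes, 127L)
  expect_equal(sum(maze6$node_kind == "junction"), 63L)
  expect_equal(sum(maze6$node_kind == "end_node"), 64L)
  expect_equal(maze6$entry_node, 0L)
  expect_equal(maze6$level[1L], 0L)
  expect_true(all(maze6$level[maze_leaves(maze6) + 1L] == 6L))
  # degree: root 2 (entrance corridor is not a node), junctions 3, leaves 1
  deg <- lengths(maze6$adjacency)
  expect_equal(deg[1L], 2L)
  expect_true(all(deg[maze6$node_kind == "junction"][-1L] == 3L))
  expect_true(all(deg[maze6$node_kind == "end_node"] == 1L))
  # tree: |E| = |V| - 1
  expect_equal(sum(deg) / 2, maze6$n_nodes - 1)
})

test_that("the smallest maze and invalid configs behave", {
  m1 <- build_maze(maze_config(1L))
  expect_equal(m1$n_nodes, 3L)
  expect_equal(sum(m1$node_kind == "junction"), 1L)
  expect_equal(sum(m1$node_kind == "end_node"), 2L)
  expect_error(maze_config(0L), "n_junction_levels")
  expect_error(maze_config(6L, water_port_leaf = 10L), "leaf")
})

test_that("heap indexing and tree distances agree with graph traversal", {
  # parent arithmetic
  for (i in c(1L, 2L, 17L, 62L, 126L))
    expect_true(i %in% maze6$adjacency[[((i - 1L) %/% 2L) + 1L]])
  # BFS oracle
  for (from in c(0L, 5L, water6)) {
    d <- bfs_distances(maze6, from)
    others <- c(0L, 13L, 63L, 90L, 126L)
    expect_equal(tree_distance(maze6, from, others), d[others + 1L])
  }
  expect_equal(tree_distance(maze6, 0L, water6), 6L)
  expect_equal(tree_distance(maze6, 44L, 44L), 0L)
  expect_error(tree_distance(maze6, 0L, 400L), "unknown node")
  # every leaf is exactly 6 steps from the root
  expect_true(all(tree_distance(maze6, 0L, maze_leaves(maze6)) == 6L))
  # metric identity via the lowest common ancestor
  set.seed(1)
  a <- sample(maze6$node_ids, 25L); b <- sample(maze6$node_ids, 25L)
  expect_equal(tree_distance(maze6, a, b),
               vapply(seq_along(a), function(j)
                 bfs_distances(maze6, a[j])[b[j] + 1L], integer(1)))
})

test_that("turn sequences address leaves bijectively", {
  leaves <- maze_leaves(maze6)
  turns <- lapply(leaves, leaf_turns, maze = maze6)
  expect_true(all(lengths(turns) == 6L))
  expect_equal(length(unique(vapply(turns, paste, collapse = "", ""))), 64L)
  for (l in leaves)
    expect_equal(turns_to_leaf(maze6, leaf_turns(maze6, l)), l)
  expect_error(leaf_turns(maze6, 0L), "end node")
})

test_that("the image node is the diametric 180-degree rotation image", {
  leaves <- maze_leaves(maze6)
  imgs <- vapply(leaves, image_node, integer(1), maze = maze6)
  # involution without fixed points
  expect_true(all(vapply(imgs, image_node, integer(1), maze = maze6) == leaves))
  expect_true(all(imgs != leaves))
  # geometric point reflection and the 12-step distance, for every leaf
  expect_true(all(maze6$coords[imgs + 1L, ] == -maze6$coords[leaves + 1L, ]))
  expect_true(all(tree_distance(maze6, leaves, imgs) == 12L))
  # flipping the first turn is the definition
  tw <- leaf_turns(maze6, water6)
  ti <- leaf_turns(maze6, image_node(maze6, water6))
  expect_equal(ti[1L], setdiff(c("L", "R"), tw[1L]))
  expect_equal(ti[-1L], tw[-1L])
  expect_error(image_node(maze6, 0L), "end node")
})

test_that("control nodes form the symmetry orbit of the target", {
  for (target in c(water6, 63L, 100L)) {
    cn <- control_nodes(maze6, target)
    expect_length(cn, 3L)
    expect_false(target %in% cn)
    expect_length(unique(cn), 3L)
    expect_true(image_node(maze6, target) %in% cn)
    # closure: the orbit of any control contains the target
    for (ctrl in cn)
      expect_true(target %in% control_nodes(maze6, ctrl))
  }
})

test_that("ring classification matches the published outer/inner counts", {
  rings <- classify_rings(maze6)
  expect_equal(unname(table(rings)["outer"]), 28L)   # 26 + port + neighbour
  expect_equal(unname(table(rings)["inner"]), 16L)
  expect_lte(sum(rings %in% c("outer", "inner")), 64L)
  expect_true(rings[as.character(water6)] == "outer")
  # invariant under the rotation map
  leaves <- maze_leaves(maze6)
  imgs <- vapply(leaves, image_node, integer(1), maze = maze6)
  expect_equal(unname(rings[as.character(imgs)]), unname(rings))
})

test_that("decision-complexity constants match the task structure", {
  expect_equal(junction_entropy_bits(), log2(3))
  expect_lt(abs(junction_entropy_bits() - 1.585), 5e-4)
  expect_lt(abs(path_complexity_bits(6) - 9.5), 0.05)
  expect_lt(abs(path_complexity_bits(63) - 100), 0.5)
})

test_that("maze JSON serialization round-trips", {
  path <- tempfile(fileext = ".json")
  maze_to_json(maze6, path)
  m2 <- maze_from_json(path)
  expect_equal(m2$n_nodes, maze6$n_nodes)
  expect_equal(m2$coords, maze6$coords)
  expect_equal(m2$config$water_port_leaf, water6)
  unlink(path)
})
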