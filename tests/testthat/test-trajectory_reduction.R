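test_that("node sequences validate their invariants", {
  expect_error(node_sequence(c(0L, 5L), c(0, 1), maze = maze6), "non-adjacent")
  expect_error(node_sequence(c(0L, 1L), c(1, 0)), "nondecreasing")
  expect_error(node_sequence(NA_integer_, 0, "maze"), "node id")
  s <- nseq(c(0L, 2L, 6L))
  expect_s3_class(s, "node_sequence")
  expect_equal(nrow(s), 3L)
})

test_that("node sequences round-trip through delimited text", {
  rec <- session_recipe(duration = 600)
  ses <- generate_session(rec, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_node_sequence(ses$seq, path)
  back <- read_node_sequence(path)
  expect_equal(back$node, ses$seq$node)
  expect_equal(back$time, ses$seq$time)
  expect_equal(back$location, ses$seq$location)
  unlink(path)
})

test_that("track reduction marks first entries into node cells only", {
  # dwell inside the root cell, poke out into the corridor, come back:
  # a single node event
  tt <- seq(0, 5, by = 1 / 30)
  track <- data.frame(time = tt, x = 0 * tt, y = 0 * tt)
  track$x[tt > 2 & tt < 2.5] <- 0.6       # into the corridor, not a node cell
  s <- to_node_sequence(track, maze6, smooth_frames = 1L)
  expect_equal(s$node[s$location == "maze"], 0L)

  # a rendered perfect run root -> water leaf gives the 7-node path
  run <- nseq(c(0L, 2L, 6L, 14L, 30L, 62L, 125L), dt = 1.5)
  tr <- render_track(run, maze6)
  s2 <- to_node_sequence(tr, maze6)
  expect_equal(s2$node[s2$location == "maze"], run$node)

  # empty track
  expect_equal(nrow(to_node_sequence(data.frame(time = numeric(0),
                                                x = numeric(0),
                                                y = numeric(0)), maze6)), 0L)
})

test_that("rendered sessions round-trip exactly up to moderate jitter", {
  ses <- generate_session(session_recipe(duration = 900), seed = 8)
  truth <- ses$seq$node[ses$seq$location == "maze"]
  for (j in c(0, 0.2)) {
    tr <- render_track(ses, jitter = j, seed = 4)
    s2 <- to_node_sequence(tr, maze6)
    expect_identical(s2$node[s2$location == "maze"], truth,
                     label = sprintf("round trip at jitter %.1f", j))
  }
  # heavy jitter is a documented failure mode
  tr6 <- render_track(ses, jitter = 0.6, seed = 4)
  s6 <- suppressWarnings(to_node_sequence(tr6, maze6))
  expect_false(identical(s6$node[s6$location == "maze"], truth))
})

test_that("bout segmentation finds maximal maze runs", {
  s <- node_sequence(c(NA, 0L, 2L, 0L, NA, 0L, NA, 0L, 1L, 0L),
                     c(0, 10, 11, 12, 20, 30, 40, 50, 51, 52),
                     c("cage", rep("maze", 3), "cage", "maze", "cage",
                       rep("maze", 3)))
  b <- segment_bouts(s)
  expect_equal(nrow(b), 3L)
  expect_equal(b$n_steps, c(2L, 0L, 2L))
  expect_equal(b$entry_time, c(10, 30, 50))
  # first and last maze nodes of every bout are the central junction
  for (k in seq_len(nrow(b))) {
    expect_equal(s$node[b$start[k]], 0L)
    expect_equal(s$node[b$end[k]], 0L)
  }
  expect_equal(nrow(segment_bouts(nseq(integer(0)))), 0L)
})

test_that("generated sessions have graph-consistent steps at realistic scale", {
  ses <- generate_session(session_recipe(duration = 7200), seed = 13)
  # constructor validates adjacency; re-check explicitly over all bouts
  b <- segment_bouts(ses$seq)
  for (k in seq_len(nrow(b))) {
    v <- ses$seq$node[b$start[k]:b$end[k]]
    if (length(v) > 1L)
      expect_true(all(abs(tree_distance(maze6, v[-length(v)], v[-1L])) == 1L))
  }
  # step count scales to ~16k per 7 h as in the study
  steps_per_s <- sum(b$n_steps) / 7200
  expect_gt(steps_per_s * 25200, 8000)
  expect_lt(steps_per_s * 25200, 30000)
})

test_that("direct paths to a target respect the strict junction threshold", {
  # perfect entrance run: 6 junctions, excluded by > 6
  s <- nseq(c(0L, 2L, 6L, 14L, 30L, 62L, 125L))
  expect_equal(nrow(find_direct_paths(s, maze6, 125L, 6L)), 0L)
  expect_equal(nrow(find_direct_paths(s, maze6, 125L, 5L)), 1L)

  # a 13-node reversal-free path from the image leaf: 11 junctions, included
  p13 <- labmaze:::.tree_path(image_node(maze6, 125L), 125L)
  expect_length(p13, 13L)
  s13 <- nseq(c(0L, 1L, 3L, 7L, 15L, 31L, p13))   # wander out then direct
  dp <- find_direct_paths(s13, maze6, 125L, 6L)
  expect_equal(nrow(dp), 1L)
  expect_equal(dp$n_junctions, 11L)
  expect_equal(dp$start_node, p13[1L])

  # a reversal on the way truncates the path below threshold
  srev <- nseq(c(p13[1:11], p13[10], p13[11], 62L, 125L))
  dp2 <- find_direct_paths(srev, maze6, 125L, 6L)
  expect_equal(nrow(dp2), 0L)
  expect_equal(find_direct_paths(srev, maze6, 125L, 2L)$n_junctions, 3L)
})

test_that("error counts follow the backtracking arithmetic", {
  expect_equal(count_errors(6, 6), 0L)
  expect_equal(count_errors(8, 6), 1L)
  expect_equal(count_errors(20, 6), 7L)
  expect_error(count_errors(7, 6), "odd")
  expect_error(count_errors(4, 6), ">=")
})

test_that("home runs are maximal reversal-free suffixes to the exit", {
  # clean 6-step home run from a leaf
  down <- labmaze:::.tree_path(125L, 0L)
  s <- nseq(c(0L, 2L, 6L, 2L, 6L, 14L, 30L, 62L, 125L, down[-1L]))
  b <- segment_bouts(s)
  hr <- home_run(s, b[1L, ], maze6)
  expect_equal(hr$start_node, 125L)
  expect_equal(hr$start_level, 6L)
  expect_equal(hr$length, 6L)

  # turn-around at the level-1 junction: home run of length 1
  s2 <- nseq(c(0L, 2L, 0L))
  hr2 <- home_run(s2, segment_bouts(s2)[1L, ], maze6)
  expect_equal(hr2$length, 1L)
  expect_equal(hr2$start_node, 2L)

  # generated to turn around exactly once, at the level-3 node
  s3 <- nseq(c(0L, 2L, 6L, 14L, 6L, 2L, 0L))
  hr3 <- home_run(s3, segment_bouts(s3)[1L, ], maze6)
  expect_equal(hr3$start_level, 3L)
  expect_equal(hr3$length, 3L)
})

test_that("path overlap counts shared distinct nodes", {
  out <- c(0L, 2L, 6L, 14L, 30L, 62L, 125L)
  expect_equal(path_overlap(out, rev(out)), 7L)
  left <- c(0L, 1L, 3L)
  right <- c(0L, 2L, 5L)
  expect_equal(path_overlap(left, right), 1L)
})

test_that("the two-step rule debounces flickering visits", {
  s <- nseq(c(0L, 2L, 6L, 14L, 30L, 62L, 125L, 62L, 125L, 62L, 30L, 62L, 125L))
  # three arrivals at the port, but the second is an immediate flicker
  expect_length(visit_times(s, maze6, 125L), 2L)
  expect_length(visit_times(s, maze6, 125L, min_departure = 1L), 3L)
})

test_that("in-maze time excises cage residencies", {
  s <- node_sequence(c(0L, 2L, 0L, NA, 0L, 1L, 0L),
                     c(0, 5, 10, 12, 20, 25, 30),
                     c(rep("maze", 3), "cage", rep("maze", 3)))
  mt <- in_maze_time(s, c(0, 12, 20, 30))
  expect_equal(as.numeric(mt), c(0, 12, 12, 22))
  d <- residency_durations(s, "cage")
  expect_equal(d$duration, 8)
})
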