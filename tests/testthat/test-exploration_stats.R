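test_that("the optimal explorer's discovery curve is the identity up to 64", {
  s <- simulate_agent(agent_policy("optimal"), maze6)
  v <- leaf_visit_sequence(s$seq$node, maze6)
  dc <- discovery_curve(v, maze6, ns = 1:64)
  expect_equal(dc$d, as.numeric(1:64))
  eff <- n32_efficiency(dc)
  expect_equal(eff$E, 1.0)
  expect_equal(eff$N32, 32)
  expect_equal(coverage_visits(s, maze6), 64L)
})

test_that("degenerate visit sequences give degenerate curves", {
  dc <- discovery_curve(rep(63L, 100), maze6, ns = c(1, 5, 20))
  expect_equal(dc$d, c(1, 1, 1))
  empty <- discovery_curve(list(), maze6)
  expect_equal(nrow(empty), 0L)
  expect_false(n32_efficiency(dc)$reached)
})

test_that("the unbiased walk's curve matches the frozen simulation oracle", {
  s <- walk(agent_policy("unbiased"), 2e5, seed = 3)
  v <- leaf_visit_sequence(s$seq$node, maze6)
  dc <- discovery_curve(v, maze6, ns = c(76, 139))
  # frozen from independent long-run simulations of the same process
  expect_lt(abs(dc$d[1] - 21.3), 1.0)
  expect_lt(abs(dc$d[2] - 31.9), 1.2)
  e <- n32_efficiency(discovery_curve(v, maze6, ns = 1:250))
  expect_lt(abs(e$E - 0.23), 0.02)
})

test_that("interpolated N32 agrees with the brute-force window search", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 4e4, seed = 9)
  v <- leaf_visit_sequence(s$seq$node, maze6)
  dc <- discovery_curve(v, maze6, ns = 1:150)
  eff <- n32_efficiency(dc)
  brute <- min(dc$n[!is.na(dc$d) & dc$d >= 32])
  expect_lte(abs(eff$N32 - brute), 1)
})

test_that("the discovery-curve fit recovers its own parameters", {
  n <- 1:400
  a0 <- 80; b0 <- 0.1
  d <- 64 * (1 - (1 + b0) / (1 + n / a0 + b0 * (n / a0)^3))
  cv <- structure(data.frame(n = n, d = d, windows = 1L),
                  class = c("discovery_curve", "data.frame"))
  attr(cv, "n_leaves") <- 64L
  f <- fit_discovery(cv)
  expect_true(f$converged)
  expect_lt(abs(f$a - a0) / a0, 0.01)
  expect_lt(abs(f$b - b0) / b0, 0.01)
  expect_equal(f$E, 32 / f$a)
})

test_that("fits of agent curves give small b and sensible a", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 2e5, seed = 21)
  v <- leaf_visit_sequence(s$seq$node, maze6)
  dc <- discovery_curve(v, maze6, ns = 1:400)
  f <- fit_discovery(dc)
  expect_true(f$converged)
  expect_lt(f$b, 0.5)                    # late acceleration is small
  eff <- n32_efficiency(dc)
  expect_lt(abs(f$a - eff$N32) / eff$N32, 0.25)

  # optimal agent: half-coverage parameter near 32
  so <- simulate_agent(agent_policy("optimal"), maze6)
  dco <- discovery_curve(leaf_visit_sequence(so$seq$node, maze6), maze6,
                         ns = 1:64)
  fo <- fit_discovery(dco)
  expect_lt(abs(fo$a - 32) / 32, 0.25)
})

test_that("split-half efficiency is stable for a stationary policy", {
  # long unrewarded sessions so each half holds enough long explore clips
  rec <- session_recipe(duration = 50400, rewarded = FALSE)
  ratios <- vapply(1:3, function(k) {
    ses <- generate_session(rec, seed = 100 + k)
    split_half_efficiency(ses$seq, ses$maze, rewarded = FALSE)$ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("a policy degrading late in the session lowers the ratio", {
  weak <- bias_set(0.75, 0.5, 0.8, 0.55)
  rec <- session_recipe(
    duration = 50400, rewarded = FALSE,
    epochs = list(
      list(start = 0, policy = bias_ref, p_drink_start = 0, p_drink_step = 0),
      list(start = 25200, policy = weak, p_drink_start = 0,
           p_drink_step = 0)))
  ratios <- vapply(1:3, function(k) {
    ses <- generate_session(rec, seed = 200 + k)
    split_half_efficiency(ses$seq, ses$maze, rewarded = FALSE)$ratio
  }, numeric(1))
  expect_lt(mean(ratios), 0.88)
})

test_that("occupancy, preference ratio and variance explained behave", {
  # uniform synthetic visits
  u <- rep(maze_leaves(maze6), 10)
  occ <- endnode_occupancy(list(u), maze6)
  expect_equal(sum(occ), 1)
  expect_equal(outer_inner_ratio(occ, maze6), 1)
  expect_equal(variance_explained(occ, occ), 1)

  # forward-biased agents with alternation prefer the outer ring
  s <- walk(agent_policy("four_bias", biases = bias_alt), 2e5, seed = 31)
  occ2 <- endnode_occupancy(list(leaf_visit_sequence(s$seq$node, maze6)), maze6)
  expect_gt(outer_inner_ratio(occ2, maze6), 1.3)

  # a replicate agent's occupancy explains much of another's variance
  s2 <- walk(agent_policy("four_bias", biases = bias_alt), 2e5, seed = 32)
  occ3 <- endnode_occupancy(list(leaf_visit_sequence(s2$seq$node, maze6)), maze6)
  expect_gt(variance_explained(occ2, occ3), 0.5)
  expect_error(variance_explained(occ2, occ3[-1]), "mismatch")
})

test_that("no policy beats the optimal explorer", {
  eff_u <- efficiency_of_policy(agent_policy("unbiased"), maze6,
                                n_steps = 5e4, replicates = 3, seed = 41)
  eff_b <- efficiency_of_policy(agent_policy("four_bias", biases = bias_ref),
                                maze6, n_steps = 5e4, replicates = 3, seed = 42)
  eff_o <- efficiency_of_policy(agent_policy("optimal"), maze6, replicates = 1)
  expect_gt(eff_b$mean, eff_u$mean)      # forward biases help
  expect_gte(1, eff_b$mean)
  expect_equal(eff_o$mean, 1)
})
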