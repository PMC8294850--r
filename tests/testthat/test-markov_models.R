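# a tiny hand-made decision table
tiny_decisions <- function(actions, keys) {
  data.frame(node = 0L, action = actions, a0 = NA_integer_, key1 = keys,
             stringsAsFactors = FALSE)
}

test_that("Laplace smoothing gives the exact conditional probabilities", {
  train <- tiny_decisions(c("L", "L"), c("h1", "h1"))
  model <- fit_markov(train, depth = 1)
  test <- tiny_decisions(c("L", "R"), c("h1", "h2"))
  pr <- predict(model, test)
  # counts (2,0,0) -> (3/5, 1/5, 1/5); unseen history -> uniform
  expect_equal(unname(pr$prob[1, ]), c(3/5, 1/5, 1/5))
  expect_equal(unname(pr$prob[2, ]), rep(1/3, 3))
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-12))
})

test_that("cross-entropy baselines are exact", {
  dec <- tiny_decisions(rep("L", 10), rep("h", 10))
  expect_equal(cross_entropy("uniform", dec)$H, log2(3))
  model <- fit_markov(dec, depth = 1)
  rep <- cross_entropy(model, dec)
  expect_lt(rep$H, log2(3))
})

test_that("a deterministic policy is predicted almost perfectly", {
  s <- walk(agent_policy("four_bias", biases = bias_set(1, 1, 1, 1)),
            2e4, seed = 81)
  dec <- markov_decisions(s, maze6, kmax = 2, mode_filter = FALSE)
  cv <- markov_cv(dec, depth = 2)
  expect_lt(cv$H, 0.1)
})

test_that("the depth-1 model converges to the oracle conditional entropy", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 3e5, seed = 82)
  dec <- markov_decisions(s, maze6, kmax = 1, mode_filter = FALSE)
  cv <- markov_cv(dec, depth = 1)

  # brute-force oracle: enumerate the policy's action distribution per
  # (junction, incoming-action) case, weight cases by their stationary
  # frequency in an independent simulation, and take H(action | junction)
  pol_probs <- function(a0, node) {
    PSF <- 0.85; PSA <- 0.55; PBF <- 0.90; PBS <- 0.60
    p <- c(L = 0, R = 0, O = 0)
    if (a0 %in% 0:1) {
      alt <- if (a0 == 0) "R" else "L"
      rep_ <- setdiff(c("L", "R"), alt)
      p["O"] <- 1 - PSF; p[alt] <- PSF * PSA; p[rep_] <- PSF * (1 - PSA)
    } else {
      back <- if (a0 == 2) "L" else "R"
      oth <- setdiff(c("L", "R"), back)
      if (node == 0) {
        prev <- (1 - PBF) / (1 - PBF * PBS)
        p[back] <- prev; p[oth] <- 1 - prev
      } else {
        p[back] <- 1 - PBF; p["O"] <- PBF * PBS; p[oth] <- PBF * (1 - PBS)
      }
    }
    p
  }
  s2 <- walk(agent_policy("four_bias", biases = bias_ref), 3e5, seed = 83)
  d2 <- markov_decisions(s2, maze6, kmax = 1, mode_filter = FALSE)
  d2 <- d2[!is.na(d2$a0), ]
  freq <- table(d2$node, d2$a0)
  H_oracle <- 0
  for (nd in rownames(freq)) {
    w <- freq[nd, ]
    if (sum(w) == 0) next
    mix <- c(L = 0, R = 0, O = 0)
    for (a0 in colnames(freq)[w > 0])
      mix <- mix + (w[a0] / sum(w)) * pol_probs(as.integer(a0), as.integer(nd))
    Hn <- -sum(ifelse(mix > 0, mix * log2(mix), 0))
    H_oracle <- H_oracle + (sum(w) / sum(freq)) * Hn
  }
  expect_lt(abs(cv$H - H_oracle), 0.02)
})

test_that("fixed-depth models overfit beyond depth 2 at session length", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 16000, seed = 84)
  dec <- markov_decisions(s, maze6, kmax = 4, mode_filter = FALSE)
  H <- vapply(1:4, function(k) markov_cv(dec, depth = k)$H, numeric(1))
  expect_lt(H[2], H[1])        # the true structure is depth 2
  expect_gt(H[3], H[2])        # deeper histories only add variance
  expect_gt(H[4], H[3])
})

test_that("the pruned variable-depth model degrades gracefully", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 16000, seed = 85)
  dec <- markov_decisions(s, maze6, kmax = 6, mode_filter = FALSE)
  H2 <- markov_cv(dec, depth = 2)$H
  Hvar <- vapply(c(10L, 20L, 50L), function(m)
    markov_cv(dec, depth = NULL, kmax = 6, m = m)$H, numeric(1))
  expect_lt(min(Hvar), H2 + 0.02)
  # much better than the deep fixed model it replaces
  expect_lt(min(Hvar), markov_cv(dec, depth = 4)$H)
  # retained histories lengthen as the threshold loosens
  cv10 <- markov_cv(dec, depth = NULL, kmax = 6, m = 10L)
  cv200 <- markov_cv(dec, depth = NULL, kmax = 6, m = 200L)
  expect_gt(cv10$mean_history_length, cv200$mean_history_length)
})

test_that("left/right pooling leaves symmetric policies unchanged", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 5e4, seed = 86)
  dec_n <- markov_decisions(s, maze6, kmax = 2, pooling = "none",
                            mode_filter = FALSE)
  dec_p <- markov_decisions(s, maze6, kmax = 2, pooling = "lr_level",
                            mode_filter = FALSE)
  Hn <- markov_cv(dec_n, depth = 2)$H
  Hp <- markov_cv(dec_p, depth = 2)$H
  expect_lt(abs(Hn - Hp), 0.03)
  # pooling shrinks the history space
  expect_lt(nrow(fit_markov(dec_p, depth = 2)$tables[[1]]),
            nrow(fit_markov(dec_n, depth = 2)$tables[[1]]))
})

test_that("model comparison covers fixed, variable and baseline models", {
  s <- walk(agent_policy("four_bias", biases = bias_ref), 16000, seed = 87)
  cmp <- compare_models(s, maze6, ks = 1:2, m_grid = c(10L, 20L),
                        mode_filter = FALSE)
  expect_true(all(c("fixed k=1", "fixed k=2", "variable m=10",
                    "four-bias walk", "uniform") %in% cmp$model))
  expect_equal(cmp$H_bits[cmp$model == "uniform"], log2(3))
  # the four-parameter baseline cannot beat the best markov chain by much
  best <- min(cmp$H_bits[grepl("fixed|variable", cmp$model)])
  expect_gte(cmp$H_bits[cmp$model == "four-bias walk"], best - 0.02)
  expect_true(all(cmp$H_bits <= log2(3) + 1e-9))
})
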