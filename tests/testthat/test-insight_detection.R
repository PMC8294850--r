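test_that("the Poisson log-likelihood has its closed forms", {
  tr <- event_train(c(100, 200, 300), 1000)
  # constant rate: n ln r - r T
  expect_equal(rate_loglik(tr, "step", ri = 0.003, rf = 0.003, ts = 500),
               3 * log(0.003) - 0.003 * 1000)
  # step at the right edge reduces to the constant-ri model
  expect_equal(rate_loglik(tr, "step", ri = 0.003, rf = 99, ts = 1000),
               3 * log(0.003) - 0.003 * 1000)
  # a vanishing sigmoid width reproduces the step likelihood
  expect_equal(rate_loglik(tr, "sigmoid", 0.002, 0.01, 500, w = 1e-4),
               rate_loglik(tr, "step", 0.002, 0.01, 500), tolerance = 1e-9)
  # zero rate at an event returns -Inf, not an error
  expect_equal(rate_loglik(tr, "step", ri = 0, rf = 0.01, ts = 500), -Inf)
  # translation invariance of train and window together
  tr2 <- event_train(c(100, 200, 300) + 50, 1050)
  expect_equal(rate_loglik(tr2, "step", 0.002, 0.01, 550) -
                 rate_loglik(tr, "step", 0.002, 0.01, 500),
               -0.002 * 50)  # only the prepended low-rate stretch contributes
})

test_that("step fits recover a rate jump and its closed-form MLE rates", {
  set.seed(71)
  tr <- simulate_event_train("step", ri = 0.002, rf = 0.02, ts = 2000,
                             T_obs = 1e4)
  f <- fit_step(tr)
  expect_lt(abs(f$ts_mean - 2000), 250)
  expect_lt(abs(f$ts_mle - 2000), 250)
  # MLE rates equal count/duration on each side of the ML step
  n1 <- sum(tr$times < f$ts_mle)
  expect_equal(f$ri, n1 / f$ts_mle)
  expect_equal(f$rf, (length(tr$times) - n1) / (tr$T - f$ts_mle))
  expect_false(f$degenerate)
  # profile weights normalise
  expect_equal(sum(f$profile$weight), 1)
})

test_that("homogeneous trains give a broad, uninformative step profile", {
  set.seed(72)
  tr <- simulate_event_train("step", ri = 0.01, rf = 0.01, ts = 5000,
                             T_obs = 1e4)
  f <- fit_step(tr)
  # SD comparable to that of a uniform step time, T/sqrt(12) ~ 2900 s
  expect_gt(f$ts_sd, 900)
})

test_that("sigmoid fits identify sudden versus gradual transitions", {
  set.seed(73)
  ws <- replicate(10, {
    tr <- simulate_event_train("step", 0.002, 0.02, 2000, T_obs = 1e4)
    fit_sigmoid(tr)$w
  })
  expect_lt(median(ws), 300)
  set.seed(74)
  wg <- replicate(10, {
    tr <- simulate_event_train("sigmoid", 0.002, 0.02, 2000, w = 1500,
                               T_obs = 1e4)
    fit_sigmoid(tr)$w
  })
  expect_gt(median(wg), 300)
  # the w = 50 setting: step time within 200 s, width typically sudden
  set.seed(75)
  fits <- replicate(16, {
    tr <- simulate_event_train("sigmoid", 0.002, 0.02, 2000, w = 50,
                               T_obs = 1e4)
    f <- fit_sigmoid(tr)
    c(f$ts, f$w)
  })
  expect_lt(median(abs(fits[1, ] - 2000)), 200)
  # the width estimate separates narrow from wide transitions
  expect_lt(median(fits[2, ]), median(wg))
  expect_gte(mean(fits[2, ] < 300), 0.4)
})

test_that("the null case fits near-equal rates", {
  set.seed(76)
  tr <- simulate_event_train("step", 0.01, 0.01, 5000, T_obs = 1e4)
  f <- fit_sigmoid(tr)
  expect_lt(abs(f$rf - f$ri), 0.008)
})

test_that("classification applies the width and uncertainty thresholds", {
  sig <- structure(list(w = 100, converged = TRUE), class = "sigmoid_fit")
  stp <- structure(list(ts_sd = 150), class = "step_fit")
  expect_equal(classify_sudden(sig, stp), "sudden")
  sig$w <- 1000
  expect_equal(classify_sudden(sig, stp), "gradual")
  sig$w <- 100; stp$ts_sd <- 950
  expect_equal(classify_sudden(sig, stp), "dropped")
})

test_that("parameter recovery holds across replicate step trains", {
  set.seed(77)
  res <- t(replicate(30, {
    tr <- simulate_event_train("step", 0.002, 0.02, 2000, T_obs = 1e4)
    f <- fit_step(tr)
    c(err = abs(f$ts_mean - 2000), cover = abs(f$ts_mean - 2000) <= 2 * f$ts_sd)
  }))
  expect_lt(median(res[, "err"]), 200)
  expect_gte(mean(res[, "cover"]), 0.9)
})

test_that("the two-event minimum is enforced", {
  expect_error(fit_step(event_train(5, 10)), "2 events")
  expect_error(fit_sigmoid(event_train(5, 10)), "2 events")
  expect_error(event_train(c(-1, 5), 10), "0, T")
})
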