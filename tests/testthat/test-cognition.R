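test_that("discovery matrix is the row-normalised inverse-square law", {
  # two sites equidistant from the nest -> equal discovery probability
  env <- new_environment(c(-30, 30), c(0, 0), 200)
  pd <- build_discovery_matrix(env)
  expect_equal(pd["nest", "1"], pd["nest", "2"])
  # distances r and 2r from the nest -> probabilities 4/5 and 1/5
  env <- new_environment(c(20, 40), c(0, 1e-6), 200)  # y offset avoids collinear overlap
  pd <- build_discovery_matrix(env)
  expect_equal(unname(pd["nest", c("1", "2")]), c(4 / 5, 1 / 5),
               tolerance = 1e-6)
  # any generated environment: zero diagonal, rows sum to 1 within 1e-12
  for (seed in 1:5) {
    env <- generate_uniform(15, 300, rng_seed = seed)
    pd <- build_discovery_matrix(env)
    expect_true(all(diag(pd) == 0))
    expect_true(all(abs(rowSums(pd) - 1) < 1e-12))
    expect_true(all(pd >= 0))
  }
  # coincident locations are refused by name
  env <- new_environment(c(10, 10, 50), c(5, 5, 5), 200)
  expect_error(build_discovery_matrix(env), "coincident")
})

test_that("perceived value, Q initialisation and Q update follow the model", {
  expect_equal(perceived_value(0, 0.3), 0)
  expect_equal(perceived_value(20, 1), 20)
  expect_equal(perceived_value(10, 0.2), 2)
  expect_error(perceived_value(-1, 0.5), "nectar")

  env <- generate_uniform(10, 300, rng_seed = 2)
  pd <- build_discovery_matrix(env)
  q0 <- q_init(pd, 20)
  expect_equal(q0, 0.5 * 20 * pd)
  expect_true(all(diag(q0) == 0))
  expect_equal(unname(rowSums(q0)), rep(10, 11))  # n_max / 2 per row

  expect_equal(q_update(4, 8, 0.5), 6)
  expect_equal(q_update(4, 8, 0), 4)    # no learning
  expect_equal(q_update(4, 8, 1), 8)    # full replacement
  expect_error(q_update(1, 1, 1.5), "alpha")
})

test_that("softmax choice probabilities honour beta and exclusions", {
  q <- c(a = 1, b = 2, c = 3, d = 4)
  # beta = 0: uniform over allowed options
  expect_equal(unname(choice_probabilities(q, 0)), rep(0.25, 4))
  expect_equal(unname(choice_probabilities(q, 0, excluded = 2)),
               c(1, 0, 1, 1) / 3)
  # equal values: uniform at any beta
  expect_equal(unname(choice_probabilities(rep(2, 5), 37)), rep(0.2, 5))
  # large beta concentrates on the argmax; checked against a direct
  # evaluation of the softmax formula
  p <- choice_probabilities(q, 200)
  direct <- exp(200 * q - max(200 * q)); direct <- direct / sum(direct)
  expect_equal(unname(p), unname(direct), tolerance = 1e-12)
  expect_gt(p[["d"]], 1 - 1e-12)
  # numerical stability for beta * Q up to 1e4
  p <- choice_probabilities(c(9999, 10000, 1), 1)
  expect_true(all(is.finite(p)) && abs(sum(p) - 1) < 1e-12)
  # rows over allowed destinations sum to 1 within 1e-12
  for (i in 1:20) {
    qq <- runif(8, 0, 20)
    pr <- choice_probabilities(qq, runif(1, 0, 50), excluded = sample(8, 3))
    expect_lt(abs(sum(pr) - 1), 1e-12)
    expect_true(all(pr[sample(8, 3)] >= 0))
  }
  # empty allowed set is signalled, not an error
  pr <- choice_probabilities(q, 5, excluded = 1:4)
  expect_true(isTRUE(attr(pr, "empty")))
  expect_equal(as.numeric(pr), rep(0, 4), ignore_attr = TRUE)
  expect_error(choice_probabilities(q, -1), "beta")
})

test_that("categorical sampling is correct and reproducible", {
  set.seed(1)
  expect_equal(choose_next(c(0, 0, 1, 0)), 3)
  # uniform over 4 options: frequencies within 5 binomial SE of 0.25
  set.seed(42)
  draws <- replicate(20000, choose_next(rep(0.25, 4)))
  freq <- tabulate(draws, 4) / 20000
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_true(all(abs(freq - 0.25) < 5 * se))
  # same RNG state -> same draw
  set.seed(7); d1 <- choose_next(c(0.3, 0.3, 0.4))
  set.seed(7); d2 <- choose_next(c(0.3, 0.3, 0.4))
  expect_identical(d1, d2)
  expect_error(choose_next(c(0.5, 0.2)), "malformed")
})

test_that("bee parameter validation enforces documented ranges", {
  p <- bee_params()
  expect_equal(p$crop_capacity, 100)  # five full site loads of 20 ul
  expect_error(bee_params(alpha = 1.2), "alpha")
  expect_error(bee_params(beta = -1), "beta")
  expect_error(bee_params(speed = 0), "speed")
})
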