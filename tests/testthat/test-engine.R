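test_that("travel kinematics follow the ceiling discretisation rule", {
  env <- ring_env(n_sites = 5, radius = 50)
  params <- bee_params(speed = 3)
  sim <- run_simulation(env, params, n_bees = 1, horizon = 3600, rng_seed = 4)
  ev <- sim$events
  # first arrival: distance 50 m from the nest at 3 m/s, dt = 1 s
  expect_equal(ev$time[1], ceiling(50 / 3))
  expect_equal(ev$from[1], 0)  # left from the nest
  # every inter-site leg is a whole-timestep straight-line flight
  pos <- rbind(c(0, 0), as.matrix(env$sites[, c("x", "y")]))
  dm <- as.matrix(dist(pos))
  for (r in 2:nrow(ev)) {
    if (ev$bee_id[r] != ev$bee_id[r - 1] || ev$from[r] != ev$to[r - 1]) next
    expect_equal(ev$time[r] - ev$time[r - 1],
                 ceiling(dm[ev$from[r] + 1, ev$to[r] + 1] / 3))
  }
})

test_that("simulations are deterministic under a fixed seed and reject bad input", {
  env <- generate_uniform(10, 300, rng_seed = 8)
  params <- bee_params()
  s1 <- run_simulation(env, params, n_bees = 2, horizon = 5000, rng_seed = 99)
  s2 <- run_simulation(env, params, n_bees = 2, horizon = 5000, rng_seed = 99)
  expect_identical(s1$bouts, s2$bouts)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$q_tables, s2$q_tables)
  s3 <- run_simulation(env, params, n_bees = 2, horizon = 5000, rng_seed = 100)
  expect_false(identical(s1$bouts, s3$bouts))
  expect_error(run_simulation(env, params, n_bees = 0), "n_bees")
  expect_error(run_simulation(env, params, horizon = -1), "positive")
})

test_that("feeding takes min(standing crop, crop space) and updates Q on arrival", {
  env <- ring_env(n_sites = 5, max_nectar = 20, renewal_duration = 100)
  sim <- run_simulation(env, bee_params(alpha = 0.5, wm_span = 10), n_bees = 1,
                        horizon = 5000, rng_seed = 31)
  ev <- sim$events
  expect_true(all(ev$collected <= ev$standing + 1e-12))
  expect_true(all(ev$collected <= 100 + 1e-12))
  expect_true(all(ev$standing >= 0 & ev$standing <= 20 + 1e-12))
  # within each bout, cumulative collection never exceeds the crop capacity
  for (b in seq_len(nrow(sim$bouts))) {
    bout <- sim$bouts[b, ]
    legs <- ev[ev$time >= bout$t_start & ev$time <= bout$t_end &
                 ev$bee_id == bout$bee_id, ]
    expect_true(max(cumsum(legs$collected)) <= 100 + 1e-9)
    expect_equal(sum(legs$collected), bout$nectar_collected)
  }
  # perceived value is standing crop x discovery probability
  pd <- build_discovery_matrix(env)
  expect_equal(ev$value, ev$standing * pd[cbind(ev$from + 1, ev$to + 1)])
})

test_that("bouts terminate on full crop, distance budget, or total inhibition", {
  # tight distance budget cuts bouts short
  env <- ring_env(n_sites = 5, radius = 50)
  sim <- run_simulation(env, bee_params(max_bout_distance = 150), n_bees = 1,
                        horizon = 4000, rng_seed = 13)
  expect_true(all(sim$bouts$n_visits <= 3))  # 50 m out + at most two legs
  # an everlasting working memory forces return once all sites are inhibited:
  # 3 sites of 20 ul against a 100 ul crop -> at most 3 visits, all distinct
  env3 <- ring_env(n_sites = 3, radius = 30, renewal_duration = 50)
  sim3 <- run_simulation(env3, bee_params(wm_span = 1e7), n_bees = 1,
                         horizon = 4000, rng_seed = 14)
  expect_true(all(sim3$bouts$n_visits <= 3))
  for (v in sim3$bouts$visit_sequence) expect_false(anyDuplicated(v) > 0)
  # with a short memory and fast renewal the crop fills instead
  sim5 <- run_simulation(ring_env(5, renewal_duration = 50),
                         bee_params(wm_span = 10), 1, 4000, rng_seed = 15)
  expect_true(any(sim5$bouts$nectar_collected >= 100 - 1e-9))
})

test_that("nest turnaround empties the crop and schedules the next departure", {
  env <- ring_env(n_sites = 5, renewal_duration = 50)
  params <- bee_params(wm_span = 10, nest_wait = 300)
  sim <- run_simulation(env, params, n_bees = 1, horizon = 8000, rng_seed = 5)
  b <- sim$bouts[order(sim$bouts$bout_index), ]
  expect_true(nrow(b) >= 3)
  # next bout starts exactly nest_wait after the previous return (no site
  # was inhibited at departure here: spans are far shorter than the wait)
  expect_equal(b$t_start[-1], b$t_end[-nrow(b)] + 300)
  expect_equal(b$bout_index, seq_len(nrow(b)))
})

test_that("nectar is conserved: replayed renewal and collections give the final stocks", {
  for (seed in c(3, 17)) {
    env <- generate_uniform(12, 300, rng_seed = seed)
    sim <- run_simulation(env, bee_params(wm_span = 60), n_bees = 3,
                          horizon = 7200, rng_seed = seed)
    expect_equal(sim$sites$final_nectar, replay_final_nectar(sim),
                 tolerance = 1e-9)
    expect_equal(sim$sites$collected,
                 as.numeric(tapply(sim$events$collected,
                                   factor(sim$events$to, levels = 1:12), sum,
                                   default = 0)))
    # total collected cannot exceed total produced (initial stock + renewal)
    produced <- sum(env$sites$nectar) +
      nrow(env$sites) * 20 * sim$horizon / env$sites$renewal_duration[1]
    expect_lte(sum(sim$sites$collected), produced)
  }
})

test_that("Q-tables stay within [0, n_max] and obey the learning-rate limits", {
  env <- generate_uniform(8, 250, rng_seed = 6)
  pd <- build_discovery_matrix(env)
  q0 <- q_init(pd, 20)
  # alpha = 0: no learning, Q stays at its initial value exactly
  sim0 <- run_simulation(env, bee_params(alpha = 0), 1, 10000, rng_seed = 44)
  expect_identical(sim0$q_tables[[1]], q0)
  # alpha = 1: Q equals the last perceived value of each realised transition
  sim1 <- run_simulation(env, bee_params(alpha = 1), 1, 10000, rng_seed = 44)
  ev <- sim1$events
  for (key in unique(paste(ev$from, ev$to))) {
    rows <- ev[paste(ev$from, ev$to) == key, ]
    last <- rows[which.max(rows$time), ]
    expect_equal(sim1$q_tables[[1]][last$from + 1, last$to + 1], last$value)
  }
  # convexity keeps every trajectory of updates inside [0, n_max]
  for (a in c(0.3, 0.7)) {
    sim <- run_simulation(env, bee_params(alpha = a), 2, 10000, rng_seed = 45)
    for (q in sim$q_tables) expect_true(all(q >= 0 & q <= 20 + 1e-12))
  }
})

test_that("a converged greedy bee repeats its route under fast renewal", {
  env <- ring_env(n_sites = 5, radius = 40, renewal_duration = 60)
  sim <- run_simulation(env, bee_params(beta = 200, wm_span = 10), n_bees = 1,
                        horizon = 10000, rng_seed = 50)
  m <- bout_metrics(sim)
  late <- m$si_lag1[m$bout_index >= max(m$bout_index) - 5 &
                      m$bout_index < max(m$bout_index)]
  expect_true(all(late == 1))
})

test_that("per-bee RNG streams leave earlier bees unchanged when bees are added", {
  env <- generate_uniform(10, 300, rng_seed = 1)
  params <- bee_params(wm_span = 10, nest_wait = 60)
  # near-instant renewal removes the resource coupling (every site is full
  # again on arrival), so bee 1's choices must be identical whether or not
  # bee 2 exists; the staggered departure only shifts its clock by one step
  env$sites$max_nectar <- 5
  env$sites$nectar <- 5
  env$sites$renewal_duration <- 1
  s1 <- run_simulation(env, params, n_bees = 1, horizon = 3000, rng_seed = 77)
  s2 <- run_simulation(env, params, n_bees = 2, horizon = 3000, rng_seed = 77)
  v1 <- s1$bouts$visit_sequence[s1$bouts$bee_id == 1]
  v2 <- s2$bouts$visit_sequence[s2$bouts$bee_id == 1]
  expect_equal(unclass(v1), unclass(v2))
})

test_that("bout tables round-trip through the CSV writer", {
  env <- ring_env()
  sim <- run_simulation(env, bee_params(wm_span = 10), 1, 3000, rng_seed = 2)
  path <- file.path(tempdir(), "bouts.csv")
  write_bouts(sim, path)
  back <- read_bouts(path)
  expect_equal(back$nectar_collected, sim$bouts$nectar_collected)
  expect_equal(unclass(back$visit_sequence), unclass(sim$bouts$visit_sequence))
})
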