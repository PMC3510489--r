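test_that("frames are assigned by posterior responsibility with tie to 1", {
  fit <- binormal_spec(0, 1, 10, 1, 0.5)
  # all values below both means: everything is state 1 (ascending means)
  ens <- make_ens(rep(-3, 20) + (1:20) * 1e-3, time = (0:19) * 0.1)
  traj <- assign_states(ens, fit)
  expect_true(all(traj$states == 1L))
  # the recorded boundary is the symmetric crossing point
  expect_equal(traj$boundary, 5, tolerance = 1e-8)
  # a value exactly at the boundary goes to state 1
  ens2 <- make_ens(c(5, 5 + 1e-9, 12), time = 0:2)
  expect_equal(assign_states(ens2, fit)$states[1], 1L)
})

test_that("non-uniform timesteps are rejected with the offending index", {
  fit <- binormal_spec(0, 1, 10, 1, 0.5)
  ens <- make_ens(rnorm(5), time = c(0, 1, 2, 3.5, 4.5))
  expect_error(assign_states(ens, fit), "frame index 4")
})

test_that("state assignment recovers telegraph ground truth", {
  em <- binormal_spec(0, 1, 8, 1, 0.5)   # 8 sigma separation
  sim <- sample_telegraph(telegraph_spec(5, 5, em, 0.001), 50, seed = 1)
  fit <- fit_binormal(sim$series, seed = 1)
  traj <- assign_states(sim$series, fit)
  expect_gte(mean(traj$states == sim$states$states), 0.99)
})

test_that("transition statistics handle degenerate sequences", {
  frozen <- state_trajectory(rep(1L, 100), dt = 0.1)
  st <- transition_stats(frozen)
  expect_equal(st$n_transitions, 0L)
  expect_equal(st$rate_per_ns, 0)
  expect_equal(unname(st$occupancy), c(1, 0))
  # strictly alternating: L - 1 transitions, rate 1/dt
  alt <- state_trajectory(rep(c(1L, 2L), 50), dt = 0.01)
  st2 <- transition_stats(alt)
  expect_equal(st2$n_transitions, 99L)
  expect_equal(st2$rate_per_ns, 1 / 0.01)
})

test_that("residence times and rates follow alternating-renewal theory", {
  em <- binormal_spec(0, 1, 8, 1, 0.5)
  k <- 5
  sim <- sample_telegraph(telegraph_spec(k, k, em, 0.001), 2000, seed = 2)
  st <- transition_stats(sim$states)
  expect_lt(abs(st$mean_residence[["1"]] - 1 / k) / (1 / k), 0.05)
  expect_lt(abs(st$mean_residence[["2"]] - 1 / k) / (1 / k), 0.05)
  n_cyc <- st$n_transitions / 2
  expect_lt(abs(st$occupancy[["1"]] - 0.5), 3 * 0.5 / sqrt(n_cyc))
  # rate ~ 2 / (tau1 + tau2)
  tau <- st$mean_residence
  expect_lt(abs(st$rate_per_ns - 2 / (tau[["1"]] + tau[["2"]])) /
              st$rate_per_ns, 0.05)
})

test_that("transition counts are invariant under state relabelling", {
  s <- seeded(3, sample(1:2, 500, replace = TRUE))
  a <- transition_stats(state_trajectory(s, 0.1))
  b <- transition_stats(state_trajectory(3L - s, 0.1))
  expect_equal(a$n_transitions, b$n_transitions)
  expect_equal(a$occupancy[["1"]], b$occupancy[["2"]])
})

test_that("the minimum-dwell filter removes fast recrossings", {
  s <- c(rep(1L, 50), 2L, rep(1L, 50), rep(2L, 50))
  traj <- state_trajectory(s, 0.1)
  expect_equal(transition_stats(traj)$n_transitions, 3L)
  em <- binormal_spec(0, 1, 100, 1, 0.5)
  ens <- make_ens(ifelse(s == 1L, 0, 100), time = (seq_along(s) - 1) * 0.1)
  filtered <- assign_states(ens, em, min_dwell_frames = 5L)
  expect_equal(transition_stats(filtered)$n_transitions, 1L)
})

test_that("prefix windows reproduce full-trajectory statistics", {
  em <- binormal_spec(0, 1, 8, 1, 0.5)
  sim <- sample_telegraph(telegraph_spec(4, 4, em, 0.001), 200, seed = 4)
  fit <- fit_binormal(sim$series, seed = 1)
  total <- diff(range(sim$series$time))
  prof <- convergence_profile(sim$series, fit, windows = total)
  st <- transition_stats(assign_states(sim$series, fit))
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$occupancy_low, st$occupancy[["1"]])
  expect_equal(prof$rate_per_ns, st$rate_per_ns)
  expect_error(convergence_profile(sim$series, fit, windows = total * 2),
               "exceeds")
})

test_that("stationary series converge; minor-state starts show burn-in bias", {
  em <- binormal_spec(0, 1, 8, 1, 0.5)
  sim <- sample_telegraph(telegraph_spec(3, 3, em, 0.001), 500, seed = 5)
  fit <- fit_binormal(sim$series, seed = 1)
  prof <- convergence_profile(sim$series, fit, windows = c(50, 100, 500) - 1)
  occ <- prof$occupancy_low[nrow(prof)]
  n_cyc <- transition_stats(sim$states)$n_transitions / 2
  expect_lt(abs(occ - 0.5), 3 * 0.5 / sqrt(n_cyc))
  # occupancies are proper fractions in every window
  expect_true(all(prof$occupancy_low >= 0 & prof$occupancy_low <= 1))
  # slow-switching chain started in the minor (low) state: the shortest
  # window overestimates the low-state population relative to the longest
  slow <- sample_telegraph(telegraph_spec(0.4, 0.04, em, 0.01), 1000,
                           seed = 6, init = 1)
  prof2 <- convergence_profile(slow$series, em, windows = c(2, 990))
  expect_gt(prof2$occupancy_low[1], prof2$occupancy_low[2])
})

test_that("block transition rates are constant for a stationary chain", {
  em <- binormal_spec(0, 1, 8, 1, 0.5)
  sim <- sample_telegraph(telegraph_spec(5, 5, em, 0.001), 1000, seed = 7)
  fit <- fit_binormal(sim$series, seed = 1)
  prof <- convergence_profile(sim$series, fit, windows = 999, n_blocks = 10)
  rates <- attr(prof, "block_rates")
  expect_length(rates, 10L)
  m <- mean(rates)
  se <- sqrt(m * 100) / 100   # Poisson-style error on a 100 ns block
  expect_true(all(abs(rates - m) <= 3 * se))
})
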