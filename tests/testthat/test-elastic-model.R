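test_that("1-D stiffness is kT over the variance", {
  x <- matrix(seeded(1, rnorm(5000, 10, 2)), ncol = 1)
  st <- stiffness_from_covariance(x, kT = 1)
  expect_equal(as.numeric(st$stiffness), 1 / var(x[, 1]))
  expect_equal(st$x0, mean(x[, 1]))
})

test_that("stiffness estimation inverts harmonic sampling (round trip)", {
  K <- 2 * 0.7^abs(outer(1:6, 1:6, "-"))   # well-conditioned, dense couplings
  spec <- harmonic_spec(c(0, -1, 3.3, 0, 2, 34), K)
  x <- sample_harmonic(spec, 1e5, seed = 2)
  est <- stiffness_from_covariance(x)
  expect_lt(max(abs(est$stiffness - K) / abs(K)), 0.05)
  expect_lt(max(abs(est$x0 - spec$x0)), 0.05)
})

test_that("singular covariances fail with the collinear coordinates named", {
  x <- seeded(3, matrix(rnorm(600), ncol = 2))
  x <- cbind(x, x[, 2])   # third column duplicates the second
  colnames(x) <- c("shift", "slide", "rise")
  expect_error(stiffness_from_covariance(x), "slide~rise")
  z <- cbind(x[, 1, drop = FALSE], twist = rep(1, nrow(x)))
  expect_error(stiffness_from_covariance(z), "zero variance in twist")
})

test_that("harmonic energy is the expected quadratic form", {
  st <- elastic_state(0, matrix(0.05), kT = 1)
  expect_equal(energy_harmonic(st, 0), 0)
  expect_equal(energy_harmonic(st, 10), 2.5)   # 0.5 * 0.05 * 100
  st6 <- elastic_state(rep(1, 3), diag(3))
  v <- c(0.3, -0.2, 0.7)
  expect_equal(energy_harmonic(st6, 1 + v), energy_harmonic(st6, 1 - v))
  expect_gt(energy_harmonic(st6, c(2, 1, 1)), 0)
  expect_error(energy_harmonic(st6, c(1, 2)), "dimension")
})

test_that("the two-branch energy honours the free-energy offset", {
  si <- elastic_state(-2, matrix(1), kT = 1)
  sj <- elastic_state(2, matrix(1), kT = 1)
  m <- bimodal_elastic(si, sj, delta_g_ij = 0.8, epsilon = 0.1)
  at_i <- energy_two_state(m, -2)
  expect_equal(at_i$e_i, 0)
  expect_equal(at_i$e_min, 0)
  at_j <- energy_two_state(m, 2)
  expect_equal(at_j$e_j, 0.8)
  expect_lte(at_j$e_min, at_j$e_i)
  # symmetric states with no offset cross at the midpoint
  m0 <- bimodal_elastic(si, sj, delta_g_ij = 0, epsilon = 0.1)
  mid <- energy_two_state(m0, 0)
  expect_equal(mid$e_i, mid$e_j)
})

test_that("the smooth coupling is the lower secular branch", {
  si <- elastic_state(-2, matrix(1), kT = 1)
  sj <- elastic_state(2, matrix(1), kT = 1)
  m <- bimodal_elastic(si, sj, delta_g_ij = 0, epsilon = 0.25)
  # at the crossing e_i = e_j = E the smooth energy is E - epsilon
  e_cross <- energy_two_state(m, 0)$e_i
  expect_equal(energy_smooth(m, 0), e_cross - 0.25)
  # everywhere below the two-branch minimum, never by more than epsilon
  grid <- seq(-6, 6, length.out = 2001)
  es <- energy_smooth(m, matrix(grid, ncol = 1))
  emin <- energy_two_state(m, matrix(grid, ncol = 1))$e_min
  expect_true(all(es <= emin + 1e-12))
  expect_true(all(emin - es <= 0.25 + 1e-12))
  # epsilon -> 0 converges to the two-branch minimum
  m_small <- bimodal_elastic(si, sj, delta_g_ij = 0, epsilon = 1e-6)
  es2 <- energy_smooth(m_small, matrix(grid, ncol = 1))
  expect_lt(max(abs(es2 - emin)), 1e-5)
})

test_that("the smooth energy has no derivative jump at the crossing", {
  si <- elastic_state(-2, matrix(1.3), kT = 1)
  sj <- elastic_state(2, matrix(0.9), kT = 1)
  eps <- 0.25
  m <- bimodal_elastic(si, sj, delta_g_ij = 0.3, epsilon = eps)
  h <- 1e-4
  grid <- seq(-3, 3, by = h)
  es <- vapply(grid, function(g) energy_smooth(m, g), numeric(1))
  d1 <- diff(es) / h
  # the second difference of a smooth function stays bounded; the kink of
  # the raw two-branch minimum would produce a jump of order 1 here
  expect_lt(max(abs(diff(d1))), 10 * eps)
})

test_that("energies are invariant under joint translation", {
  si <- elastic_state(c(-1, 0), diag(c(1, 2)), kT = 1)
  sj <- elastic_state(c(2, 1), diag(c(0.5, 1)), kT = 1)
  m <- bimodal_elastic(si, sj, delta_g_ij = 0.4, epsilon = 0.2)
  x <- c(0.3, -0.8)
  shift <- c(5, -7)
  si2 <- elastic_state(si$x0 + shift, si$stiffness, kT = 1)
  sj2 <- elastic_state(sj$x0 + shift, sj$stiffness, kT = 1)
  m2 <- bimodal_elastic(si2, sj2, delta_g_ij = 0.4, epsilon = 0.2)
  expect_equal(energy_smooth(m, x), energy_smooth(m2, x + shift))
})

test_that("free-energy offsets follow Boltzmann inversion of populations", {
  expect_equal(delta_g_from_mixture(binormal_spec(0, 1, 4, 1, 0.5)), 0)
  p <- exp(1) / (1 + exp(1))   # population ratio e => 1 kT
  expect_equal(delta_g_from_mixture(binormal_spec(0, 1, 4, 1, p)), 1)
  # symmetric in which component dominates
  expect_equal(delta_g_from_mixture(binormal_spec(0, 1, 4, 1, 1 - p)), 1)
})

test_that("telegraph occupancies round-trip through delta G", {
  # rates chosen for dG = 1 kT between the states
  dg <- 1
  k12 <- 5; k21 <- 5 * exp(-dg)   # state 1 is the major state
  em <- binormal_spec(0, 1, 8, 1, 0.5)
  sim <- sample_telegraph(telegraph_spec(k12, k21, em, 0.001), 3000, seed = 4)
  occ <- transition_stats(sim$states)$occupancy
  # note rate_12 out of the MAJOR state is larger here; occupancy of state 1
  # is k21/(k12+k21), so the major state is state 2
  p_major <- max(occ)
  dg_est <- log(p_major / (1 - p_major))
  expect_lt(abs(dg_est - dg) / dg, 0.05)
})

test_that("snapshots split cleanly into substates on separated mixtures", {
  spec <- binormal_spec(0, 1, 8, 1, 0.4)
  seeded(5, {
    truth <- rbinom(5000, 1, 1 - spec$p_r) + 1
    x1 <- rnorm(5000, ifelse(truth == 1, 0, 8), 1)
    x2 <- rnorm(5000)   # second, unsplit parameter
  })
  samples <- cbind(twist = x1, roll = x2)
  fit <- fit_binormal(x1, seed = 1)
  sp <- per_state_split(samples, fit, "twist")
  expect_gte(mean(sp$assignment == truth), 0.99)
  expect_equal(nrow(sp$ensemble_i) + nrow(sp$ensemble_j), 5000L)
  # near-degenerate mixture puts everything in the dominant state
  fit1 <- binormal_spec(0, 1, 8, 1, 1 - 1e-9)
  all_i <- per_state_split(samples[x1 < 4, , drop = FALSE], fit1, "twist")
  expect_equal(nrow(all_i$ensemble_j), 0L)
  # balanced symmetric data splits near half and half
  n_i <- nrow(sp$ensemble_i)
  expect_lt(abs(n_i - 5000 * spec$p_r), 4 * sqrt(5000 * 0.4 * 0.6))
})

test_that("state-model bookkeeping scales as 2^(n-1)", {
  expect_equal(n_state_models(1:3), c(1L, 2L, 4L))
})

test_that("the unimodal error profile shows the barrier-top artefact", {
  # symmetric wells at +/-2, unimodal fit centred between them
  si <- elastic_state(-2, matrix(1), kT = 1)
  sj <- elastic_state(2, matrix(1), kT = 1)
  m <- bimodal_elastic(si, sj, delta_g_ij = 0, epsilon = 0.1)
  mix <- binormal_spec(-2, 1, 2, 1, 0.5)
  ws <- weighted_stats(mix)
  uni <- elastic_state(ws$mean, matrix(1 / ws$sd^2), kT = 1)
  prof <- unimodal_error_profile(uni, m, seq(-5, 5, length.out = 201))
  at0 <- prof[which.min(abs(prof$x)), ]
  # the unimodal minimum sits on the true barrier: energy underestimated
  expect_gt(at0$difference, 0)
  # at the well bottoms the unimodal model overestimates instead
  at_well <- prof[which.min(abs(prof$x - 2)), ]
  expect_lt(at_well$difference, 0)
  # bimodality inflates the unimodal sigma, so its curvature (kT/sigma^2)
  # underestimates the within-well curvature in the high-deformation tail
  expect_lt(1 / ws$sd^2, 1)
})

test_that("elastic model files round-trip through YAML", {
  si <- elastic_state(c(-1, 2), matrix(c(2, 0.3, 0.3, 1), 2), kT = 1)
  sj <- elastic_state(c(1, 2.5), matrix(c(1.5, -0.2, -0.2, 0.8), 2), kT = 1)
  m <- bimodal_elastic(si, sj, delta_g_ij = 0.7, epsilon = 0.25)
  path <- withr::local_tempfile(fileext = ".yml")
  write_elastic_model(m, path)
  back <- read_elastic_model(path)
  expect_equal(back$state_i$x0, m$state_i$x0)
  expect_equal(unname(back$state_j$stiffness), unname(m$state_j$stiffness),
               tolerance = 1e-12)
  expect_equal(back$delta_g_ij, 0.7)
  x <- c(0.5, 2.2)
  expect_equal(energy_smooth(back, x), energy_smooth(m, x), tolerance = 1e-10)
})
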