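#' Two-component Gaussian (binormal) specification
#'
#' Describes the mixture density
#' `g(x) = p_r * N(mu1, sigma1^2) + (1 - p_r) * N(mu2, sigma2^2)`.
#' `p_r = 1` is accepted as the degenerate pure-Gaussian limit (useful for
#' boundary checks); fitted models always have `0 < p_r < 1`.
#'
#' @param mu1,mu2 Component means (parameter units).
#' @param sigma1,sigma2 Component standard deviations (> 0).
#' @param p_r Mixture proportion of component 1, in (0, 1].
#' @return Object of class `binormal_spec`.
#' @export
binormal_spec <- function(mu1, sigma1, mu2, sigma2, p_r) {
  stopifnot(sigma1 > 0, sigma2 > 0, p_r > 0, p_r <= 1)
  structure(list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
                 p_r = p_r),
            class = "binormal_spec")
}

#' @export
print.binormal_spec <- function(x, ...) {
  cat(sprintf("<binormal_spec> %.3g * N(%.4g, %.4g^2) + %.3g * N(%.4g, %.4g^2)\n",
              x$p_r, x$mu1, x$sigma1, 1 - x$p_r, x$mu2, x$sigma2))
  invisible(x)
}

#' Mixture density of a binormal specification
#'
#' @param spec A [binormal_spec()].
#' @param x Numeric vector of evaluation points.
#' @return `p_r * dnorm(x, mu1, sigma1) + (1 - p_r) * dnorm(x, mu2, sigma2)`.
#' @export
dbinormal <- function(spec, x) {
  spec$p_r * dnorm(x, spec$mu1, spec$sigma1) +
    (1 - spec$p_r) * dnorm(x, spec$mu2, spec$sigma2)
}

#' Two-state telegraph process specification
#'
#' A discrete-time two-state Markov chain sampled every `dt` ns with per-step
#' switching probabilities `1 - exp(-rate * dt)` and Gaussian emissions per
#' state. Emulates the high-/low-state dynamics of a bimodal helical
#' parameter along an MD trajectory.
#'
#' @param rate_12,rate_21 Switching rates state 1 -> 2 and 2 -> 1 (per ns).
#' @param emission A [binormal_spec()]; component 1 is the emission of
#'   state 1, component 2 of state 2 (`p_r` is ignored — occupancy follows
#'   from the rates).
#' @param dt Sampling interval in ns. A warning is issued when
#'   `dt * (rate_12 + rate_21) > 0.2`, where the discretization becomes
#'   noticeably coarse.
#' @return Object of class `telegraph_spec`.
#' @export
telegraph_spec <- function(rate_12, rate_21, emission, dt) {
  stopifnot(rate_12 > 0, rate_21 > 0, dt > 0,
            inherits(emission, "binormal_spec"))
  if (dt * (rate_12 + rate_21) > 0.2)
    warning("dt * (rate_12 + rate_21) > 0.2: discretization will be coarse")
  structure(list(rate_12 = rate_12, rate_21 = rate_21,
                 emission = emission, dt = dt),
            class = "telegraph_spec")
}

#' Harmonic (multivariate Gaussian) ensemble specification
#'
#' Equilibrium geometry plus stiffness matrix of a harmonic model for up to
#' six coupled helical parameters; samples are drawn from
#' `N(x0, kT * solve(stiffness))`.
#'
#' @param x0 Equilibrium parameter vector (length 1-6).
#' @param stiffness Symmetric positive-definite stiffness matrix
#'   (energy per unit^2).
#' @param kT Energy scale (default 1 kT).
#' @return Object of class `harmonic_spec`.
#' @export
harmonic_spec <- function(x0, stiffness, kT = 1) {
  stiffness <- as.matrix(stiffness)
  d <- length(x0)
  stopifnot(nrow(stiffness) == d, ncol(stiffness) == d, kT > 0)
  if (max(abs(stiffness - t(stiffness))) > 1e-10 * max(1, max(abs(stiffness))))
    stop("stiffness matrix must be symmetric")
  ev <- eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("stiffness matrix must be positive definite")
  structure(list(x0 = as.numeric(x0), stiffness = stiffness, kT = kT, d = d),
            class = "harmonic_spec")
}

#' Draw i.i.d. samples from a binormal distribution
#'
#' Each draw picks component 1 with probability `p_r` and then draws from the
#' component Gaussian.
#'
#' @param spec A [binormal_spec()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param step_type,parameter,origin Labels attached to the returned ensemble.
#' @return A [helical_ensemble()] of `n` values.
#' @examples
#' ens <- sample_binormal(binormal_spec(25, 2, 35, 2, 0.3), 1000, seed = 1)
#' mean(ens$values)  # ~ 0.3*25 + 0.7*35 = 32
#' @export
sample_binormal <- function(spec, n, seed, step_type = "CG",
                            parameter = "twist", origin = "md") {
  stopifnot(inherits(spec, "binormal_spec"), n >= 1)
  x <- with_seed(seed, {
    comp1 <- runif(n) < spec$p_r
    ifelse(comp1,
           rnorm(n, spec$mu1, spec$sigma1),
           rnorm(n, spec$mu2, spec$sigma2))
  })
  helical_ensemble(x, step_type, parameter, origin)
}

#' Simulate a two-state telegraph time series with Gaussian emissions
#'
#' Simulates the discrete-time chain of a [telegraph_spec()] for
#' `duration_ns`, draws per-frame emissions from the current state's
#' Gaussian, and returns both the observed series and the hidden state
#' sequence, so state-assignment and kinetics estimators can be validated
#' against ground truth.
#'
#' @param spec A [telegraph_spec()].
#' @param duration_ns Total simulated time (>= 10 * dt).
#' @param seed Integer seed.
#' @param init One of `"stationary"` (draw the initial state from the
#'   stationary distribution), `1` or `2`.
#' @param step_type,parameter,origin Labels for the returned ensemble.
#' @return List with `series` (a [helical_ensemble()] with `time`) and
#'   `states` (a [state_trajectory()] holding the ground-truth states).
#' @export
sample_telegraph <- function(spec, duration_ns, seed, init = "stationary",
                             step_type = "CG", parameter = "twist",
                             origin = "md") {
  stopifnot(inherits(spec, "telegraph_spec"), duration_ns >= 10 * spec$dt)
  n <- floor(duration_ns / spec$dt)
  q12 <- 1 - exp(-spec$rate_12 * spec$dt)  # per-step switch probabilities
  q21 <- 1 - exp(-spec$rate_21 * spec$dt)
  out <- with_seed(seed, {
    s0 <- if (identical(init, "stationary")) {
      pi1 <- spec$rate_21 / (spec$rate_12 + spec$rate_21)
      if (runif(1) < pi1) 1L else 2L
    } else as.integer(init)
    # dwell lengths (in frames) are geometric; build the alternating chain
    states <- integer(0)
    cur <- s0
    while (length(states) < n) {
      q <- if (cur == 1L) q12 else q21
      dwell <- if (q <= 0) n else rgeom(1L, q) + 1L
      states <- c(states, rep.int(cur, min(dwell, n - length(states))))
      cur <- 3L - cur
    }
    em <- spec$emission
    mu <- ifelse(states == 1L, em$mu1, em$mu2)
    sg <- ifelse(states == 1L, em$sigma1, em$sigma2)
    list(states = states, x = rnorm(n, mu, sg))
  })
  time <- (seq_len(n) - 1L) * spec$dt
  list(series = helical_ensemble(out$x, step_type, parameter, origin,
                                 time = time),
       states = state_trajectory(out$states, spec$dt))
}

#' Draw a correlated multi-parameter ensemble from a harmonic model
#'
#' Samples `n` snapshots of the joint helical-parameter vector from the
#' multivariate Gaussian implied by a [harmonic_spec()]:
#' mean `x0`, covariance `kT * solve(stiffness)`.
#'
#' @param spec A [harmonic_spec()].
#' @param n Number of snapshots.
#' @param seed Integer seed.
#' @param parameters Column names (default the canonical six when `d == 6`).
#' @return An `n x d` numeric matrix with named columns.
#' @export
sample_harmonic <- function(spec, n, seed, parameters = NULL) {
  stopifnot(inherits(spec, "harmonic_spec"), n >= 1)
  covm <- spec$kT * solve(spec$stiffness)
  covm <- (covm + t(covm)) / 2
  x <- with_seed(seed, MASS::mvrnorm(n, mu = spec$x0, Sigma = covm))
  x <- matrix(x, nrow = n)
  colnames(x) <- if (!is.null(parameters)) parameters
                 else if (spec$d == 6L) HELICAL_PARAMETERS
                 else paste0("q", seq_len(spec$d))
  x
}

#' Bundled synthetic scenarios
#'
#' Named parameter bundles for common test scenarios. `"cg_twist_like"` places
#' its minor mode at 25 degrees, the low-twist region a CpG step visits; the
#' major mode, widths and mixture weight are plausible but arbitrary choices.
#' `"ag_slide_like"` places its minor slide mode at -1.5 Angstrom; again the
#' remaining numbers are arbitrary. `"unimodal_twist"` is a plain Gaussian
#' scenario (as a degenerate binormal).
#'
#' @param name One of `"cg_twist_like"`, `"ag_slide_like"`,
#'   `"unimodal_twist"`.
#' @return A list with `spec` (a [binormal_spec()]) and the ensemble labels
#'   `step_type`, `parameter`, `origin`.
#' @export
scenario_preset <- function(name = c("cg_twist_like", "ag_slide_like",
                                     "unimodal_twist")) {
  name <- match.arg(name)
  switch(name,
    cg_twist_like = list(
      spec = binormal_spec(25, 2.5, 36, 3.5, 0.25),
      step_type = "CG", parameter = "twist", origin = "md"),
    ag_slide_like = list(
      spec = binormal_spec(-1.5, 0.35, 0.0, 0.45, 0.3),
      step_type = "AG", parameter = "slide", origin = "md"),
    unimodal_twist = list(
      spec = binormal_spec(34, 4, 34, 4, 0.5),
      step_type = "AA", parameter = "twist", origin = "md"))
}
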