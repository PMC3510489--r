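#' Harmonic elastic state of a base-pair step
#'
#' Equilibrium helical-parameter vector plus stiffness matrix, the standard
#' harmonic description of a single conformational substate:
#' `E(x) = 1/2 (x - x0)' K (x - x0)`.
#'
#' @param x0 Equilibrium vector (length 1-6; Angstrom / degrees).
#' @param stiffness Symmetric positive-definite d x d matrix
#'   (energy per unit^2).
#' @param kT Energy unit of the stiffness entries; 1 for kT units,
#'   0.593 for kcal/mol at 298 K.
#' @return Object of class `elastic_state`.
#' @export
elastic_state <- function(x0, stiffness, kT = 1) {
  stiffness <- as.matrix(stiffness)
  d <- length(x0)
  stopifnot(nrow(stiffness) == d, ncol(stiffness) == d, kT > 0)
  if (max(abs(stiffness - t(stiffness))) > 1e-8 * max(1, max(abs(stiffness))))
    stop("stiffness matrix must be symmetric")
  ev <- eigen((stiffness + t(stiffness)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (any(ev <= 0)) stop("stiffness matrix must be positive definite")
  structure(list(x0 = as.numeric(x0), stiffness = stiffness, kT = kT, d = d),
            class = "elastic_state")
}

#' @export
print.elastic_state <- function(x, ...) {
  cat(sprintf("<elastic_state> d = %d, kT = %g\n  x0: %s\n",
              x$d, x$kT, paste(signif(x$x0, 5), collapse = ", ")))
  invisible(x)
}

#' Estimate an elastic state from an equilibrium ensemble
#'
#' Inverse-covariance estimator: the equilibrium vector is the sample mean
#' and the stiffness matrix is `kT` times the inverse of the sample
#' covariance, yielding both the diagonal force constants and the
#' off-diagonal couplings between helical parameters.
#'
#' @param samples Numeric matrix or data frame, one snapshot per row, one
#'   helical parameter per column. Requires `n > 10 * d`.
#' @param kT Energy unit for the stiffness (default 1 kT).
#' @return An [elastic_state()].
#' @examples
#' x <- sample_harmonic(harmonic_spec(rep(0, 2), diag(2)), 5000, seed = 1)
#' stiffness_from_covariance(x)$stiffness  # ~ identity
#' @export
stiffness_from_covariance <- function(samples, kT = 1) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  d <- ncol(x)
  n <- nrow(x)
  if (n <= 10 * d) stop("need n > 10 * d snapshots to invert the covariance")
  covm <- cov(x)
  # diagnose singularity before inverting, naming the offending coordinates
  sds <- sqrt(diag(covm))
  cols <- if (!is.null(colnames(x))) colnames(x) else paste0("q", seq_len(d))
  if (any(sds == 0))
    stop("covariance is singular: zero variance in ",
         paste(cols[sds == 0], collapse = ", "))
  cm <- covm / outer(sds, sds)
  pairs <- which(abs(cm) > 1 - 1e-10 & row(cm) < col(cm), arr.ind = TRUE)
  if (nrow(pairs) > 0L)
    stop("covariance is singular: collinear coordinates ",
         paste(sprintf("%s~%s", cols[pairs[, 1]], cols[pairs[, 2]]),
               collapse = ", "))
  K <- kT * solve(covm)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(cols, cols)
  elastic_state(colMeans(x), K, kT)
}

#' Harmonic deformation energy
#'
#' `E = 1/2 (x - x0)' K (x - x0)`, in the state's energy unit.
#'
#' @param state An [elastic_state()].
#' @param x A d-vector, or an n x d matrix of coordinates (one energy per
#'   row).
#' @return Numeric scalar or vector of energies (>= 0, zero only at `x0`).
#' @export
energy_harmonic <- function(state, x) {
  stopifnot(inherits(state, "elastic_state"))
  if (is.null(dim(x))) {
    if (length(x) != state$d) stop("coordinate has wrong dimension")
    dx <- x - state$x0
    return(as.numeric(0.5 * crossprod(dx, state$stiffness %*% dx)))
  }
  x <- as.matrix(x)
  if (ncol(x) != state$d) stop("coordinate has wrong dimension")
  dx <- sweep(x, 2L, state$x0)
  0.5 * rowSums((dx %*% state$stiffness) * dx)
}

#' Two-state bimodal elastic model
#'
#' Couples two harmonic substates: branch `i` is `E_i(x)` and branch `j` is
#' `E_j(x) + delta_g_ij`, where `delta_g_ij` is the free-energy offset of
#' state j's minimum relative to state i's. `epsilon` is the (small,
#' positive) coupling used by [energy_smooth()] to remove the derivative
#' discontinuity where the branches cross.
#'
#' @param state_i,state_j [elastic_state()] objects of equal dimension and
#'   energy unit.
#' @param delta_g_ij Free-energy offset of state j (energy units).
#' @param epsilon Coupling strength (> 0; default 0.25, well below kT so
#'   barrier shapes are preserved while gradients stay smooth).
#' @return Object of class `bimodal_elastic`.
#' @export
bimodal_elastic <- function(state_i, state_j, delta_g_ij = 0,
                            epsilon = 0.25) {
  stopifnot(inherits(state_i, "elastic_state"),
            inherits(state_j, "elastic_state"),
            state_i$d == state_j$d, epsilon > 0)
  structure(list(state_i = state_i, state_j = state_j,
                 delta_g_ij = delta_g_ij, epsilon = epsilon,
                 d = state_i$d),
            class = "bimodal_elastic")
}

#' @export
print.bimodal_elastic <- function(x, ...) {
  cat(sprintf("<bimodal_elastic> d = %d, delta_g_ij = %.4g, epsilon = %.4g\n",
              x$d, x$delta_g_ij, x$epsilon))
  invisible(x)
}

#' Two-branch (discontinuous) bimodal energy
#'
#' Evaluates both harmonic branches and their pointwise minimum. The minimum
#' surface has a discontinuous derivative at the branch crossing, which makes
#' it unsuitable for optimization or dynamics — use [energy_smooth()] there.
#'
#' @param model A [bimodal_elastic()].
#' @param x d-vector or n x d matrix.
#' @return List with `e_i`, `e_j` (branch j includes `delta_g_ij`) and
#'   `e_min`.
#' @export
energy_two_state <- function(model, x) {
  stopifnot(inherits(model, "bimodal_elastic"))
  e_i <- energy_harmonic(model$state_i, x)
  e_j <- energy_harmonic(model$state_j, x) + model$delta_g_ij
  list(e_i = e_i, e_j = e_j, e_min = pmin(e_i, e_j))
}

#' Smoothly coupled bimodal energy
#'
#' Lower branch of the 2 x 2 two-state secular problem with constant
#' coupling `epsilon`:
#' \deqn{E(x) = \tfrac12 (E_i + E_j) - \tfrac12 \sqrt{(E_i - E_j)^2 + 4\epsilon^2}}
#' This is the standard surface-crossing construction: continuous with
#' continuous first derivatives everywhere, equal to `E - epsilon` where the
#' branches cross at energy `E`, and converging pointwise to the two-branch
#' minimum as `epsilon -> 0`.
#'
#' @inheritParams energy_two_state
#' @return Numeric scalar or vector of energies.
#' @export
energy_smooth <- function(model, x) {
  e <- energy_two_state(model, x)
  0.5 * (e$e_i + e$e_j) - 0.5 * sqrt((e$e_i - e$e_j)^2 + 4 * model$epsilon^2)
}

#' Free-energy offset between substates from mixture weights
#'
#' Boltzmann inversion of the fitted populations: with component i the more
#' populated one, `delta_g_ij = kT * log(p_i / p_j) >= 0`.
#'
#' @param fit A [binormal_fit()] or [binormal_spec()] with `0 < p_r < 1`.
#' @param kT Energy unit.
#' @return Non-negative free-energy difference in units of `kT`.
#' @examples
#' delta_g_from_mixture(binormal_spec(0, 1, 4, 1, 0.5))  # 0
#' @export
delta_g_from_mixture <- function(fit, kT = 1) {
  m <- if (inherits(fit, "binormal_fit")) fit$model else fit
  stopifnot(inherits(m, "binormal_spec"), m$p_r > 0, m$p_r < 1)
  p_major <- max(m$p_r, 1 - m$p_r)
  kT * log(p_major / (1 - p_major))
}

#' Split a joint ensemble into its two conformational substates
#'
#' Assigns each snapshot to the mixture component with the larger posterior
#' responsibility, evaluated on one splitting parameter (ties go to
#' component i, the lower-mean component). Feeding each part to
#' [stiffness_from_covariance()] yields the per-state stiffness matrices of
#' the refined two-state model.
#'
#' @param samples Matrix or data frame of joint snapshots (columns =
#'   parameters).
#' @param fit A [binormal_fit()] on the splitting parameter.
#' @param split_parameter Column name carrying the bimodal parameter.
#' @return List with `ensemble_i`, `ensemble_j` (row subsets of `samples`)
#'   and `assignment` (1/2 per snapshot).
#' @export
per_state_split <- function(samples, fit, split_parameter) {
  x <- as.matrix(samples)
  if (!split_parameter %in% colnames(x))
    stop("split_parameter not found in samples: ", split_parameter)
  if (inherits(fit, "binormal_fit") && !isTRUE(fit$converged))
    warning("binormal fit did not converge; state split may be unreliable")
  r1 <- responsibility(fit, x[, split_parameter])
  assignment <- ifelse(r1 >= 0.5, 1L, 2L)
  d <- ncol(x)
  for (s in 1:2) {
    if (sum(assignment == s) > 0 && sum(assignment == s) <= 10 * d)
      stop(sprintf("insufficient data for state %d: %d snapshots (need > %d)",
                   s, sum(assignment == s), 10 * d))
  }
  list(ensemble_i = x[assignment == 1L, , drop = FALSE],
       ensemble_j = x[assignment == 2L, , drop = FALSE],
       assignment = assignment)
}

#' Number of state models required for multi-parameter bimodality
#'
#' When `n` helical coordinates of one step are bimodal, the two-state
#' construction must be expanded: the number of stiffness matrices and
#' equilibrium vectors scales as `2^(n-1)`.
#'
#' @param n_bimodal Number of bimodal coordinates (>= 1).
#' @return Integer count of required state models.
#' @examples
#' n_state_models(1:3)  # 1 2 4
#' @export
n_state_models <- function(n_bimodal) {
  stopifnot(all(n_bimodal >= 1))
  as.integer(2^(n_bimodal - 1))
}

#' Compare a unimodal elastic fit against the bimodal surface
#'
#' Tabulates, on a coordinate grid, the harmonic energy of a single-state
#' (unimodal) model and the smooth bimodal energy, plus their difference
#' `e_bi - e_uni` — positive where the unimodal model underestimates the
#' deformation energy. For a genuinely bimodal distribution the unimodal
#' minimum sits at the barrier top, where this difference is largest.
#'
#' @param fit_uni A 1-D [elastic_state()] (the unimodal fit).
#' @param model A 1-D [bimodal_elastic()].
#' @param grid Numeric vector of coordinates.
#' @return Data frame with columns `x`, `e_uni`, `e_bi`, `difference`.
#' @export
unimodal_error_profile <- function(fit_uni, model, grid) {
  stopifnot(inherits(fit_uni, "elastic_state"), fit_uni$d == 1L,
            inherits(model, "bimodal_elastic"), model$d == 1L)
  e_uni <- vapply(grid, function(g) energy_harmonic(fit_uni, g), numeric(1))
  e_bi <- vapply(grid, function(g) energy_smooth(model, g), numeric(1))
  data.frame(x = grid, e_uni = e_uni, e_bi = e_bi,
             difference = e_bi - e_uni)
}

#' Write / read a two-state elastic model file
#'
#' Flat YAML serialization of a [bimodal_elastic()] model: equilibrium
#' vectors, full stiffness matrices (row-major), free-energy offset,
#' coupling and energy unit.
#'
#' @param model A [bimodal_elastic()].
#' @param path Output path.
#' @return `path` (write) / the reconstructed model (read), invisibly for
#'   write.
#' @export
write_elastic_model <- function(model, path) {
  stopifnot(inherits(model, "bimodal_elastic"))
  obj <- list(d = model$d,
              kT = model$state_i$kT,
              x0_i = model$state_i$x0,
              stiffness_i = as.numeric(t(model$state_i$stiffness)),
              x0_j = model$state_j$x0,
              stiffness_j = as.numeric(t(model$state_j$stiffness)),
              delta_g_ij = model$delta_g_ij,
              epsilon = model$epsilon)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_elastic_model
#' @export
read_elastic_model <- function(path) {
  obj <- yaml::read_yaml(path)
  d <- obj$d
  mk <- function(x0, k) elastic_state(x0, matrix(k, d, d, byrow = TRUE),
                                      kT = obj$kT)
  bimodal_elastic(mk(obj$x0_i, obj$stiffness_i),
                  mk(obj$x0_j, obj$stiffness_j),
                  delta_g_ij = obj$delta_g_ij, epsilon = obj$epsilon)
}
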