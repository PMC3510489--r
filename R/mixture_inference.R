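#' Maximum-likelihood single-Gaussian fit
#'
#' Closed-form MLE: `mu` is the sample mean and `sigma` the root mean squared
#' deviation (divisor `n`, not `n - 1`), with the log-likelihood evaluated
#' exactly at the optimum.
#'
#' @param ens A [helical_ensemble()] or numeric vector with at least 2 values
#'   and nonzero variance.
#' @return Object of class `gaussian_fit`: `mu`, `sigma`, `loglik`,
#'   `k = 2`, `n`, `bic`.
#' @examples
#' fit_gaussian(c(-1, 1))  # mu = 0, sigma = 1
#' @export
fit_gaussian <- function(ens) {
  x <- ensemble_values(ens)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("degenerate fit: sample variance is zero")
  loglik <- sum(dnorm(x, mu, sigma, log = TRUE))
  structure(list(mu = mu, sigma = sigma, loglik = loglik, k = 2L, n = n,
                 bic = bic(loglik, 2L, n)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu = %.5g, sigma = %.5g, loglik = %.5g, BIC = %.5g (n = %d)\n",
              x$mu, x$sigma, x$loglik, x$bic, x$n))
  invisible(x)
}

ensemble_values <- function(ens) {
  if (inherits(ens, "helical_ensemble")) ens$values else as.numeric(ens)
}

#' Two-component Gaussian mixture fit by EM
#'
#' Fits the binormal model by expectation-maximization from several
#' deterministic, seeded initializations and keeps the best log-likelihood.
#' The restart set always contains (a) a split at the sample median with
#' half-sample moments, (b) the degenerate single-Gaussian configuration
#' (`mu1 = mu2`, `p_r = 0.5`) — which, by EM monotonicity, guarantees the
#' nesting property `loglik(binormal) >= loglik(gaussian)` — and (c)
#' `n_restarts` seeded random perturbations of the component means.
#'
#' Component collapse is prevented by a standard-deviation floor of
#' `1e-3 * sd(x)` and by clamping `p_r` to `[1e-3, 1 - 1e-3]`; without these
#' guards the likelihood is unbounded when a component shrinks onto a single
#' point. Components are reported in ascending-mean order.
#'
#' @param ens A [helical_ensemble()] or numeric vector (n >= 10).
#' @param n_restarts Number of random restarts beyond the two deterministic
#'   ones (default 4).
#' @param seed Integer seed; same data + same seed gives a bitwise-identical
#'   fit.
#' @param fit_range Optional `c(lo, hi)`: only samples inside the interval
#'   enter the fit (the truncation window used when a neighbouring
#'   conformational basin must be excluded).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` (default 1e-8) or after `max_iter`
#'   iterations (default 500).
#' @param trace If `TRUE`, attach the per-iteration log-likelihood path of
#'   the winning restart as attribute `"loglik_trace"`.
#' @return Object of class `binormal_fit`: `model` (a [binormal_spec()]),
#'   `loglik`, `k = 5`, `n`, `bic`, `converged`, `n_restarts_used`.
#' @examples
#' ens <- sample_binormal(binormal_spec(0, 1, 6, 1, 0.5), 2000, seed = 1)
#' fit_binormal(ens, seed = 1)
#' @export
fit_binormal <- function(ens, n_restarts = 4L, seed = 1L, fit_range = NULL,
                         max_iter = 500L, tol = 1e-8, trace = FALSE) {
  x <- ensemble_values(ens)
  if (!is.null(fit_range)) {
    stopifnot(length(fit_range) == 2L)
    x <- x[x >= fit_range[1] & x <= fit_range[2]]
  }
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations to fit a mixture")
  s_all <- sqrt(mean((x - mean(x))^2))
  if (s_all == 0) stop("degenerate fit: sample variance is zero")
  sigma_floor <- 1e-3 * s_all
  p_clamp <- c(1e-3, 1 - 1e-3)

  inits <- list()
  # restart 0: median split, half-sample moments
  med <- median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (length(hi) == 0L) { hi <- lo }  # all values tie at the median
  inits[[1]] <- c(mean(lo), max(sd0(lo), sigma_floor),
                  mean(hi), max(sd0(hi), sigma_floor), 0.5)
  # degenerate start: exactly the single-Gaussian solution
  inits[[2]] <- c(mean(x), s_all, mean(x), s_all, 0.5)
  # seeded random perturbations of the means
  if (n_restarts > 0L) {
    qs <- quantile(x, c(0.25, 0.75), names = FALSE)
    rand <- with_seed(seed, {
      lapply(seq_len(n_restarts), function(i)
        c(qs[1] + rnorm(1, 0, s_all), s_all,
          qs[2] + rnorm(1, 0, s_all), s_all,
          runif(1, 0.2, 0.8)))
    })
    inits <- c(inits, rand)
  }

  best <- NULL
  for (init in inits) {
    fit <- em_binormal(x, init, sigma_floor, p_clamp, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # ascending-mean ordering removes label switching
  if (best$mu1 > best$mu2) {
    best[c("mu1", "sigma1", "mu2", "sigma2")] <-
      best[c("mu2", "sigma2", "mu1", "sigma1")]
    best$p <- 1 - best$p
  }
  out <- structure(
    list(model = binormal_spec(best$mu1, best$sigma1, best$mu2, best$sigma2,
                               min(max(best$p, p_clamp[1]), p_clamp[2])),
         loglik = best$loglik, k = 5L, n = n,
         bic = bic(best$loglik, 5L, n),
         converged = best$converged,
         n_restarts_used = length(inits)),
    class = "binormal_fit")
  if (trace) attr(out, "loglik_trace") <- best$trace
  out
}

sd0 <- function(x) if (length(x) < 2L) 0 else sqrt(mean((x - mean(x))^2))

# one EM run; init = (mu1, sigma1, mu2, sigma2, p)
em_binormal <- function(x, init, sigma_floor, p_clamp, max_iter, tol) {
  mu1 <- init[1]; s1 <- max(init[2], sigma_floor)
  mu2 <- init[3]; s2 <- max(init[4], sigma_floor)
  p <- min(max(init[5], p_clamp[1]), p_clamp[2])
  ll_old <- -Inf
  converged <- FALSE
  path <- numeric(0)
  for (it in seq_len(max_iter)) {
    # E step in log space (overflow-safe)
    a <- log(p) + dnorm(x, mu1, s1, log = TRUE)
    b <- log1p(-p) + dnorm(x, mu2, s2, log = TRUE)
    m <- pmax(a, b)
    ll_i <- m + log(exp(a - m) + exp(b - m))
    ll <- sum(ll_i)
    path <- c(path, ll)
    if (ll - ll_old < tol && it > 1L) { converged <- TRUE; break }
    ll_old <- ll
    r1 <- exp(a - ll_i)
    # M step
    w1 <- sum(r1); w2 <- length(x) - w1
    p <- min(max(w1 / length(x), p_clamp[1]), p_clamp[2])
    mu1 <- sum(r1 * x) / w1
    mu2 <- sum((1 - r1) * x) / w2
    s1 <- max(sqrt(sum(r1 * (x - mu1)^2) / w1), sigma_floor)
    s2 <- max(sqrt(sum((1 - r1) * (x - mu2)^2) / w2), sigma_floor)
  }
  list(mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2, p = p,
       loglik = ll, converged = converged, trace = path)
}

#' @export
print.binormal_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("<binormal_fit> %.3g * N(%.5g, %.4g^2) + %.3g * N(%.5g, %.4g^2)\n",
              m$p_r, m$mu1, m$sigma1, 1 - m$p_r, m$mu2, m$sigma2))
  cat(sprintf("  loglik = %.5g, BIC = %.5g (n = %d, converged = %s)\n",
              x$loglik, x$bic, x$n, x$converged))
  invisible(x)
}

#' Posterior responsibilities of component 1 under a binormal fit
#'
#' @param fit A [binormal_fit()] result or a [binormal_spec()].
#' @param x Numeric vector.
#' @return Probability that each value belongs to component 1 (the
#'   lower-mean component).
#' @export
responsibility <- function(fit, x) {
  m <- if (inherits(fit, "binormal_fit")) fit$model else fit
  a <- log(m$p_r) + dnorm(x, m$mu1, m$sigma1, log = TRUE)
  b <- log1p(-m$p_r) + dnorm(x, m$mu2, m$sigma2, log = TRUE)
  mx <- pmax(a, b)
  exp(a - (mx + log(exp(a - mx) + exp(b - mx))))
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 * loglik + k * log(n)`; the model with the lower BIC is
#' preferred. The penalty term controls the introduction of the three extra
#' parameters the binormal model carries over the single Gaussian.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (2 for the Gaussian, 5 for the
#'   binormal).
#' @param n Sample size (>= 1).
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) {
  stopifnot(n >= 1)
  -2 * loglik + k * log(n)
}

#' Posterior probability of the two-component model from a BIC difference
#'
#' The BIC difference between two models approximates minus twice the log
#' Bayes factor, so with equal prior probability on the one- and
#' two-component models, `F = exp((bic1 - bic2) / 2)` and
#' `p(M2 | data) = F / (1 + F)`. Computed in log space so that large BIC
#' differences cannot overflow.
#'
#' @param bic1 BIC of the single-Gaussian model (M1).
#' @param bic2 BIC of the binormal model (M2).
#' @return `p(M2 | data)` in `[0, 1]`.
#' @examples
#' bayes_posterior(10, 10)            # 0.5
#' bayes_posterior(2 * log(19), 0)    # 0.95
#' @export
bayes_posterior <- function(bic1, bic2) {
  stopifnot(is.finite(bic1), is.finite(bic2))
  plogis((bic1 - bic2) / 2)
}

#' Evidence label from the model posterior
#'
#' Strong evidence for the binormal model (`"M2"`) when
#' `p(M2|data) > hi`, strong evidence for the single Gaussian (`"M1"`) when
#' `p(M2|data) < lo`, and insufficient evidence (`"IE"`) otherwise. The
#' thresholds are strict inequalities, so the boundary values themselves
#' classify as IE.
#'
#' @param p_m2 Posterior probability of the two-component model.
#' @param hi,lo Decision thresholds (defaults 0.95 and 0.05).
#' @return `"M1"`, `"M2"` or `"IE"`.
#' @export
classify_evidence <- function(p_m2, hi = 0.95, lo = 0.05) {
  stopifnot(p_m2 >= 0, p_m2 <= 1, lo < hi)
  if (p_m2 > hi) "M2" else if (p_m2 < lo) "M1" else "IE"
}

#' Run the full evidence analysis on one ensemble
#'
#' Convenience wrapper: Gaussian fit, binormal fit, BIC comparison, Bayes
#' posterior and evidence label in one call.
#'
#' @inheritParams fit_binormal
#' @param hi,lo Evidence thresholds passed to [classify_evidence()].
#' @return Object of class `evidence_result`: `fit1`, `fit2`, `bic1`,
#'   `bic2`, `p_m2`, `label`.
#' @export
evidence_analysis <- function(ens, n_restarts = 4L, seed = 1L,
                              fit_range = NULL, hi = 0.95, lo = 0.05) {
  fit1 <- fit_gaussian(ens)
  fit2 <- fit_binormal(ens, n_restarts = n_restarts, seed = seed,
                       fit_range = fit_range)
  p <- bayes_posterior(fit1$bic, fit2$bic)
  structure(list(fit1 = fit1, fit2 = fit2, bic1 = fit1$bic, bic2 = fit2$bic,
                 p_m2 = p, label = classify_evidence(p, hi, lo)),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("<evidence_result> %s  (p(M2|data) = %.4g; BIC1 = %.5g, BIC2 = %.5g)\n",
              x$label, x$p_m2, x$bic1, x$bic2))
  invisible(x)
}
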