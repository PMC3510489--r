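# shared fixtures and independent oracles used across test files

seeded <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

make_ens <- function(values, step = "CG", param = "twist", origin = "md",
                     time = NULL) {
  helical_ensemble(values, step, param, origin, time = time)
}

# independent oracle: binormal log-likelihood evaluated directly
binormal_loglik <- function(x, mu1, s1, mu2, s2, p) {
  sum(log(p * dnorm(x, mu1, s1) + (1 - p) * dnorm(x, mu2, s2)))
}

# brute-force lattice search for the best equal-sigma binormal fit on tiny n;
# independent of the EM implementation
grid_search_binormal <- function(x) {
  rng <- range(x)
  mus <- seq(rng[1], rng[2], length.out = 15)
  sds <- sd(x) * seq(0.2, 2, length.out = 10)
  ps <- seq(0.1, 0.9, by = 0.1)
  best <- -Inf
  for (m1 in mus) for (m2 in mus) for (s in sds) for (p in ps) {
    ll <- binormal_loglik(x, m1, s, m2, s, p)
    if (ll > best) best <- ll
  }
  best
}

# analytic mixture CDF for Kolmogorov distance checks
pbinormal <- function(spec, q) {
  spec$p_r * pnorm(q, spec$mu1, spec$sigma1) +
    (1 - spec$p_r) * pnorm(q, spec$mu2, spec$sigma2)
}
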