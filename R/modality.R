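#' Generalized Helguero separation factor
#'
#' For a mixture of two Gaussians with variance ratio
#' `r = max(sigma1, sigma2)^2 / min(sigma1, sigma2)^2 >= 1`, the separation
#' factor is
#' \deqn{S(r) = \frac{\sqrt{-2 + 3r + 3r^2 - 2r^3 + 2(r^2 - r + 1)^{3/2}}}
#'                   {\sqrt{r}\,(1 + \sqrt{r})}}
#' and the mixture density is unimodal for every mixture proportion if and
#' only if `|mu2 - mu1| <= S(r) * (sigma1 + sigma2)`. At `r = 1` the factor
#' is exactly 1, recovering the classical de Helguero bound of two standard
#' deviations between the means.
#'
#' @param sigma1,sigma2 Component standard deviations (> 0). The result is
#'   symmetric in the two arguments.
#' @return List with `r` (variance ratio >= 1), `s_r` (the separation
#'   factor) and `threshold` (`s_r * (sigma1 + sigma2)`, the critical mean
#'   separation).
#' @examples
#' separation_factor(1, 1)$threshold  # 2: the classical equal-variance bound
#' @export
separation_factor <- function(sigma1, sigma2) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  v <- sort(c(sigma1^2, sigma2^2))
  r <- v[2] / v[1]
  s_r <- sqrt(-2 + 3 * r + 3 * r^2 - 2 * r^3 + 2 * (r^2 - r + 1)^1.5) /
    (sqrt(r) * (1 + sqrt(r)))
  list(r = r, s_r = s_r, threshold = s_r * (sigma1 + sigma2))
}

#' Modality of a binormal model
#'
#' Applies the generalized Helguero criterion: the fitted two-component model
#' is labelled bimodal (`"B"`) when the separation of the component means
#' exceeds `S(r) * (sigma1 + sigma2)` (see [separation_factor()]), and
#' unimodal (`"U"`) otherwise. The criterion is a for-all-proportions
#' statement; the numerical mode count at the model's own `p_r` is attached
#' for reference.
#'
#' @param model A [binormal_spec()] (or a [binormal_fit()], whose model is
#'   used).
#' @return Object of class `modality_result`: `r`, `s_r`, `separation`,
#'   `threshold`, `label` (`"U"`/`"B"`) and `n_modes_numeric`.
#' @examples
#' is_bimodal(binormal_spec(0, 1, 5, 1, 0.5))$label  # "B"
#' is_bimodal(binormal_spec(0, 1, 1, 1, 0.5))$label  # "U"
#' @export
is_bimodal <- function(model) {
  if (inherits(model, "binormal_fit")) model <- model$model
  stopifnot(inherits(model, "binormal_spec"))
  sf <- separation_factor(model$sigma1, model$sigma2)
  separation <- abs(model$mu2 - model$mu1)
  structure(list(r = sf$r, s_r = sf$s_r, separation = separation,
                 threshold = sf$threshold,
                 label = if (separation > sf$threshold) "B" else "U",
                 n_modes_numeric = count_modes_numeric(model)),
            class = "modality_result")
}

#' @export
print.modality_result <- function(x, ...) {
  cat(sprintf("<modality_result> %s  (separation %.4g vs threshold %.4g; r = %.4g, S(r) = %.4g; numeric modes = %d)\n",
              x$label, x$separation, x$threshold, x$r, x$s_r,
              x$n_modes_numeric))
  invisible(x)
}

#' Count the modes of a binormal density numerically
#'
#' Brute-force oracle for the analytic modality criterion: evaluates the
#' mixture density on a regular grid spanning
#' `[min(mu) - 6 * max(sigma), max(mu) + 6 * max(sigma)]` and counts strict
#' local maxima after collapsing flat runs. With the default 4096-point grid
#' the count is exact for any mode separation worth reporting.
#'
#' @param model A [binormal_spec()].
#' @param grid_n Number of grid points (default 4096).
#' @return 1 or 2.
#' @export
count_modes_numeric <- function(model, grid_n = 4096L) {
  stopifnot(inherits(model, "binormal_spec"))
  smax <- max(model$sigma1, model$sigma2)
  lo <- min(model$mu1, model$mu2) - 6 * smax
  hi <- max(model$mu1, model$mu2) + 6 * smax
  x <- seq(lo, hi, length.out = grid_n)
  g <- dbinormal(model, x)
  d <- sign(diff(g))
  d <- d[d != 0]                      # merge plateaus
  if (length(d) == 0L) return(1L)
  v <- rle(d)$values
  modes <- sum(v[-length(v)] == 1 & v[-1] == -1)
  if (v[length(v)] == 1) modes <- modes + 1L   # maximum at the right edge
  max(1L, as.integer(modes))
}

#' Mixture proportion range over which a binormal model is bimodal
#'
#' Solves the stationarity condition of the mixture density for the
#' proportion as a function of mode location:
#' `p/(1-p) = -f2'(x) / f1'(x)` on the open interval between the means. The
#' density has two modes exactly for proportions strictly inside the range of
#' the interior extrema of that curve; a monotone curve means no proportion
#' makes the mixture bimodal. This is the exact counterpart of the
#' [separation_factor()] bound and is used as its independent check.
#'
#' @param model A [binormal_spec()] (its `p_r` is ignored).
#' @param grid_n Resolution of the scan between the means.
#' @return `NULL` when no proportion yields two modes; otherwise
#'   `c(lo, hi)`, the open interval of bimodal proportions.
#' @export
bimodal_p_range <- function(model, grid_n = 20001L) {
  mu1 <- min(model$mu1, model$mu2); mu2 <- max(model$mu1, model$mu2)
  s1 <- if (model$mu1 <= model$mu2) model$sigma1 else model$sigma2
  s2 <- if (model$mu1 <= model$mu2) model$sigma2 else model$sigma1
  if (mu2 - mu1 < .Machine$double.eps^0.5) return(NULL)
  x <- seq(mu1 + 1e-9 * (mu2 - mu1), mu2 - 1e-9 * (mu2 - mu1),
           length.out = grid_n)
  # g'(x) = 0  <=>  p * (x - mu1)/s1^2 f1 = (1 - p) * (mu2 - x)/s2^2 f2
  a <- (x - mu1) / s1^2 * dnorm(x, mu1, s1)
  b <- (mu2 - x) / s2^2 * dnorm(x, mu2, s2)
  p <- b / (a + b)
  # p(x) runs from 1 at mu1 to 0 at mu2; the mixture is bimodal for exactly
  # the proportions strictly between its interior turning points
  dp <- diff(p)
  if (all(dp >= -1e-15) || all(dp <= 1e-15)) return(NULL)
  turn <- which(diff(sign(dp)) != 0)
  turn <- turn[turn > 1L & turn < grid_n - 1L]
  if (length(turn) == 0L) return(NULL)
  vals <- p[turn + 1L]
  range(vals)
}

#' Collapsed weighted statistics of a binormal model
#'
#' When a binormal fit is unimodal in practice (M2/U cells), the distribution
#' can still be summarized by a single weighted mean and standard deviation:
#' the exact moments of the mixture.
#'
#' @param model A [binormal_spec()] or [binormal_fit()].
#' @return List with `mean` and `sd`.
#' @examples
#' weighted_stats(binormal_spec(0, 1, 10, 1, 0.5))$mean  # 5
#' @export
weighted_stats <- function(model) {
  if (inherits(model, "binormal_fit")) model <- model$model
  stopifnot(inherits(model, "binormal_spec"))
  p <- model$p_r
  m <- p * model$mu1 + (1 - p) * model$mu2
  v <- p * (model$sigma1^2 + model$mu1^2) +
    (1 - p) * (model$sigma2^2 + model$mu2^2) - m^2
  list(mean = m, sd = sqrt(v))
}
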